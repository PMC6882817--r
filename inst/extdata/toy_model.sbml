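<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" compartment="e" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="A" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B_e" compartment="e" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="lb_rev" value="-20" constant="true"/>
      <parameter id="ub_twenty" value="20" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g_at" fbc:label="g_at"/>
      <fbc:geneProduct fbc:id="g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="g_bt" fbc:label="g_bt"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfProducts>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="At" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: transport</p></body></notes>
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g_at"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R1" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_twenty">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: core</p></body></notes>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:or>
              <fbc:geneProductRef fbc:geneProduct="g1"/>
              <fbc:geneProductRef fbc:geneProduct="g2"/>
            </fbc:or>
            <fbc:geneProductRef fbc:geneProduct="g3"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="Bt" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_twenty">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: transport</p></body></notes>
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g_bt"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_B" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_twenty">
        <listOfReactants>
          <speciesReference species="B_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
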