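## A hand-built toy metabolic network emulating central carbon metabolism:
## a glycolysis-like chain, a pentose-phosphate-like branch, a TCA-like
## cycle with anaplerotic shunts, glutaminolysis, lipid synthesis and a
## serine/glycine branch, plus boundary exchanges.  Every boundary
## metabolite is touched by exactly one transporter and one exchange, so
## exchange fluxes are conservation-locked to their transporter.

#' Build the toy metabolic network
#'
#' Fixed 44-reaction topology (the simulation seed changes omics
#' intensities, never the network).  All internal reactions carry a GPR
#' (a few with AND/OR structure), eight subsystems, ~29% bidirectional
#' reactions, and a nonzero FBA optimum through lactate export.
#'
#' @param config a \code{\link{simulation_config}} (currently only carried
#'   for interface symmetry; topology is fixed).
#' @return a \code{\link{metabolic_network}}.
#' @export
build_toy_network <- function(config = simulation_config()) {
  mets <- data.frame(
    id = c("glc_e", "glc", "g6p", "f6p", "fdp", "g3p", "pep", "pyr",
           "lac", "lac_e", "r5p", "nuc", "nuc_e", "accoa", "malcoa",
           "fa", "fa_e", "oaa", "cit", "icit", "akg", "succ", "fum",
           "mal", "gln_e", "gln", "glu", "glu_e", "ser", "ser_e",
           "gly", "gly_e", "pyr_e"),
    compartment = "c")
  mets$compartment[grepl("_e$", mets$id)] <- "e"

  rxn <- function(id, st, lb, ub, gpr = NULL, sub = "exchange")
    reaction(id, st, lb, ub, gpr = gpr, subsystem = sub)

  rxns <- list(
    ## exchanges (no GPR)
    rxn("EX_glc", c(glc_e = 1), 0, 10),
    rxn("EX_gln", c(gln_e = 1), 0, 6),
    rxn("EX_lac", c(lac_e = -1), 0, 40),
    rxn("EX_nuc", c(nuc_e = -1), 0, 2),
    rxn("EX_fa",  c(fa_e = -1), 0, 3),
    rxn("EX_glu", c(glu_e = -1), 0, 6),
    rxn("EX_ser", c(ser_e = -1), 0, 2),
    rxn("EX_gly", c(gly_e = -1), 0, 2),
    rxn("EX_pyr", c(pyr_e = 1), 0, 6),
    ## transporters
    rxn("GLCt",  c(glc_e = -1, glc = 1), 0, 10, "g_glct", "transport"),
    rxn("GLNt",  c(gln_e = -1, gln = 1), 0, 6, "g_glnt", "transport"),
    rxn("LACt",  c(lac = -1, lac_e = 1), -40, 40, "g_lact", "transport"),
    rxn("NUCt",  c(nuc = -1, nuc_e = 1), 0, 2, "g_nuct", "transport"),
    rxn("FAt",   c(fa = -1, fa_e = 1), 0, 3, "g_fat", "transport"),
    rxn("GLUt",  c(glu = -1, glu_e = 1), -6, 6, "g_glut", "transport"),
    rxn("SERt",  c(ser = -1, ser_e = 1), 0, 2, "g_sert", "transport"),
    rxn("GLYt",  c(gly = -1, gly_e = 1), 0, 2, "g_glyt", "transport"),
    rxn("PYRt",  c(pyr_e = -1, pyr = 1), 0, 6, "g_pyrt", "pyruvate"),
    ## glycolysis
    rxn("HEX1", c(glc = -1, g6p = 1), 0, 10, "g_hex1", "glycolysis"),
    rxn("PGI",  c(g6p = -1, f6p = 1), -20, 20, "g_pgi", "glycolysis"),
    rxn("PFK",  c(f6p = -1, fdp = 1), 0, 20, "g_pfkl or g_pfkm", "glycolysis"),
    rxn("FBA3", c(fdp = -1, g3p = 2), 0, 20, "g_fba3", "glycolysis"),
    rxn("GAPD", c(g3p = -1, pep = 1), -40, 40, "g_gapd", "glycolysis"),
    rxn("PYK",  c(pep = -1, pyr = 1), 0, 40, "g_pyk", "glycolysis"),
    rxn("LDH",  c(pyr = -1, lac = 1), -40, 40, "g_ldha or g_ldhb", "glycolysis"),
    ## pentose phosphate-like branch
    rxn("G6PD", c(g6p = -1, r5p = 1), 0, 4, "g_g6pd and g_pgls", "ppp"),
    rxn("TKT",  c(r5p = -1, f6p = 1), -4, 4, "g_tkt", "ppp"),
    rxn("PRPS", c(r5p = -1, nuc = 1), 0, 2, "g_prps", "ppp"),
    ## TCA-like cycle
    rxn("PDH",  c(pyr = -1, accoa = 1), 0, 20, "g_pdha and g_pdhb", "tca"),
    rxn("CS",   c(accoa = -1, oaa = -1, cit = 1), 0, 20, "g_cs", "tca"),
    rxn("ACONT", c(cit = -1, icit = 1), -20, 20, "g_acont", "tca"),
    rxn("ICDH", c(icit = -1, akg = 1), 0, 20, "g_idh1 or g_idh2", "tca"),
    rxn("AKGD", c(akg = -1, succ = 1), 0, 20, "g_akgd", "tca"),
    rxn("SUCD", c(succ = -1, fum = 1), -20, 20, "g_sucd", "tca"),
    rxn("FUM",  c(fum = -1, mal = 1), -20, 20, "g_fum", "tca"),
    rxn("MDH",  c(mal = -1, oaa = 1), -20, 20, "g_mdh", "tca"),
    ## anaplerosis / pyruvate cycling
    rxn("PC", c(pyr = -1, oaa = 1), 0, 4, "g_pc", "anaplerosis"),
    rxn("ME", c(mal = -1, pyr = 1), 0, 4, "g_me1 or g_me2", "anaplerosis"),
    ## glutaminolysis
    rxn("GLS", c(gln = -1, glu = 1), 0, 6, "g_gls", "glutaminolysis"),
    rxn("GDH", c(glu = -1, akg = 1), -6, 6, "g_gdh", "glutaminolysis"),
    ## lipid synthesis
    rxn("ACC", c(accoa = -1, malcoa = 1), 0, 3, "g_acc", "lipid"),
    rxn("FAS", c(malcoa = -1, fa = 1), 0, 3, "g_fasn and g_mcat", "lipid"),
    ## serine/glycine branch
    rxn("PGCD", c(g3p = -1, ser = 1), 0, 2, "g_pgcd", "serine"),
    rxn("GLYC", c(ser = -1, gly = 1), -2, 2, "g_shmt", "serine")
  )
  metabolic_network(mets, rxns)
}

# reaction ids considered exchanges (unlabeled in the planted truth)
exchange_reactions <- function(net) net$rxn_id[grepl("^EX_", net$rxn_id)]

# Conservation-locked single-path chains among internal reactions: the
# members of each group carry identical (or proportional) flux in every
# feasible state, hence pairwise coupling 1.  Used by the generator to
# plant indirect reactions stoichiometrically coupled to direct drivers.
locked_groups <- function(net) {
  gr <- list(c("GLCt", "HEX1"), c("PFK", "FBA3"), c("GAPD", "PYK"),
             c("CS", "ACONT", "ICDH"), c("AKGD", "SUCD", "FUM"),
             c("ACC", "FAS", "FAt"), c("GLNt", "GLS"), c("PGCD", "SERt"),
             c("GLYC", "GLYt"), c("NUCt", "PRPS"))
  lapply(gr, intersect, x = net$rxn_id)
}

# Pathway-level chains (locked groups plus their tightly coupled
# neighbours).  The generator keeps at most one indirect reaction per
# chain, so indirect reactions are coupled to direct drivers but not to
# each other.
pathway_chains <- function(net) {
  gr <- list(c("GLCt", "HEX1", "PGI", "PFK", "FBA3", "GAPD", "PYK"),
             c("LDH", "LACt"),
             c("PDH", "CS", "ACONT", "ICDH", "AKGD", "SUCD", "FUM", "MDH"),
             c("G6PD", "TKT", "PRPS", "NUCt"),
             c("ACC", "FAS", "FAt"),
             c("GLNt", "GLS", "GDH", "GLUt"),
             c("PGCD", "SERt", "GLYC", "GLYt"),
             c("PC", "ME"),
             "PYRt")
  lapply(gr, intersect, x = net$rxn_id)
}

# The chain member reserved as planted-indirect: a bidirectional member
# where the chain has one (indirect reactions are predominantly
# reversible in the emulated structure), else the second-to-last member.
reserve_member <- function(net, g) {
  if (length(g) < 2) return(character(0))
  bid <- g[is_bidirectional(net, g)]
  if (length(bid) > 0) bid[length(bid)] else g[length(g) - 1L]
}

# central-carbon reactions offered as "measured" fluxes
central_flux_reactions <- function(net) {
  intersect(c("HEX1", "PGI", "PFK", "FBA3", "GAPD", "PYK", "LDH", "PDH",
              "CS", "ICDH", "AKGD", "GLS", "G6PD", "PC", "ME"), net$rxn_id)
}
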