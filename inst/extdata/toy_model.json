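{
  "metabolites": [
    {"id": "A_e", "compartment": "e"},
    {"id": "A", "compartment": "c"},
    {"id": "B", "compartment": "c"},
    {"id": "B_e", "compartment": "e"}
  ],
  "reactions": [
    {"id": "EX_A", "stoichiometry": {"A_e": 1}, "lower_bound": 0,
     "upper_bound": 10, "gpr": "", "subsystem": "exchange"},
    {"id": "At", "stoichiometry": {"A_e": -1, "A": 1}, "lower_bound": 0,
     "upper_bound": 10, "gpr": "g_at", "subsystem": "transport"},
    {"id": "R1", "stoichiometry": {"A": -1, "B": 1}, "lower_bound": -20,
     "upper_bound": 20, "gpr": "(g1 or g2) and g3", "subsystem": "core"},
    {"id": "Bt", "stoichiometry": {"B": -1, "B_e": 1}, "lower_bound": 0,
     "upper_bound": 20, "gpr": "g_bt", "subsystem": "transport"},
    {"id": "EX_B", "stoichiometry": {"B_e": -1}, "lower_bound": 0,
     "upper_bound": 20, "gpr": "", "subsystem": "exchange"}
  ],
  "genes": ["g_at", "g1", "g2", "g3", "g_bt"]
}
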