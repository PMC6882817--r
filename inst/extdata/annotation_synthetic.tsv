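gene	term
g1	TF_A
g2	TF_A
g3	TF_B
g_at	TF_B
g_hex1	TF_A
g_pgi	TF_C
g_pfkl	TF_C
g_pyk	TF_A
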