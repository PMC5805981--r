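# KB-model parameter template (activator-titration circuit with explicit
# mRNA, activator homodimerization, distributive multi-site binding and
# reversible titration).
#
# Numeric values are NOT shipped with this package: fill every ~ (null)
# placeholder with the rate set of the original publication before use.
# Units follow the model's time base; second-order rates are per
# concentration per time.  Validated by read_extended_params() /
# kb_params(): every key must be present and non-negative.
model: KB
tx_A: ~          # activator transcription (constitutive)
tx_I_free: ~     # inhibitor transcription with empty promoter (G = 0)
tx_I_bound: ~    # inhibitor transcription with any site bound (G > 0)
tl_A: ~          # activator translation
tl_I: ~          # inhibitor translation
d_rA: ~          # activator mRNA degradation
d_rI: ~          # inhibitor mRNA degradation
d_A: ~           # activator monomer degradation
d_A2: ~          # activator homodimer degradation
d_I: ~           # inhibitor degradation
d_AI: ~          # heterodimer degradation
k_dim_f: ~       # dimerization forward, 2A -> A2
k_dim_r: ~       # dimerization reverse, A2 -> 2A
k_het_f: ~       # heterodimerization forward, A + I -> AI
k_het_r: ~       # heterodimerization reverse, AI -> A + I
kappa_b: ~       # dimer-promoter association (per site, distributive)
theta_b: ~       # dimer-promoter dissociation (per bound site)
G_max: ~         # number of promoter binding sites
V: ~             # system-size analogue
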