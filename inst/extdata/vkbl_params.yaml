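# VKBL-model parameter template (activator-titration circuit with activator
# self-activation; two one-site promoters with binary occupancy).
#
# Numeric values are NOT shipped with this package: fill every ~ (null)
# placeholder with the rate set of the original publication before use.
# Validated by read_extended_params() / vkbl_params().
model: VKBL
tx_A_free: ~     # activator transcription, own promoter free
tx_A_bound: ~    # activator transcription, activator bound (self-activation)
tx_R_free: ~     # inhibitor transcription, promoter free
tx_R_bound: ~    # inhibitor transcription, activator bound
tl_A: ~          # activator translation
tl_R: ~          # inhibitor translation
d_mA: ~          # activator mRNA degradation
d_mR: ~          # inhibitor mRNA degradation
d_A: ~           # activator degradation (also releases R from the complex)
d_R: ~           # inhibitor degradation
k_C: ~           # A + R -> C association (titration)
kappa_A: ~       # activator binding at its own promoter
theta_A: ~       # unbinding from the A promoter
kappa_R: ~       # activator binding at the R promoter
theta_R: ~       # unbinding from the R promoter
V: ~             # system-size analogue
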