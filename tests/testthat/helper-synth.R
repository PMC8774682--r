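# shared fixtures, built in code

# study-condition truths used across tests: competitive inhibition with the
# reference Km/Ki, 1:1 binding with the reference Ka, and the assay's
# sampling schedule (every 3 min to 30 min, every 6 min to 60 min, then
# 70 and 80 min)
ref_kinetic_truth <- function(model = "competitive", Ki2 = NULL) {
  kinetic_truth(Vmax = 1, Km = 1.674, Ki = 4.32,
                substrate_grid = c(0.5, 1, 2, 4, 8, 16),
                inhibitor_grid = c(0, 4, 8, 10),
                model = model, Ki2 = Ki2)
}

ref_binding_truth <- function(Ka = 6.66e4) {
  binding_truth(Ka = Ka, Pt = 1.7e-7,
                quencher_grid = seq(0, 16e-6, length.out = 10))
}

inactivation_schedule <- function() {
  c(seq(0, 30, by = 3), seq(36, 60, by = 6), 70, 80) * 60
}

cfg_clean <- function(seed = 1) synth_config(seed = seed)

cfg_noisy <- function(seed = 1, scale = 0.01) {
  synth_config(seed = seed, noise_model = "gaussian_multiplicative",
               noise_scale = scale)
}
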