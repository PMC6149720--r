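# shared fixtures: the three measurement contrasts and a reference model
study_contrasts <- function() lapply(c(0.08, 0.20, 0.50), contrast_spec)

reference_model <- function() bilayer_model()

# full reduction of a simulated table; returns structure + truth for
# round-trip comparisons
simulate_and_reduce <- function(model, noise_scale = 0, seed = 1,
                                hmax = 5, noise_model = "counting") {
  tab <- simulate_peak_table(model, study_contrasts(), hmax = hmax,
                             noise_scale = noise_scale, seed = seed,
                             noise_model = noise_model)
  res <- reduce_sample(tab)
  list(res = res, truth = attr(tab, "truth"), tab = tab)
}

# true sign matrix (orders x contrasts) of a simulated table
truth_signs <- function(truth) {
  sign(vapply(truth$F, identity, numeric(length(truth$F[[1]]))))
}
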