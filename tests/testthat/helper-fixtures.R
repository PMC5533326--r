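# shared fixtures: small deterministic worlds used across test files

# default world with all stochastic disturbances switched off
noiseless_config <- function(..., n_per_point = 1) {
  synth_config(
    noise_sd = 0, scatter_range = c(1, 1),
    baseline_offset_range = c(0, 0), baseline_slope_range = c(0, 0),
    calibration_design = data.frame(pmi_h = seq(0, 48, 6), n = n_per_point),
    ...)
}

# near-noiseless limit of the full default design (both sets at full size)
clean_config <- function(noise_sd = 1e-5, seed = 1) {
  synth_config(noise_sd = noise_sd, scatter_range = c(1, 1),
               baseline_offset_range = c(0, 0), baseline_slope_range = c(0, 0),
               seed = seed)
}

# small fast world: short axis, modest designs
small_config <- function(..., seed = 1) {
  synth_config(
    axis = seq(1800, 900, length.out = 60),
    calibration_design = data.frame(pmi_h = seq(0, 48, 6), n = 4),
    prediction_design = data.frame(pmi_h = seq(3, 45, 6), n = 1),
    seed = seed, ...)
}

# random regression problem for PLS unit tests
random_problem <- function(n = 20, p = 50, seed = 1) {
  withr::with_seed(seed, {
    list(X = matrix(rnorm(n * p), n, p), y = rnorm(n),
         X_new = matrix(rnorm(10 * p), 10, p))
  })
}

# planted-signal world for GA recovery tests: 3 complementary informative
# bins among nb, each carrying one orthogonal third of the response
planted_bin_problem <- function(seed, n = 60, nb = 50,
                                info = c(10, 25, 40), noise = 0.05) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * length(info)), n, length(info))
    y <- rowSums(z) * 5 + 24
    X <- matrix(rnorm(n * nb), n, nb)
    for (k in seq_along(info)) X[, info[k]] <- z[, k] + rnorm(n, 0, noise)
    list(X = X, y = y, info = info)
  })
}
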