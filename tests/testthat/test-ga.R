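test_that("binning is exhaustive with a remainder bin", {
  b467 <- bin_variables(467, 3)
  expect_equal(nrow(b467), 156)
  sizes <- b467$end - b467$start + 1
  expect_equal(sum(sizes == 3), 155)
  expect_equal(sizes[156], 2)
  expect_equal(b467$start[1], 1)
  expect_equal(b467$end[156], 467)
  expect_true(all(b467$start[-1] == b467$end[-156] + 1))  # non-overlapping

  expect_equal(nrow(bin_variables(6, 3)), 2)
  expect_equal(bin_variables(7, 3)$end - bin_variables(7, 3)$start + 1,
               c(3, 3, 1))
})

test_that("binned columns are the means of their members", {
  withr::with_seed(1, X <- matrix(rnorm(5 * 7), 5, 7))
  bins <- bin_variables(7, 3)
  Xb <- apply_bins(X, bins)
  expect_equal(Xb[, 1], rowMeans(X[, 1:3]))
  expect_equal(Xb[, 2], rowMeans(X[, 4:6]))
  expect_equal(Xb[, 3], X[, 7])
})

test_that("a GA run is deterministic, monotone, and finds a planted predictor", {
  prob <- planted_bin_problem(seed = 1, nb = 12, info = 5)
  cfg <- ga_config(n_runs = 1, n_evaluations = 60, population = 20)

  r1 <- ga_run(prob$X, prob$y, cfg, run_seed = 99)
  r2 <- ga_run(prob$X, prob$y, cfg, run_seed = 99)
  expect_identical(r1, r2)
  r3 <- ga_run(prob$X, prob$y, cfg, run_seed = 100)
  expect_false(identical(r1$trajectory, r3$trajectory))

  # elitism: best-so-far fitness never decreases
  expect_true(all(diff(r1$trajectory) >= -1e-12))

  # the planted near-perfect predictor bin is selected
  expect_equal(r1$best[5], 1L)

  # degenerate single-bin search space: repaired to the only chromosome
  one <- ga_run(prob$X[, 5, drop = FALSE], prob$y,
                ga_config(n_evaluations = 10, population = 4), run_seed = 1)
  expect_equal(one$best, 1L)
  expect_gt(one$best_fitness, 90)

  expect_error(ga_run(prob$X, rep(1, nrow(prob$X)), cfg, 1),
               class = "plasmapls_error")
})

fake_runs <- function(bests) {
  lapply(seq_len(nrow(bests)), function(i) {
    list(best = bests[i, ], best_fitness = 0, trajectory = numeric(0))
  })
}

test_that("aggregation applies the strict >50% rule over runs", {
  # frequencies 60 / 50 / 51 out of 100: bins 1 and 3 retained, 50 is not
  bests <- cbind(rep(1:0, c(60, 40)), rep(1:0, c(50, 50)), rep(1:0, c(51, 49)))
  sel <- aggregate_runs(fake_runs(bests), bin_variables(9, 3), ga_config())
  expect_equal(sel$frequency$frequency, c(60, 50, 51))
  expect_equal(sel$retained_bins, c(1, 3))
  expect_equal(sel$retained_variables, c(1:3, 7:9))

  # all runs identical: frequencies in {0, n_runs}; retained = the chromosome
  bests2 <- matrix(rep(c(1L, 0L, 1L), each = 10), 10, 3)
  sel2 <- aggregate_runs(fake_runs(bests2), bin_variables(9, 3),
                         ga_config(n_runs = 10))
  expect_true(all(sel2$frequency$frequency %in% c(0, 10)))
  expect_equal(sel2$retained_bins, c(1, 3))

  # zero retained bins: warned fallback to the top bins
  bests3 <- matrix(0L, 10, 3); bests3[1:2, 2] <- 1L
  expect_warning(sel3 <- aggregate_runs(fake_runs(bests3), bin_variables(9, 3),
                                        ga_config(n_runs = 10)),
                 "falling back")
  expect_true(sel3$fallback)
  expect_true(2 %in% sel3$retained_bins)

  # 56 retained triple bins expand to 168 original variables
  bests4 <- matrix(0L, 4, 156)
  bests4[, 1:56] <- 1L
  sel4 <- aggregate_runs(fake_runs(bests4), bin_variables(467, 3),
                         ga_config(n_runs = 4))
  expect_length(sel4$retained_variables, 168)
  expect_equal(round(100 * (1 - 168 / 467)), 64)  # percent data-size reduction
})

test_that("selecting every variable reproduces the full-spectrum report", {
  cfg <- small_config(seed = 3)
  sets <- simulate_dataset(cfg)
  pc <- preprocess_spectra(sets$calibration)
  pp <- preprocess_spectra(sets$prediction)
  p <- length(wavenumbers(pc))
  all_bins <- bin_variables(p, 3)
  bests <- matrix(1L, 2, nrow(all_bins))
  sel <- aggregate_runs(fake_runs(bests), all_bins, ga_config(n_runs = 2))
  full <- evaluate_pls(pc, pp)
  ga <- fit_selected(pc, pp, sel)
  expect_equal(ga$rmsecv, full$rmsecv)
  expect_equal(ga$rmsep, full$rmsep)
  expect_equal(ga$n_lv, full$n_lv)
  expect_equal(ga$method, "GA-PLS")
})

test_that("ga_select recovers planted informative bins by frequency", {
  prob <- planted_bin_problem(seed = 7)
  cfg <- ga_config(bin_width = 1, n_runs = 10, n_evaluations = 100,
                   population = 30, seed = 7)
  sel <- ga_select(prob$X, prob$y, cfg)
  expect_true(all(prob$info %in% sel$retained_bins))
  expect_true(all(sel$frequency$frequency >= 0 &
                    sel$frequency$frequency <= 10))
  # determinism of the replicated driver under one master seed
  sel2 <- ga_select(prob$X, prob$y, cfg)
  expect_identical(sel$frequency, sel2$frequency)
})

test_that("GA selection does not hurt cross-validated error on planted signal", {
  # median comparison over seeds, scaled down for the test budget
  deltas <- vapply(1:5, function(seed) {
    prob <- planted_bin_problem(seed = seed, nb = 30, info = c(5, 15, 25))
    sel <- ga_select(prob$X, prob$y,
                     ga_config(bin_width = 1, n_runs = 6, n_evaluations = 80,
                               seed = seed))
    full <- evaluate_pls(prob$X, prob$X, y_cal = prob$y, y_pred = prob$y)
    ga <- fit_selected(prob$X, prob$X, sel, y_cal = prob$y, y_pred = prob$y)
    ga$rmsecv - full$rmsecv
  }, numeric(1))
  expect_lte(median(deltas), 0)
})
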