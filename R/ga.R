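#' GA-PLS configuration
#'
#' Settings for replicated genetic-algorithm wavelength selection. Defaults
#' follow the Leardi-style small-run recipe: spectral variables are first
#' reduced by 3-point binning, each replicate run evolves a small population
#' of binary chromosomes (one gene per bin) under cross-validated PLS fitness,
#' and bins selected by more than half of the replicate runs are retained.
#'
#' The search is steady-state: each new chromosome is bred from two
#' tournament-selected parents (single-point crossover, per-gene mutation)
#' and replaces the current worst individual when it is fitter, so the best
#' chromosome can never be lost and best-so-far fitness is non-decreasing.
#' A fitness cache keeps re-visited chromosomes from consuming the
#' evaluation budget.
#'
#' @param bin_width contiguous wavenumbers averaged per bin (default 3).
#' @param n_runs replicate GA runs (default 100).
#' @param population chromosomes per run (default 30, must be even).
#' @param n_evaluations fitness-evaluation budget per run (default 200).
#' @param p_init_on probability that a bin starts selected (default
#'   `5 / n_bins`, set at run time when `NULL`).
#' @param p_crossover single-point crossover probability (default 0.5).
#' @param p_mutation per-gene mutation probability (default 0.01).
#' @param elitism number of protected top chromosomes; the steady-state
#'   scheme never replaces the best individuals, so this is honored by
#'   construction.
#' @param tournament tournament size for parent selection (default 3).
#' @param fitness_max_lv LV ceiling inside the fitness CV (default 10).
#' @param frequency_threshold retention threshold as a fraction of runs;
#'   strictly greater-than (default 0.5).
#' @param seed master seed; per-run seeds are derived by counter.
#' @return a `ga_config` list.
#' @export
ga_config <- function(bin_width = 3, n_runs = 100, population = 30,
                      n_evaluations = 200, p_init_on = NULL,
                      p_crossover = 0.5, p_mutation = 0.01, elitism = 2,
                      tournament = 3, fitness_max_lv = 10,
                      frequency_threshold = 0.5, seed = 1) {
  stopifnot(bin_width >= 1, n_runs >= 1, population >= 4,
            population %% 2 == 0, n_evaluations >= population,
            frequency_threshold > 0, frequency_threshold < 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation > 0, p_mutation < 1)
  structure(list(bin_width = bin_width, n_runs = n_runs, population = population,
                 n_evaluations = n_evaluations, p_init_on = p_init_on,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = elitism, tournament = tournament,
                 fitness_max_lv = fitness_max_lv,
                 frequency_threshold = frequency_threshold,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Bin contiguous spectral variables
#'
#' Consecutive, non-overlapping, exhaustive bins of `width` variables in axis
#' order; the final bin holds the remainder (1..width variables). 467
#' variables at width 3 give 156 bins (155 triples and one pair).
#'
#' @param p number of original variables.
#' @param width bin width (default 3).
#' @return tibble with `bin`, `start`, `end` (original-variable index ranges).
#' @export
bin_variables <- function(p, width = 3) {
  stopifnot(p >= 1, width >= 1)
  starts <- seq(1, p, by = width)
  tibble::tibble(bin = seq_along(starts), start = starts,
                 end = pmin(starts + width - 1, p))
}

#' Average spectra within bins
#'
#' @param x matrix of original variables.
#' @param bins bin table from [bin_variables()].
#' @return matrix with one column per bin (mean of member columns).
#' @export
apply_bins <- function(x, bins) {
  x <- as.matrix(x)
  out <- vapply(seq_len(nrow(bins)), function(b) {
    rowMeans(x[, bins$start[b]:bins$end[b], drop = FALSE])
  }, numeric(nrow(x)))
  matrix(out, nrow = nrow(x))
}

# 5-fold venetian-blind CV "explained variance" fitness:
# 100 * (1 - PRESS / SS_y), LV count chosen by minimum CV PRESS up to max_lv.
cv_fitness <- function(X, y, max_lv = 10, n_folds = 5) {
  n <- nrow(X)
  folds <- (seq_len(n) - 1) %% n_folds + 1
  ceil <- min(max_lv, ncol(X), n - max(tabulate(folds)) - 1)
  if (ceil < 1) ceil <- 1
  press <- numeric(ceil)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- try(pls1_engine(X[tr, , drop = FALSE], y[tr], ceil), silent = TRUE)
    if (inherits(fit, "try-error")) return(-Inf)
    E <- (sweep(X[!tr, , drop = FALSE], 2, fit$x_mean) %*% fit$B + fit$y_mean) - y[!tr]
    press <- press + colSums(E^2)
  }
  100 * (1 - min(press) / sum((y - mean(y))^2))
}

#' One replicate GA run over binned variables
#'
#' @param x_binned binned predictor matrix (samples x bins).
#' @param y response.
#' @param config a [ga_config()].
#' @param run_seed integer seed for this replicate; identical seeds give
#'   identical trajectories.
#' @return list with `best` (binary chromosome), `best_fitness`, and
#'   `trajectory` (best-so-far fitness after each consumed evaluation).
#' @export
ga_run <- function(x_binned, y, config = ga_config(), run_seed) {
  X <- as.matrix(x_binned)
  nb <- ncol(X)
  if (nrow(X) < 10) abort_plasmapls("GA fitness CV needs n >= 10", "ga_invalid")
  if (stats::sd(y) == 0) abort_plasmapls("response has zero variance", "ga_invalid")
  p_init <- config$p_init_on %||% (5 / nb)
  pop_size <- min(config$population, config$n_evaluations)
  with_seed(run_seed, {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    evals <- 0L
    traj <- numeric(0)
    best_so_far <- -Inf
    evalf <- function(ch) {
      key <- rawToChar(as.raw(ch + 48L))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      f <- cv_fitness(X[, ch == 1L, drop = FALSE], y, config$fitness_max_lv)
      evals <<- evals + 1L
      best_so_far <<- max(best_so_far, f)
      traj[evals] <<- best_so_far
      cache[[key]] <- f
      f
    }
    repair <- function(ch) {
      if (sum(ch) == 0L) ch[sample.int(nb, 1)] <- 1L
      ch
    }
    pop <- matrix(as.integer(stats::runif(pop_size * nb) < p_init), pop_size, nb)
    for (i in seq_len(pop_size)) pop[i, ] <- repair(pop[i, ])
    fit <- vapply(seq_len(pop_size), function(i) evalf(pop[i, ]), numeric(1))
    iter <- 0L
    max_iter <- 100L * config$n_evaluations  # guard: converged populations only hit the cache
    while (evals < config$n_evaluations && iter < max_iter) {
      iter <- iter + 1L
      pick <- function() {
        cand <- sample.int(pop_size, min(config$tournament, pop_size))
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      ch <- if (nb > 1 && stats::runif(1) < config$p_crossover) {
        cp <- sample.int(nb - 1, 1)
        c(p1[1:cp], p2[(cp + 1):nb])
      } else {
        p1
      }
      mut <- stats::runif(nb) < config$p_mutation
      ch[mut] <- 1L - ch[mut]
      ch <- repair(ch)
      f <- evalf(ch)
      worst <- which.min(fit)
      if (f > fit[worst]) {
        pop[worst, ] <- ch
        fit[worst] <- f
      }
    }
    best <- which.max(fit)
    list(best = pop[best, ], best_fitness = fit[best], trajectory = traj)
  })
}

#' Aggregate replicate GA runs into a selection
#'
#' `frequency[b]` counts the runs whose best chromosome includes bin `b`;
#' bins are retained iff `frequency > threshold * n_runs` (strictly), and
#' retained bins are expanded to their original-variable members. When no bin
#' clears the threshold, the top 10 bins by frequency are retained as a
#' logged fallback.
#'
#' @param runs list of [ga_run()] results.
#' @param bins bin table from [bin_variables()].
#' @param config a [ga_config()].
#' @param axis optional wavenumber axis for reporting retained wavenumbers.
#' @return a `ga_selection` object.
#' @export
aggregate_runs <- function(runs, bins, config = ga_config(), axis = NULL) {
  n_runs <- length(runs)
  stopifnot(n_runs >= 1)
  freq <- Reduce(`+`, lapply(runs, `[[`, "best"))
  retained <- which(freq > config$frequency_threshold * n_runs)
  fallback <- FALSE
  if (length(retained) == 0) {
    rlang::warn("no bin exceeded the frequency threshold; falling back to top 10 bins")
    retained <- utils::head(order(-freq), 10)
    fallback <- TRUE
  }
  retained <- sort(retained)
  vars <- sort(unique(unlist(lapply(retained, function(b) {
    bins$start[b]:bins$end[b]
  }))))
  structure(list(
    bins = bins,
    frequency = tibble::tibble(
      bin = bins$bin, frequency = freq,
      wavenumber = if (!is.null(axis)) {
        (axis[bins$start] + axis[bins$end]) / 2
      } else {
        NA_real_
      },
      retained = bins$bin %in% retained),
    retained_bins = retained,
    retained_variables = vars,
    retained_wavenumbers = if (!is.null(axis)) axis[vars] else NULL,
    n_runs = n_runs,
    threshold = config$frequency_threshold,
    fallback = fallback,
    trajectories = lapply(runs, `[[`, "trajectory"),
    best_fitness = vapply(runs, `[[`, numeric(1), "best_fitness")),
    class = "ga_selection")
}

#' Replicated GA-PLS wavelength selection
#'
#' Bins the (preprocessed) calibration spectra, executes `n_runs` independent
#' GA replicates with counter-derived seeds, and aggregates best chromosomes
#' into per-bin selection frequencies and a retained variable set.
#'
#' @param data labeled calibration spectra table (or matrix with `y`).
#' @param y response when a matrix is supplied.
#' @param config a [ga_config()].
#' @return a `ga_selection` object (see [aggregate_runs()]).
#' @export
ga_select <- function(data, y = NULL, config = ga_config()) {
  d <- resolve_xy(data, y)
  bins <- bin_variables(ncol(d$X), config$bin_width)
  Xb <- apply_bins(d$X, bins)
  runs <- lapply(seq_len(config$n_runs), function(r) {
    ga_run(Xb, d$y, config, run_seed = derive_seed(config$seed, paste0("ga_run_", r)))
  })
  aggregate_runs(runs, bins, config, axis = d$axis)
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("GA-PLS selection: %d/%d bins retained (> %.0f%% of %d runs)%s\n",
              length(x$retained_bins), nrow(x$bins), 100 * x$threshold,
              x$n_runs, if (x$fallback) " [fallback]" else ""))
  cat(sprintf("  %d original variables retained\n", length(x$retained_variables)))
  invisible(x)
}

#' Evaluate a PLS model restricted to GA-retained variables
#'
#' Runs the full evaluation pipeline ([evaluate_pls()]) on the retained
#' original variables only; the report is tagged `method = "GA-PLS"`.
#'
#' @param calibration,prediction labeled spectra tables (or matrices with
#'   `y_cal` / `y_pred`).
#' @param selection a `ga_selection`.
#' @param y_cal,y_pred responses for matrix input.
#' @param ... passed to [evaluate_pls()].
#' @return a `cv_report`.
#' @export
fit_selected <- function(calibration, prediction, selection,
                         y_cal = NULL, y_pred = NULL, ...) {
  stopifnot(inherits(selection, "ga_selection"))
  vars <- selection$retained_variables
  if (length(vars) == 0) abort_plasmapls("empty selection", "ga_invalid")
  dc <- resolve_xy(calibration, y_cal)
  dp <- resolve_xy(prediction, y_pred)
  evaluate_pls(dc$X[, vars, drop = FALSE], dp$X[, vars, drop = FALSE],
               y_cal = dc$y, y_pred = dp$y, method = "GA-PLS", ...)
}
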