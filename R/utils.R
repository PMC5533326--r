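# internal helpers shared across modules

#' Derive a labelled child seed from a master seed
#'
#' Stage and run seeds are derived by hashing `master:label`, so adding a new
#' stage (or reordering runs) never perturbs the random stream of another.
#' The result is kept below 2^28 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param label character label naming the consumer of the child seed.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1, is.finite(master), length(label) == 1)
  h <- rlang::hash(paste0(as.integer(master), ":", label))
  strtoi(substr(h, 1, 7), base = 16L)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

abort_plasmapls <- function(msg, class) {
  rlang::abort(msg, class = c(class, "plasmapls_error"))
}

`%||%` <- rlang::`%||%`
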