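#' Derive a reproducible sub-seed from a master seed
#'
#' Folds a master seed together with any number of integer or character
#' qualifiers (patient index, timepoint, rater, run, stage name, ...) into a
#' stable 31-bit seed.  The fold is a plain polynomial hash modulo the Mersenne
#' prime 2^31 - 1, so sub-seeds are identical across platforms and R versions
#' and every (patient, timepoint, rater, run) cell of a cohort can be
#' regenerated in isolation.
#'
#' @param seed master seed (single integer).
#' @param ... further qualifiers; integers or strings.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "patient", 3, "rater", 1)
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  toks <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "|")) else as.integer(x)
  }), use.names = FALSE)
  h <- as.numeric(seed) %% m
  for (t in c(toks, 0L)) {
    # multiply-add in double precision; 127 * m < 2^53 so this stays exact
    h <- (h * 127 + (as.numeric(t) %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards so package internals never disturb user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
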