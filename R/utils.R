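#' @importFrom data.table data.table as.data.table setorder setorderv rbindlist
#'   setnames copy fwrite fread setattr setcolorder rowid uniqueN := .N .SD .GRP
#' @importFrom stats rpois rbinom runif dbinom dnbinom pnbinom qnbinom phyper
#'   pchisq glm binomial predict quantile optimize setNames
#' @importFrom utils head
NULL

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-sample RNG seed from a master seed and a sample identifier
#'
#' Each simulated sample consumes its own RNG stream so that cohorts are
#' reproducible regardless of the order in which samples are generated.
#' The derivation is a deterministic polynomial hash of the identifier mixed
#' with the master seed, reduced modulo 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param id Character scalar identifying the stream (e.g. a sample name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "case01_plasma")
derive_seed <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(id),
            length(id) == 1L)
  m <- 2147483647
  h <- master %% m
  for (code in utf8ToInt(id)) h <- (h * 131 + code) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

other_bases <- function(b) {
  lapply(b, function(x) BASES[BASES != x])
}

# random bases different from ref, vectorised
random_alt <- function(ref) {
  idx <- sample.int(3L, length(ref), replace = TRUE)
  vapply(seq_along(ref), function(i) BASES[BASES != ref[i]][idx[i]], character(1))
}
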