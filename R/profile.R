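#' Sequencing error profile
#'
#' Collects the error processes the simulator injects:
#' \describe{
#'   \item{seq_error}{per-base substitution probability of each sequenced
#'     read (polymerase/sequencer noise; largely removed by consensus).}
#'   \item{pre_umi_damage}{per-molecule, per-site single-strand damage
#'     probability. Damage precedes UMI ligation, so it is shared by every
#'     replicate of a molecule and survives consensus calling.}
#'   \item{umi_error}{per-base substitution probability inside the UMI tag of
#'     each read (errors after the first PCR cycle).}
#'   \item{hotspots}{a table of (site, alt, rate) giving positions with an
#'     elevated per-molecule mismatch probability; such positions reach
#'     mismatch fractions of about 1 percent in real panels and are the classic
#'     source of recurrent artifacts.}
#' }
#'
#' @param seq_error,pre_umi_damage,umi_error Probabilities in `[0, 1]`.
#' @param hotspots `NULL` or a data.frame with columns `site` (1-based panel
#'   site index), `alt` (base) and `rate`.
#' @return A list of class `umivar_error_profile`.
#' @export
#' @examples
#' error_profile(seq_error = 1e-3)
error_profile <- function(seq_error = 1e-3, pre_umi_damage = 1e-5,
                          umi_error = 1e-3, hotspots = NULL) {
  stop_if_not_prob(seq_error, "seq_error")
  stop_if_not_prob(pre_umi_damage, "pre_umi_damage")
  stop_if_not_prob(umi_error, "umi_error")
  if (!is.null(hotspots)) {
    hotspots <- as.data.table(hotspots)
    stopifnot(all(c("site", "alt", "rate") %in% names(hotspots)))
    stop_if_not_prob(hotspots$rate, "hotspot rate")
    if (any(hotspots$rate < pre_umi_damage))
      stop("hotspot rates must be at least pre_umi_damage", call. = FALSE)
    if (!all(hotspots$alt %in% BASES))
      stop("hotspot alt bases must be in {A,C,G,T}", call. = FALSE)
  } else {
    hotspots <- data.table(site = integer(), alt = character(),
                           rate = numeric())
  }
  structure(list(seq_error = seq_error, pre_umi_damage = pre_umi_damage,
                 umi_error = umi_error, hotspots = hotspots),
            class = "umivar_error_profile")
}

#' Default error profile for a panel
#'
#' The working defaults: Q30-like raw read error (1e-3), a residual
#' single-strand damage rate of 1e-5 per molecule-site, UMI-tag errors at the
#' raw read error rate, and two recurrent error hotspots at 1 percent placed
#' deterministically at a quarter and three quarters of the panel, with the
#' alphabetically first non-reference base as the recurrent alternative.
#'
#' @param panel A `umivar_panel` used to place hotspots.
#' @param n_hotspots Number of hotspot positions.
#' @param hotspot_rate Per-molecule mismatch rate at a hotspot.
#' @inheritParams error_profile
#' @return A `umivar_error_profile`.
#' @export
default_error_profile <- function(panel, n_hotspots = 2L, hotspot_rate = 0.01,
                                  seq_error = 1e-3, pre_umi_damage = 1e-5,
                                  umi_error = 1e-3) {
  L <- panel_size(panel)
  hs <- NULL
  if (n_hotspots > 0L) {
    sites <- unique(pmax(1L, pmin(L, round(L * seq_len(n_hotspots) /
                                             (n_hotspots + 1L)))))
    hs <- data.table(site = as.integer(sites),
                     alt = vapply(panel$ref[sites],
                                  function(r) BASES[BASES != r][1L],
                                  character(1)),
                     rate = hotspot_rate)
  }
  error_profile(seq_error = seq_error, pre_umi_damage = pre_umi_damage,
                umi_error = umi_error, hotspots = hs)
}

#' Consensus miscall probability by family size
#'
#' Probability that a quality-weighted majority vote over `m` replicate reads
#' of one molecule emits a wrong (non-truth) base, when every read carries the
#' same per-base substitution probability `seq_error` and a constant base
#' quality. Computed by exact enumeration of the multinomial read-count
#' configurations: the consensus is wrong when a single alternative base
#' strictly outnumbers the truth base (ties yield `N`, which is dropped from
#' pileups rather than miscounted).
#'
#' @param seq_error Per-read, per-base substitution probability.
#' @param m Integer vector of family sizes.
#' @return Numeric vector: miscall probability for each `m`.
#' @export
#' @examples
#' consensus_error_by_size(1e-3, c(1, 3, 5))
consensus_error_by_size <- function(seq_error, m) {
  stop_if_not_prob(seq_error, "seq_error")
  vapply(as.integer(m), function(mi) {
    if (mi < 1L) stop("family size must be >= 1", call. = FALSE)
    p_wrong <- 0
    for (ne in seq_len(mi)) {          # ne = number of errored reads
      w_ne <- dbinom(ne, mi, seq_error)
      correct <- mi - ne
      # allocate ne errors over 3 alternative bases, uniformly
      for (a in 0:ne) for (b in 0:(ne - a)) {
        cc <- ne - a - b
        top <- max(a, b, cc)
        if (top <= correct) next                   # truth wins or ties
        if (sum(c(a, b, cc) == top) > 1L) next     # tie among alts -> N
        w_alloc <- exp(lgamma(ne + 1) - lgamma(a + 1) - lgamma(b + 1) -
                         lgamma(cc + 1) - ne * log(3))
        p_wrong <- p_wrong + w_ne * w_alloc
      }
    }
    p_wrong
  }, numeric(1))
}

#' Post-consensus residual error rate under a family-size distribution
#'
#' Expected consensus miscall probability per retained molecule, averaging
#' [consensus_error_by_size()] over a negative-binomial family-size
#' distribution truncated at 1 and conditioned on passing the minimum
#' family-size filter. This links the read-level simulator (which applies raw
#' read errors and votes) to the consensus-count simulator (which draws
#' collapsed pileup counts directly).
#'
#' @inheritParams consensus_error_by_size
#' @param family_size_mean,family_size_dispersion Mean and dispersion (the
#'   negative-binomial `size` parameter) of the replicate-count distribution.
#' @param min_reads Minimum family size retained by consensus filtering.
#' @return A single probability.
#' @export
consensus_error_rate <- function(seq_error, family_size_mean = 4,
                                 family_size_dispersion = 2, min_reads = 3L) {
  stopifnot(family_size_mean > 0, family_size_dispersion > 0, min_reads >= 1L)
  m_max <- max(qnbinom(1 - 1e-9, mu = family_size_mean,
                       size = family_size_dispersion), min_reads) + 1L
  m <- seq.int(min_reads, m_max)
  w <- dnbinom(m, mu = family_size_mean, size = family_size_dispersion)
  # truncated at >= 1, conditioned on >= min_reads
  w <- w / sum(dnbinom(seq.int(min_reads, m_max), mu = family_size_mean,
                       size = family_size_dispersion))
  sum(w * consensus_error_by_size(seq_error, m))
}
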