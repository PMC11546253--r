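#' Filter candidate variants against the matched PBMC sample
#'
#' Removes germline SNPs and clonal hematopoiesis (CHIP) variants using the
#' patient's PBMC data under one of two depth regimes:
#' \describe{
#'   \item{wes}{WES-like PBMC: remove candidates with PBMC coverage below 10
#'     or PBMC VAF above 10 percent.}
#'   \item{deep}{deep UMI-collapsed PBMC: remove candidates with PBMC
#'     coverage below 1000 or PBMC VAF above 0.1 percent.}
#' }
#' Comparisons are strict, exactly as stated: coverage "less than" the
#' minimum, VAF "larger than" the maximum. A candidate site missing from the
#' PBMC pileup counts as coverage 0 and is removed.
#'
#' @param variants A statistics table from [call_variants()].
#' @param pbmc The patient's PBMC `umivar_pileup`.
#' @param regime `"deep"` or `"wes"`.
#' @param min_coverage,max_vaf Optional overrides of the regime thresholds.
#' @return A list: `kept` (surviving rows) and `removed` (rows with a `rule`
#'   column naming the rule that fired: `"coverage"` or `"vaf"`).
#' @export
filter_by_pbmc <- function(variants, pbmc, regime = c("deep", "wes"),
                           min_coverage = NULL, max_vaf = NULL) {
  regime <- match.arg(regime)
  min_coverage <- min_coverage %||% switch(regime, wes = 10, deep = 1000)
  max_vaf <- max_vaf %||% switch(regime, wes = 0.10, deep = 0.001)
  v <- as.data.table(variants)
  in_panel <- v$site >= 1L & v$site <= nrow(pbmc)
  cov <- rep(0, nrow(v)); pvaf <- rep(0, nrow(v))
  if (any(in_panel)) {
    cnt <- pileup_counts(pbmc, v$site[in_panel], v$alt[in_panel])
    cov[in_panel] <- cnt$n_fwd + cnt$n_rev
    pvaf[in_panel] <- ifelse(cov[in_panel] > 0,
                             (cnt$k_fwd + cnt$k_rev) / cov[in_panel], 0)
  }
  rule <- rep(NA_character_, nrow(v))
  rule[cov < min_coverage] <- "coverage"
  rule[is.na(rule) & pvaf > max_vaf] <- "vaf"
  removed <- copy(v[!is.na(rule)])
  if (nrow(removed)) removed[, rule := rule[!is.na(rule)]]
  else removed[, rule := character()]
  list(kept = v[is.na(rule)], removed = removed[])
}

#' Mask recurrent mismatch positions using the panel of normals
#'
#' A (site, alt) pair is masked when its VAF exceeds `vaf_threshold` in more
#' than `min_samples - 1` distinct PON samples — the recurrent-artifact filter
#' that removes position-specific error hotspots the read-feature and TLOD
#' callers cannot see. By default the mask is per-allele; `per_allele = FALSE`
#' masks every alternative at an offending site.
#'
#' @param variants A statistics table from [call_variants()].
#' @param pon A `umivar_pon` with per-sample pileups.
#' @param vaf_threshold VAF that counts as a recurrent mismatch (strictly
#'   exceeded).
#' @param min_samples Minimum number of PON samples exceeding the threshold
#'   for the mask to fire (default 2: "more than one sample").
#' @param per_allele Mask the (site, alt) pair (default) or the whole site.
#' @return A list: `kept`, `masked` (removed rows) and `mask` (the masked
#'   position table).
#' @export
filter_by_pon_recurrence <- function(variants, pon, vaf_threshold = 0.01,
                                     min_samples = 2L, per_allele = TRUE) {
  if (!inherits(pon, "umivar_pon") || length(pon$samples) == 0L)
    stop("a non-empty PON is required", call. = FALSE)
  v <- as.data.table(variants)
  hits <- rbindlist(lapply(pon$samples, function(p) {
    rbindlist(lapply(BASES, function(b) {
      k <- p[[paste0(b, "_fwd")]] + p[[paste0(b, "_rev")]]
      n <- p$depth
      idx <- which(p$ref != b & n > 0 & k / pmax(n, 1) > vaf_threshold)
      data.table(site = idx, alt = b)
    }))
  }))
  if (nrow(hits)) {
    mask <- hits[, .(n_samples = .N), by = .(site, alt)][n_samples >=
                                                           min_samples]
  } else {
    mask <- data.table(site = integer(), alt = character(),
                       n_samples = integer())
  }
  if (per_allele) {
    masked_idx <- v[mask, on = c("site", "alt"), which = TRUE, nomatch = NULL]
  } else {
    masked_idx <- which(v$site %in% unique(mask$site))
  }
  keep <- setdiff(seq_len(nrow(v)), masked_idx)
  list(kept = v[keep], masked = v[masked_idx], mask = mask[])
}
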