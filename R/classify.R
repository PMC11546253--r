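#' Fisher's method for combining p-values
#'
#' `X = -2 sum(log p)` referred to a chi-square with `2m` degrees of freedom.
#' P-values are floored at 1e-300 so the combined statistic stays finite.
#'
#' @param p Vector of p-values.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' fisher_method(c(0.05, 0.05))
fisher_method <- function(p) {
  if (length(p) == 0L) stop("no p-values to combine", call. = FALSE)
  stop_if_not_prob(p, "p")
  p <- pmax(p, 1e-300)
  x <- -2 * sum(log(p))
  list(statistic = x, df = 2L * length(p),
       p_value = pchisq(x, df = 2L * length(p), lower.tail = FALSE))
}

#' Combine the statistics of a sample's tumor-informed variants
#'
#' One scalar cancer-likeness score per sample from the statistics of its
#' informed variant list: TLODs are averaged; Bayes factors are multiplied
#' (accumulated in log space and reported as `-log10` of the product, so
#' higher = more cancer-like); p-values are combined by Fisher's method and
#' reported as `-log10` of the combined p. Informed variants without
#' alternative support must already carry their caller's null value (p = 1,
#' the k = 0 Bayes factor, TLOD 0).
#'
#' @param x Statistic values of the informed variants.
#' @param kind `"tlod"`, `"bayes_factor"` or `"p_value"`.
#' @return A single oriented score (higher = more cancer-like).
#' @export
#' @examples
#' combine_statistics(c(2, 4), "tlod")
combine_statistics <- function(x, kind = c("tlod", "bayes_factor",
                                           "p_value")) {
  kind <- match.arg(kind)
  if (length(x) == 0L) stop("empty informed variant set", call. = FALSE)
  switch(kind,
    tlod = mean(x),
    bayes_factor = -sum(log10(pmax(x, 1e-300))),
    p_value = -log10(pmax(fisher_method(x)$p_value, 1e-300))
  )
}

#' Oriented score of a sample's highest-ranking variant
#'
#' The statistic of the most significant candidate: the maximum TLOD, or
#' `-log10` of the minimum p-value / posterior probability. A sample with no
#' candidates scores 0 and is flagged via attribute `"no_candidates"`.
#'
#' @param x Statistic values of the sample's candidates (may be empty).
#' @param kind `"tlod"`, `"p_value"` or `"posterior"`.
#' @return A single oriented score.
#' @export
highest_ranking <- function(x, kind = c("tlod", "p_value", "posterior")) {
  kind <- match.arg(kind)
  if (length(x) == 0L)
    return(structure(0, no_candidates = TRUE))
  if (kind == "tlod") max(x) else -log10(pmax(min(x), 1e-300))
}

#' Pair classification controls with case truth-set donors
#'
#' Healthy controls have no tumor mutation list, so each control borrows the
#' tumor-informed variant set of randomly chosen case donors, contributing
#' `multiplicity` control points (a control never borrows the same donor
#' twice). With 37 controls and multiplicity 3 this yields the canonical 111
#' case-control pairs.
#'
#' @param controls Character vector of control sample/patient ids.
#' @param cases Character vector of case ids with non-empty truth sets.
#' @param multiplicity Donors borrowed per control.
#' @param seed Integer seed (sampling is deterministic per seed).
#' @return A `data.table` with columns `control`, `donor`.
#' @export
pair_controls <- function(controls, cases, multiplicity = 3L, seed = 1L) {
  if (multiplicity > length(cases))
    stop("multiplicity exceeds the number of cases", call. = FALSE)
  with_seed(derive_seed(seed, "pairing"), {
    rbindlist(lapply(controls, function(ct)
      data.table(control = ct,
                 donor = sample(cases, multiplicity, replace = FALSE))))
  })
}

#' Statistic cutoff at a target pooled false-positive rate
#'
#' Pools filtered candidates over all samples, counts false positives (calls
#' not matching any case's tumor-informed truth), ranks them by decreasing
#' quality, and returns the quality of the FP at rank
#' `max(1, round(FP_total * rate))` (round half up). Calls are candidates
#' with quality at or above the cutoff.
#'
#' @param quality Oriented qualities of pooled candidates.
#' @param label `"TP"`/`"FP"` labels (or logical TP indicator).
#' @param rate Target FP rate (default 0.0005, i.e. 0.05 percent).
#' @param among `"fp"` (rank within false positives, default) or `"all"`
#'   (rank within all pooled candidates).
#' @return A list: `cutoff`, `rank`, `n_fp`, `zero_fp` (logical flag).
#' @export
fpr_cutoff <- function(quality, label, rate = 5e-4,
                       among = c("fp", "all")) {
  among <- match.arg(among)
  lab <- if (is.logical(label)) label else label == "TP"
  fp_q <- sort(quality[!lab], decreasing = TRUE)
  n_fp <- length(fp_q)
  if (n_fp == 0L) {
    return(list(cutoff = if (length(quality)) max(quality) else Inf,
                rank = 0L, n_fp = 0L, zero_fp = TRUE))
  }
  pool <- if (among == "fp") fp_q else sort(quality, decreasing = TRUE)
  r <- max(1L, as.integer(floor(n_fp * rate + 0.5)))
  r <- min(r, length(pool))
  list(cutoff = pool[r], rank = r, n_fp = n_fp, zero_fp = FALSE)
}

#' Tumor-agnostic per-sample scores
#'
#' Computes, per sample, the three agnostic cancer-likeness criteria:
#' \describe{
#'   \item{count}{number of candidates called at the FPR cutoff.}
#'   \item{mean_vaf}{mean VAF of the called candidates (0 when none).}
#'   \item{top}{quality of the highest-ranking candidate, ignoring the
#'     cutoff.}
#' }
#'
#' @param variants A labelled/filtered statistics table for many samples
#'   (columns `sample`, `vaf` and the supplied `quality`).
#' @param quality Oriented qualities aligned with `variants`.
#' @param cutoff Quality cutoff from [fpr_cutoff()].
#' @param samples Character vector of all sample ids to score (samples with
#'   no surviving candidates score 0 on every criterion).
#' @return A `data.table`: `sample`, `count`, `mean_vaf`, `top`.
#' @export
agnostic_scores <- function(variants, quality, cutoff, samples = NULL) {
  v <- copy(as.data.table(variants))
  v[, quality := quality]
  sc <- v[, .(count = sum(quality >= cutoff),
              mean_vaf = if (any(quality >= cutoff))
                mean(vaf[quality >= cutoff]) else 0,
              top = max(quality)), by = sample]
  if (!is.null(samples)) {
    sc <- sc[data.table(sample = samples), on = "sample"]
    sc[is.na(count), `:=`(count = 0L, mean_vaf = 0, top = 0)]
  }
  sc[]
}

#' ROC curve and area by threshold sweep
#'
#' Sweeps score thresholds over the distinct values and reports (FPR, TPR)
#' points; the trapezoidal area equals the probability that a random case
#' outscores a random control, counting ties as one half.
#'
#' @param score Oriented scores, higher = more cancer-like.
#' @param label `"case"`/`"control"` labels (or logical case indicator).
#' @return A list of class `umivar_roc`: `points` and `auc`.
#' @export
#' @examples
#' roc_curve(c(0.9, 0.8, 0.7, 0.85), c("case", "case", "control", "control"))
roc_curve <- function(score, label) {
  lab <- if (is.logical(label)) label else label == "case"
  stopifnot(length(score) == length(lab))
  if (all(lab) || !any(lab))
    stop("both cases and controls are required", call. = FALSE)
  o <- order(-score)
  s <- score[o]; lab <- lab[o]
  n_case <- sum(lab); n_ctrl <- sum(!lab)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.table(threshold = s[last],
                    fpr = fp[last] / n_ctrl, tpr = tp[last] / n_case)
  pts <- rbind(data.table(threshold = Inf, fpr = 0, tpr = 0), pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts[], auc = auc), class = "umivar_roc")
}

#' @export
print.umivar_roc <- function(x, ...) {
  cat("ROC curve:", nrow(x$points) - 1L, "thresholds, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}
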