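#' Label candidate variants against the tumor truth set
#'
#' A candidate is a true positive when its (sample, site, alt) triple matches
#' a tumor-origin truth variant of that sample's patient; every other
#' candidate — wrong allele, error call, CHIP or germline leak-through, or any
#' call in a control sample — is a false positive.
#'
#' @param variants A statistics table (optionally for several samples; the
#'   `sample` column is used when present in both inputs).
#' @param truth Tumor truth rows for the relevant sample(s): columns `site`,
#'   `alt`, plus `sample` when labelling multiple samples at once.
#' @return The input with a `label` column (`"TP"`/`"FP"`).
#' @export
label_truth <- function(variants, truth) {
  v <- copy(as.data.table(variants))
  tr <- as.data.table(truth)
  keys <- c(if ("sample" %in% names(v) && "sample" %in% names(tr)) "sample",
            "site", "alt")
  if (anyDuplicated(v[, keys, with = FALSE]))
    stop("duplicate candidates for the same (sample, site, alt)",
         call. = FALSE)
  if (nrow(tr)) {
    hit <- v[unique(tr[, keys, with = FALSE]), on = keys, which = TRUE,
             nomatch = NULL]
  } else hit <- integer()
  v[, label := "FP"]
  if (length(hit)) v[hit, label := "TP"]
  v[]
}

#' Precision-recall curve by threshold sweep
#'
#' Sweeps the candidate quality over its distinct values (ties enter and
#' leave together, making the curve deterministic) and accumulates the area
#' as `sum(precision_j * (recall_j - recall_(j-1)))` — the step-wise
#' (average-precision) integral over recall.
#'
#' @param quality Oriented significance, higher = more variant-like (see
#'   [variant_quality()]).
#' @param label `"TP"`/`"FP"` labels (or logicals).
#' @param positives Recall denominator. Defaults to the number of TP
#'   candidates (truth variants with alternative support); pass the full
#'   truth count to include variants that were undetectable or filtered out.
#' @return A list of class `umivar_pr`: `points` (threshold, recall,
#'   precision) and `auc`.
#' @export
pr_curve <- function(quality, label, positives = NULL) {
  lab <- if (is.logical(label)) label else label == "TP"
  stopifnot(length(quality) == length(lab))
  positives <- positives %||% sum(lab)
  if (positives == 0) stop("no positives: recall is undefined", call. = FALSE)
  o <- order(-quality)
  q <- quality[o]; lab <- lab[o]
  grp <- cumsum(!duplicated(q))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.table(threshold = q[last],
                    recall = tp[last] / positives,
                    precision = tp[last] / (tp[last] + fp[last]))
  auc <- sum(pts$precision * diff(c(0, pts$recall)))
  structure(list(points = pts, auc = auc), class = "umivar_pr")
}

#' @export
print.umivar_pr <- function(x, ...) {
  cat("PR curve:", nrow(x$points), "thresholds, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' VAF-stratified precision-recall analysis
#'
#' Splits true positives into the four canonical plasma-VAF strata
#' `(0, 1e-4]`, `(1e-4, 1e-3]`, `(1e-3, 1e-2]`, `(1e-2, 1]` and computes one
#' PR curve per stratum. True positives are assigned to exactly one stratum;
#' false positives are by default shared across all strata (`fp_mode =
#' "all"`), since an error call competes with true variants of every
#' frequency; `fp_mode = "matched"` instead places each FP in the stratum of
#' its own measured VAF.
#'
#' Strata can be formed from the measured VAF (alt reads / depth, the
#' default) or — useful when the collapsed depth is too small to resolve the
#' lowest stratum — from the known target VAF of the injected truth variants
#' (`stratum_by = "target"`, requires `truth`).
#'
#' @param labeled A labelled statistics table (needs `vaf`, `label` and a
#'   quality; see `quality`).
#' @param quality Numeric vector of oriented qualities aligned with
#'   `labeled`.
#' @param breaks Stratum boundaries (half-open, closed on the right).
#' @param fp_mode `"all"` or `"matched"`.
#' @param stratum_by `"measured"` or `"target"`.
#' @param truth Truth table with `site`, `alt`, `vaf` (and `sample` when
#'   present in `labeled`); needed for `stratum_by = "target"` or for
#'   `positives = "all"`.
#' @param positives `"detected"` (TPs in the labelled set) or `"all"` (every
#'   truth variant in the stratum, detectable or not).
#' @return A named list of `umivar_pr` objects (one per stratum; `NULL` where
#'   a stratum holds no positives).
#' @export
stratify_by_vaf <- function(labeled, quality,
                            breaks = c(0, 1e-4, 1e-3, 1e-2, 1),
                            fp_mode = c("all", "matched"),
                            stratum_by = c("measured", "target"),
                            truth = NULL,
                            positives = c("detected", "all")) {
  fp_mode <- match.arg(fp_mode)
  stratum_by <- match.arg(stratum_by)
  positives <- match.arg(positives)
  v <- copy(as.data.table(labeled))
  stopifnot(nrow(v) == length(quality))
  v[, quality := quality]
  if (any(v$vaf == 0 & v$label == "TP"))
    v <- v[!(vaf == 0 & label == "TP")]   # open lower bound: vaf 0 excluded
  stratum_of <- function(x) cut(x, breaks = breaks, labels = FALSE)

  if (stratum_by == "target" || positives == "all") {
    if (is.null(truth)) stop("truth table required", call. = FALSE)
    tr <- as.data.table(truth)
    keys <- c(if ("sample" %in% names(v) && "sample" %in% names(tr)) "sample",
              "site", "alt")
  }
  if (stratum_by == "measured") {
    v[, stratum := stratum_of(vaf)]
  } else {
    v[, stratum := NA_integer_]
    tv <- tr[, c(keys, "vaf"), with = FALSE]
    setnames(tv, "vaf", "target_vaf")
    v <- tv[v, on = keys]
    v[label == "TP", stratum := stratum_of(target_vaf)]
    v[label == "FP", stratum := stratum_of(vaf)]
  }

  labels <- sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1L])
  out <- setNames(vector("list", length(labels)), labels)
  for (s in seq_along(labels)) {
    tp_s <- v[label == "TP" & stratum == s]
    fp_s <- if (fp_mode == "all") v[label == "FP"]
            else v[label == "FP" & stratum == s]
    sub <- rbindlist(list(tp_s, fp_s), fill = TRUE)
    npos <- if (positives == "detected") nrow(tp_s)
            else sum(stratum_of(tr$vaf) == s, na.rm = TRUE)
    if (npos == 0 || nrow(sub) == 0) next
    out[[s]] <- pr_curve(sub$quality, sub$label, positives = npos)
  }
  out
}
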