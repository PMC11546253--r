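#' Variant call quality of a caller statistic
#'
#' The common orientation used for ranking, FPR cutoffs and depth
#' diagnostics: `-log10` of a p-value or posterior probability, the TLOD as
#' is. Exact zeros are capped at `cap` so qualities stay finite (the cap is
#' recorded in attribute `"capped"`).
#'
#' @param statistic Statistic values.
#' @param kind `"p_value"`, `"posterior"` or `"tlod"` (scalar or vector).
#' @param cap Maximum quality assigned to a zero p-value/posterior.
#' @return Numeric qualities, higher = more likely to be called.
#' @export
#' @examples
#' variant_quality(0.01, "p_value")
variant_quality <- function(statistic, kind, cap = 100) {
  kind <- rep_len(kind, length(statistic))
  q <- numeric(length(statistic))
  is_log <- kind %in% c("p_value", "posterior")
  capped <- is_log & statistic <= 10^(-cap)
  q[is_log] <- -log10(pmax(statistic[is_log], 10^(-cap)))
  q[!is_log] <- statistic[!is_log]
  structure(q, capped = sum(capped))
}

#' Depth-binned quality quantiles
#'
#' Groups position-allele records into `n_bins` equal-count depth bins and
#' reports the upper empirical quantiles (default 99 and 99.5 percent,
#' type-7 estimator) of the variant call qualities per bin — the diagnostic
#' that exposes sequencing depth as a confounder of call quality.
#'
#' @param depth Per-record depths.
#' @param quality Per-record qualities.
#' @param n_bins Number of depth bins.
#' @param probs Quantile levels to report.
#' @return A `data.table`: `bin`, `depth_min`, `depth_max`, `n`, one column
#'   per quantile (`q99`, `q99.5`, ...).
#' @export
bin_by_depth <- function(depth, quality, n_bins = 20L,
                         probs = c(0.99, 0.995)) {
  stopifnot(length(depth) == length(quality))
  if (length(depth) < n_bins)
    stop("fewer records than bins", call. = FALSE)
  o <- order(depth)
  bin <- ceiling(seq_along(o) / (length(o) / n_bins))
  d <- data.table(depth = depth[o], quality = quality[o],
                  bin = pmin(as.integer(bin), n_bins))
  out <- d[, c(.(depth_min = min(depth), depth_max = max(depth), n = .N),
               setNames(as.list(quantile(quality, probs, type = 7,
                                         names = FALSE)),
                        paste0("q", probs * 100))),
           by = bin]
  setorder(out, bin)
  out[]
}

#' Downsample a sample to a target mean depth
#'
#' Binomial thinning with retention probability `target_mean / current_mean`:
#' for a pileup every count cell is thinned independently; for a consensus
#' observation or read-family table rows are retained independently. Used to
#' equalise mean depths between cases and controls before comparing variant
#' qualities across samples.
#'
#' @param x A `umivar_pileup`, or an observation table.
#' @param target_mean Target mean depth; must not exceed the current mean.
#' @param seed Integer seed (deterministic thinning).
#' @return Thinned object of the same shape.
#' @export
downsample_to_mean_depth <- function(x, target_mean, seed = 1L) {
  if (inherits(x, "umivar_pileup")) {
    cur <- mean(x$depth)
    if (target_mean > cur)
      stop("target mean exceeds the current mean depth", call. = FALSE)
    p <- target_mean / cur
    out <- copy(as.data.table(x))
    with_seed(derive_seed(seed, "downsample"), {
      for (b in BASES) for (s in c("_fwd", "_rev")) {
        cl <- paste0(b, s)
        out[, (cl) := rbinom(.N, out[[cl]], p)]
      }
    })
    fwd <- as.matrix(out[, paste0(BASES, "_fwd"), with = FALSE])
    rv <- as.matrix(out[, paste0(BASES, "_rev"), with = FALSE])
    out[, depth_fwd := rowSums(fwd)][, depth_rev := rowSums(rv)]
    out[, depth := depth_fwd + depth_rev]
    setattr(out, "class", class(x))
    return(out[])
  }
  obs <- as.data.table(x)
  site_depth <- obs[, .N, by = site]
  cur <- mean(site_depth$N)
  if (target_mean > cur)
    stop("target mean exceeds the current mean depth", call. = FALSE)
  p <- target_mean / cur
  with_seed(derive_seed(seed, "downsample"),
            obs[runif(nrow(obs)) < p])
}
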