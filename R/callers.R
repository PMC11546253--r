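#' Log marginal likelihood of counts under a beta-binomial
#'
#' `log C(n,k) B(k + alpha, n - k + beta) / B(alpha, beta)`: the marginal
#' probability of `k` alternative reads out of `n` when the per-molecule
#' error/variant fraction has a Beta(alpha, beta) prior. This is the building
#' block of the position-wise beta-binomial caller, where the prior
#' pseudo-counts come from pooled panel-of-normals counts.
#'
#' @param k,n Alt count and depth (vectors, `0 <= k <= n`).
#' @param alpha,beta Positive pseudo-counts.
#' @return Log probabilities.
#' @export
#' @examples
#' exp(betabin_log_marginal(0, 1, 1, 1))  # 0.5
betabin_log_marginal <- function(k, n, alpha, beta) {
  if (any(k < 0) || any(n < 0) || any(k > n))
    stop("need 0 <= k <= n", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive", call. = FALSE)
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

#' Strand-aware beta-binomial Bayes factor against a PON error model
#'
#' The null model holds that alternative reads on each strand arise from the
#' position- and allele-specific error process calibrated by the pooled panel
#' of normals (conjugate pseudo-counts `K_s + 1`, `N_s - K_s + 1` per strand
#' `s`). The variant model places a flat Beta(1, 1) prior on the variant
#' fraction: under `mode = "AND"` one shared fraction generates both strands
#' jointly (evidence on a single strand suffices), while `mode = "OR"` uses
#' independent per-strand fractions, so both strands must deviate for a small
#' Bayes factor. The Bayes factor is null over alternative: smaller values
#' favour the variant.
#'
#' @param k_fwd,n_fwd,k_rev,n_rev Sample alt counts and depths per strand
#'   (vectors).
#' @param K_fwd,N_fwd,K_rev,N_rev Pooled PON alt counts and depths per strand
#'   (the tested sample must not be part of the pool).
#' @param mode `"AND"` or `"OR"`.
#' @return Bayes factors (numeric vector); 1 when both strands have zero
#'   depth.
#' @export
shearwater_bf <- function(k_fwd, n_fwd, k_rev, n_rev,
                          K_fwd, N_fwd, K_rev, N_rev,
                          mode = c("AND", "OR")) {
  mode <- match.arg(mode)
  null_f <- betabin_log_marginal(k_fwd, n_fwd, K_fwd + 1, N_fwd - K_fwd + 1)
  null_r <- betabin_log_marginal(k_rev, n_rev, K_rev + 1, N_rev - K_rev + 1)
  if (mode == "AND") {
    alt <- lchoose(n_fwd, k_fwd) + lchoose(n_rev, k_rev) +
      lbeta(k_fwd + k_rev + 1, n_fwd + n_rev - k_fwd - k_rev + 1)
    log_bf <- null_f + null_r - alt
  } else {
    alt_f <- betabin_log_marginal(k_fwd, n_fwd, 1, 1)  # log 1/(n+1)
    alt_r <- betabin_log_marginal(k_rev, n_rev, 1, 1)
    log_bf <- (null_f - alt_f) + (null_r - alt_r)
  }
  bf <- exp(pmin(log_bf, 700))
  bf[n_fwd + n_rev == 0] <- 1
  bf
}

#' Posterior variant probability from a Bayes factor
#'
#' Under a prior probability of one half for the error-only null, the
#' posterior probability of the null is `BF / (1 + BF)`; smaller values mean
#' stronger variant evidence, matching the orientation of the Bayes factor.
#'
#' @param bf Non-negative Bayes factors.
#' @return Posterior probabilities in `[0, 1)`.
#' @export
#' @examples
#' bf_to_posterior(c(0, 1, 3))
bf_to_posterior <- function(bf) {
  if (any(bf < 0)) stop("Bayes factors must be non-negative", call. = FALSE)
  ifelse(is.infinite(bf), 1, bf / (1 + bf))
}

#' One-sided Fisher's exact test for tumor-normal alt enrichment
#'
#' The classic tumor-normal contingency test: p-value for observing at least
#' the tumor's alternative count under the hypergeometric null given both
#' samples' counts (strands pooled). Candidates with no usable table (all
#' zeros) get p = 1, mirroring the convention of assigning p = 1 to variants
#' missing from a caller's output.
#'
#' @param alt_tumor,ref_tumor,alt_normal,ref_normal Count vectors.
#' @return One-sided p-values.
#' @export
varscan_fisher <- function(alt_tumor, ref_tumor, alt_normal, ref_normal) {
  if (any(c(alt_tumor, ref_tumor, alt_normal, ref_normal) < 0))
    stop("counts must be non-negative", call. = FALSE)
  phyper(alt_tumor - 1, alt_tumor + alt_normal, ref_tumor + ref_normal,
         alt_tumor + ref_tumor, lower.tail = FALSE)
}

#' TLOD-style likelihood-ratio score
#'
#' A deliberately simplified stand-in for haplotype-caller log-odds scores:
#' each read reports the alternative with probability
#' `f (1 - e) + (1 - f) e / 3` given variant fraction `f` and per-base error
#' `e`; the score is `log10 L(f_hat) / L(0)` with `f_hat` the maximum
#' likelihood fraction on `[0, 1]`. Non-negative by construction.
#'
#' @param k,n Alt counts and depths (vectors).
#' @param e Assumed per-base error rate, in `(0, 0.75)`.
#' @return TLOD scores.
#' @export
tlod_score <- function(k, n, e) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  if (any(e <= 0) || any(e >= 0.75))
    stop("e must lie in (0, 0.75)", call. = FALSE)
  p_of <- function(f) e / 3 + f * (1 - 4 * e / 3)
  ll <- function(f, k, n) {
    p <- p_of(f)
    k * log(p) + (n - k) * log1p(-p)
  }
  f_hat <- pmin(1, pmax(0, (k / pmax(n, 1) - e / 3) / (1 - 4 * e / 3)))
  out <- (ll(f_hat, k, n) - ll(0, k, n)) / log(10)
  out[n == 0] <- 0
  pmax(out, 0)
}

#' Fit a read-feature error model on control observations
#'
#' Logistic regression of the per-observation mismatch indicator on whatever
#' feature columns are supplied (typical features: trinucleotide context,
#' alternative base, strand, read-position quartile, family-size bucket).
#' An optional `weight` column supplies aggregated counts. When the input is
#' single-class (no mismatches, or nothing but mismatches) the model falls
#' back to an intercept-only floor rate.
#'
#' @param obs A data.frame with a logical/0-1 column `mismatch`, an optional
#'   `weight` column, and one or more feature columns.
#' @param floor_rate Error rate used by the degenerate-input fallback, and the
#'   lower bound on predicted rates.
#' @return An object of class `umivar_error_model` with a `predict()` method
#'   returning per-observation error probabilities.
#' @export
fit_error_model <- function(obs, floor_rate = 1e-9) {
  obs <- as.data.table(obs)
  stopifnot("mismatch" %in% names(obs))
  w <- if ("weight" %in% names(obs)) obs$weight else rep(1, nrow(obs))
  y <- as.numeric(obs$mismatch)
  feats <- setdiff(names(obs), c("mismatch", "weight"))
  n_mis <- sum(w[y > 0.5]); n_match <- sum(w[y <= 0.5])
  if (n_mis == 0 || n_match == 0) {
    rate <- if (n_mis == 0) floor_rate else 1 - floor_rate
    return(structure(list(fit = NULL, rate = rate, features = character(),
                          floor_rate = floor_rate, fallback = TRUE),
                     class = "umivar_error_model"))
  }
  dat <- as.data.frame(obs[, c("mismatch", feats), with = FALSE])
  dat$mismatch <- y
  fit <- tryCatch(
    suppressWarnings(glm(mismatch ~ ., family = binomial(), data = dat,
                         weights = w)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(fit = NULL, rate = max(floor_rate, n_mis /
                                                   (n_mis + n_match)),
                          features = character(), floor_rate = floor_rate,
                          fallback = TRUE), class = "umivar_error_model"))
  }
  structure(list(fit = fit, rate = n_mis / (n_mis + n_match),
                 features = feats, floor_rate = floor_rate, fallback = FALSE),
            class = "umivar_error_model")
}

#' @export
predict.umivar_error_model <- function(object, newdata = NULL, ...) {
  if (object$fallback || is.null(object$fit)) {
    n <- if (is.null(newdata)) 1L else nrow(newdata)
    return(rep(object$rate, n))
  }
  p <- predict(object$fit, newdata = as.data.frame(newdata),
               type = "response")
  pmin(1 - object$floor_rate, pmax(object$floor_rate, unname(p)))
}

#' Read-wise likelihood-ratio p-value under a per-read error model
#'
#' Models each read's probability of reporting the alternative as
#' `tau (1 - eps_i) + (1 - tau) eps_i` with per-read error probabilities
#' `eps_i` from [fit_error_model()] and a variant fraction `tau` estimated by
#' maximum likelihood on `[0, 1]`. The deviance against `tau = 0` is referred
#' to a chi-square with one degree of freedom, halved because the null lies on
#' the boundary of the parameter space.
#'
#' @param is_alt Logical vector: does read i support the alternative?
#' @param eps Per-read error probabilities (recycled).
#' @return A single p-value.
#' @export
dreams_like_pvalue <- function(is_alt, eps) {
  if (length(is_alt) == 0L) stop("empty observation set", call. = FALSE)
  stop_if_not_prob(eps, "eps")
  eps <- rep_len(eps, length(is_alt))
  y <- as.logical(is_alt)
  ll <- function(tau) {
    p <- tau * (1 - eps) + (1 - tau) * eps
    sum(log(p[y])) + sum(log1p(-p[!y]))
  }
  if (!any(y)) return(1)
  opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-10)
  tau_hat <- opt$maximum
  d <- 2 * (max(opt$objective, ll(0)) - ll(0))
  if (d <= 0) 1 else 0.5 * pchisq(d, df = 1, lower.tail = FALSE)
}

#' Count-level version of the read-wise likelihood-ratio p-value
#'
#' Equivalent to [dreams_like_pvalue()] when every read at a site shares the
#' same error probability: the likelihood depends only on the alt count `k`
#' and depth `n`, and the maximiser has the closed form
#' `tau_hat = (k/n - eps) / (1 - 2 eps)` clipped to `[0, 1]`.
#'
#' @param k,n Alt counts and depths (vectors).
#' @param eps Per-observation error probability (vector).
#' @return P-values (vector).
#' @export
dreams_pvalue_counts <- function(k, n, eps) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  stop_if_not_prob(eps, "eps")
  eps <- pmin(pmax(eps, 1e-12), 0.5 - 1e-12)
  ll <- function(tau) {
    p <- tau * (1 - 2 * eps) + eps
    k * log(p) + (n - k) * log1p(-p)
  }
  tau_hat <- pmin(1, pmax(0, (k / pmax(n, 1) - eps) / (1 - 2 * eps)))
  d <- 2 * (ll(tau_hat) - ll(0))
  p <- ifelse(d <= 0 | k == 0, 1, 0.5 * pchisq(d, df = 1, lower.tail = FALSE))
  p[n == 0] <- 1
  p
}

#' Build error-model training observations from PON pileups
#'
#' Aggregates pooled PON counts into feature cells with mismatch indicators
#' and count weights — the count-level analogue of read-feature training
#' data. Cells whose pooled VAF exceeds `exclude_vaf` are excluded from
#' training: those are germline polymorphisms (or gross artifacts) carried by
#' the normal donors, not sequencing errors. The default feature is the
#' alternative base alone; at collapsed-count resolution richer features
#' (trinucleotide context, strand) leave too few error events per cell to be
#' identifiable, but can be requested for read-level or large-panel data.
#'
#' @param pon A `umivar_pon`.
#' @param panel The `umivar_panel` the pileups cover.
#' @param features Subset of `c("alt", "context", "strand")`.
#' @param exclude_vaf Pooled-VAF ceiling above which a (site, alt) cell is
#'   treated as a variant and excluded from error training.
#' @return A `data.table` with the feature columns plus `mismatch`, `weight`.
#' @export
pon_error_observations <- function(pon, panel, features = "alt",
                                   exclude_vaf = 0.01) {
  stopifnot(all(features %in% c("alt", "context", "strand")),
            length(features) >= 1L)
  pooled <- pon_pool(pon)
  ctx <- trinucleotide_context(panel)
  rows <- rbindlist(lapply(BASES, function(b) {
    alt_site <- which(panel$ref != b)
    kf <- pooled[[paste0(b, "_fwd")]][alt_site]
    kr <- pooled[[paste0(b, "_rev")]][alt_site]
    nf <- pooled$depth_fwd[alt_site]; nr <- pooled$depth_rev[alt_site]
    keep <- (kf + kr) / pmax(nf + nr, 1) <= exclude_vaf
    rbindlist(list(
      data.table(context = ctx[alt_site][keep], alt = b, strand = "fwd",
                 k = kf[keep], n = nf[keep]),
      data.table(context = ctx[alt_site][keep], alt = b, strand = "rev",
                 k = kr[keep], n = nr[keep])))
  }))
  agg <- rows[, .(k = sum(k), n = sum(n)), by = features]
  mk <- function(mis, w) {
    x <- agg[, features, with = FALSE]
    x[, mismatch := mis][, weight := w]
    x
  }
  rbindlist(list(mk(1, agg$k), mk(0, agg$n - agg$k)))[weight > 0]
}

#' Compute a per-variant calling statistic over candidate SNVs
#'
#' The driver used by the benchmarking pipeline: given a sample's consensus
#' pileup, compute the chosen statistic for each candidate (site, alt) pair.
#' By default candidates are all alternatives with at least one supporting
#' consensus read; an explicit candidate table (e.g. a tumor-informed variant
#' list) may be supplied, in which case zero-support candidates receive their
#' caller's null value (p = 1, the k = 0 Bayes factor, TLOD 0).
#'
#' @param pileup The sample's `umivar_pileup`.
#' @param caller One of `"shearwater_and"`, `"shearwater_or"`, `"fisher"`,
#'   `"tlod"`, `"dreams"`.
#' @param pon A `umivar_pon`; required for the shearwater modes and, unless
#'   overridden, to calibrate the TLOD error rate and the dreams error model.
#' @param normal The matched-normal `umivar_pileup` (required for
#'   `"fisher"`).
#' @param error_model A fitted `umivar_error_model` for `"dreams"`; fitted
#'   from the PON when omitted.
#' @param panel The panel (needed to derive sequence context for `"dreams"`;
#'   defaults to the pileup's own `contig`/`pos`/`ref` columns).
#' @param tlod_error Per-base error rate for `"tlod"`; when `NULL`, estimated
#'   as the pooled PON mismatch rate.
#' @param candidates Optional `data.table(site, alt)`.
#' @param sample_id Optional sample label carried into the output.
#' @return A `data.table` of per-candidate statistics: `sample`, `site`,
#'   `ref`, `alt`, `k`, `depth`, `vaf`, `statistic`, `kind` (one of
#'   `"p_value"`, `"posterior"`, `"tlod"`), plus `bf` for shearwater modes.
#' @export
call_variants <- function(pileup,
                          caller = c("shearwater_and", "shearwater_or",
                                     "fisher", "tlod", "dreams"),
                          pon = NULL, normal = NULL, error_model = NULL,
                          panel = NULL, tlod_error = NULL, candidates = NULL,
                          sample_id = NA_character_) {
  caller <- match.arg(caller)
  if (is.null(candidates)) candidates <- alt_supported_candidates(pileup)
  candidates <- as.data.table(candidates)[, .(site, alt)]
  if (anyDuplicated(candidates))
    stop("duplicate (site, alt) candidates", call. = FALSE)
  cnt <- pileup_counts(pileup, candidates$site, candidates$alt)
  k <- cnt$k_fwd + cnt$k_rev
  n <- cnt$n_fwd + cnt$n_rev
  out <- data.table(sample = sample_id, site = candidates$site,
                    ref = pileup$ref[candidates$site], alt = candidates$alt,
                    k = k, depth = n, vaf = ifelse(n > 0, k / n, 0))

  if (caller %in% c("shearwater_and", "shearwater_or")) {
    if (is.null(pon)) stop("shearwater modes require a PON", call. = FALSE)
    pooled <- if (inherits(pon, "umivar_pon")) pon_pool(pon) else pon
    P <- pileup_counts(pooled, candidates$site, candidates$alt)
    bf <- shearwater_bf(cnt$k_fwd, cnt$n_fwd, cnt$k_rev, cnt$n_rev,
                        P$k_fwd, P$n_fwd, P$k_rev, P$n_rev,
                        mode = if (caller == "shearwater_and") "AND" else "OR")
    out[, bf := bf][, statistic := bf_to_posterior(bf)][, kind := "posterior"]
  } else if (caller == "fisher") {
    if (is.null(normal))
      stop("the Fisher caller requires a matched normal pileup", call. = FALSE)
    Ncnt <- pileup_counts(normal, candidates$site, candidates$alt)
    alt_n <- Ncnt$k_fwd + Ncnt$k_rev
    n_n <- Ncnt$n_fwd + Ncnt$n_rev
    out[, statistic := varscan_fisher(k, n - k, alt_n, n_n - alt_n)]
    out[, kind := "p_value"]
  } else if (caller == "tlod") {
    e <- tlod_error %||% pon_mismatch_rate(pon)
    out[, statistic := tlod_score(k, n, e)][, kind := "tlod"]
  } else { # dreams
    if (is.null(error_model)) {
      if (is.null(pon))
        stop("the dreams caller needs an error model or a PON", call. = FALSE)
      pn <- panel %||% pileup_panel(pileup)
      error_model <- fit_error_model(pon_error_observations(pon, pn))
    }
    pn <- panel %||% pileup_panel(pileup)
    nd <- data.table(context = trinucleotide_context(pn)[candidates$site],
                     alt = candidates$alt)
    eps <- predict(error_model, nd)
    out[, statistic := dreams_pvalue_counts(k, n, eps)][, kind := "p_value"]
  }
  out[]
}

# estimate a global per-base mismatch rate from pooled PON counts, skipping
# likely-variant cells (pooled VAF above exclude_vaf: germline, artifacts)
pon_mismatch_rate <- function(pon, floor = 1e-6, exclude_vaf = 0.01) {
  if (is.null(pon)) return(1e-3)
  pooled <- if (inherits(pon, "umivar_pon")) pon_pool(pon) else pon
  mism <- 0
  for (b in BASES) {
    k <- pooled[[paste0(b, "_fwd")]] + pooled[[paste0(b, "_rev")]]
    use <- pooled$ref != b & k / pmax(pooled$depth, 1) <= exclude_vaf
    mism <- mism + sum(k[use])
  }
  max(floor, mism / max(1, sum(pooled$depth)))
}

# reconstruct a minimal panel view from a pileup's own columns
pileup_panel <- function(pileup) {
  p <- as.data.table(pileup)[, .(contig, pos, ref)]
  setattr(p, "class", c("umivar_panel", class(p)))
  p
}

#' Write candidate statistics as a minimal VCF
#'
#' One record per candidate with the statistic, its kind and the VAF in INFO.
#' Positions are emitted 1-based against the panel's contigs.
#'
#' @param variants A statistics table from [call_variants()].
#' @param pileup The pileup the candidates came from (for contig/pos lookup).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_variants_vcf <- function(variants, pileup, path) {
  v <- as.data.table(variants)
  hdr <- c("##fileformat=VCFv4.3",
           paste0("##contig=<ID=", unique(pileup$contig), ">"),
           "##INFO=<ID=STAT,Number=1,Type=Float,Description=\"Caller statistic\">",
           "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Statistic kind\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- v[, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tSTAT=%g;KIND=%s;VAF=%g",
                     pileup$contig[site], pileup$pos[site] + 1L, ref, alt,
                     statistic, kind, vaf)]
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @param path File path of a statistics TSV.
#' @export
write_variants_tsv <- function(variants, path) {
  fwrite(as.data.table(variants), path, sep = "\t")
  invisible(path)
}
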