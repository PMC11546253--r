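#' Assemble the panel of normals from a simulated cohort
#'
#' @param cohort A counts-level `umivar_cohort`.
#' @return A `umivar_pon` over the cohort's PON samples.
#' @export
pon_from_cohort <- function(cohort) {
  ids <- cohort$sample_table[role == "pon", sample_id]
  if (length(ids) == 0L) stop("cohort has no PON samples", call. = FALSE)
  pon_matrix(cohort$samples[ids])
}

# tumor truth rows of one patient as a candidate table
tumor_truth_of <- function(cohort, patient_id) {
  cohort$truth[patient == patient_id & origin == "tumor", .(site, alt, vaf)]
}

# kind of combination input per caller
combine_kind <- function(caller) {
  switch(caller,
         shearwater_and = , shearwater_or = "bayes_factor",
         fisher = , dreams = "p_value",
         tlod = "tlod")
}

rank_kind <- function(caller) {
  switch(caller,
         shearwater_and = , shearwater_or = "posterior",
         fisher = , dreams = "p_value",
         tlod = "tlod")
}

# statistic vector handed to combine_statistics for a stats table
combine_values <- function(stats, caller) {
  if (combine_kind(caller) == "bayes_factor") stats$bf else stats$statistic
}

#' Mutation-level benchmark of the variant callers on a cohort
#'
#' Runs the full mutation-detection evaluation on every case plasma sample:
#' candidate generation (every alternative with consensus support), per-
#' candidate statistics for each caller, PBMC filtering under the chosen
#' regime, optional PON recurrent-mismatch masking, truth labelling, and a
#' pooled precision-recall curve per caller. The recall denominator is the
#' number of tumor truth variants with at least one alternative consensus
#' read in their own plasma (i.e. detectable in principle), counted before
#' filtering.
#'
#' @param cohort A counts-level `umivar_cohort`.
#' @param callers Character vector of caller names (see [call_variants()]).
#' @param regime PBMC filtering regime, `"deep"` or `"wes"`.
#' @param pon_mask Apply [filter_by_pon_recurrence()]?
#' @param quality_cap Cap passed to [variant_quality()].
#' @return A list per caller: `labeled` (pooled labelled candidates with a
#'   `quality` column), `pr` (a `umivar_pr`), `positives` (recall
#'   denominator).
#' @export
benchmark_mutations <- function(cohort,
                                callers = c("shearwater_and",
                                            "shearwater_or", "fisher",
                                            "tlod", "dreams"),
                                regime = c("deep", "wes"), pon_mask = TRUE,
                                quality_cap = 100) {
  regime <- match.arg(regime)
  stopifnot(cohort$level == "counts")
  pon <- pon_from_cohort(cohort)
  panel <- cohort$config$panel
  emodel <- fit_error_model(pon_error_observations(pon, panel))
  tlod_e <- pon_mismatch_rate(pon)
  cases <- cohort$sample_table[role == "case_plasma"]

  # recall denominator: tumor truths with >= 1 alt read in their own plasma
  detectable <- 0L
  for (i in seq_len(nrow(cases))) {
    tt <- tumor_truth_of(cohort, cases$patient[i])
    if (!nrow(tt)) next
    cnt <- pileup_counts(cohort$samples[[cases$sample_id[i]]], tt$site, tt$alt)
    detectable <- detectable + sum(cnt$k_fwd + cnt$k_rev >= 1L)
  }

  out <- setNames(vector("list", length(callers)), callers)
  for (cl in callers) {
    pooled <- vector("list", nrow(cases))
    for (i in seq_len(nrow(cases))) {
      pid <- cases$patient[i]
      plasma <- cohort$samples[[cases$sample_id[i]]]
      # the regime decides which PBMC data exists: it serves both as the
      # Fisher caller's matched normal and as the filtering sample
      pbmc <- cohort$samples[[paste0(
        pid, if (regime == "deep") "_pbmc_deep" else "_pbmc_wes")]]
      stats <- call_variants(
        plasma, cl, pon = pon, normal = pbmc,
        error_model = emodel, panel = panel, tlod_error = tlod_e,
        sample_id = cases$sample_id[i])
      stats <- filter_by_pbmc(stats, pbmc, regime)$kept
      if (pon_mask) stats <- filter_by_pon_recurrence(stats, pon)$kept
      tt <- tumor_truth_of(cohort, pid)
      pooled[[i]] <- label_truth(stats, tt[, .(site, alt)])
    }
    lab <- rbindlist(pooled)
    lab[, quality := as.numeric(variant_quality(statistic, kind,
                                                cap = quality_cap))]
    pr <- if (detectable > 0 && nrow(lab))
      pr_curve(lab$quality, lab$label, positives = detectable) else NULL
    out[[cl]] <- list(labeled = lab[], pr = pr, positives = detectable)
  }
  out
}

#' Informed variant statistics for one plasma sample
#'
#' Evaluates a tumor-informed variant list in a plasma pileup, returning the
#' caller statistic for every informed variant whether or not it has
#' alternative support (unsupported variants take the caller's null value).
#'
#' @param pileup The plasma `umivar_pileup`.
#' @param informed A `data.table(site, alt)` truth list.
#' @inheritParams call_variants
#' @return A statistics table, one row per informed variant.
#' @export
informed_variant_stats <- function(pileup, informed, caller, pon = NULL,
                                   normal = NULL, error_model = NULL,
                                   panel = NULL, tlod_error = NULL,
                                   sample_id = NA_character_) {
  if (nrow(informed) == 0L)
    stop("empty informed variant set", call. = FALSE)
  call_variants(pileup, caller, pon = pon, normal = normal,
                error_model = error_model, panel = panel,
                tlod_error = tlod_error,
                candidates = informed[, .(site, alt)], sample_id = sample_id)
}

#' Sample-level cancer classification on a cohort
#'
#' Scores every case and control plasma sample under the tumor-informed
#' criteria (combined statistic of the informed variants; highest-ranking
#' informed variant) and the tumor-agnostic criteria (number of calls at the
#' pooled FPR cutoff; mean VAF of those calls; highest-ranking candidate),
#' then computes one ROC per criterion. Controls borrow informed variant
#' lists from randomly paired case donors, each control contributing
#' `multiplicity` points; agnostic candidates are PBMC-filtered (deep regime)
#' and PON-masked for cases and controls alike.
#'
#' @param cohort A counts-level `umivar_cohort`.
#' @param caller A caller name (see [call_variants()]).
#' @param multiplicity Donors borrowed per control.
#' @param pairing_seed Seed of the control-donor pairing.
#' @param fpr_rate Pooled FPR for the agnostic cutoff (default 0.05 percent).
#' @param pon_mask Apply the PON recurrence mask to agnostic candidates?
#' @param quality_cap Cap passed to [variant_quality()].
#' @param case_pbmc Optional named list replacing the cases' PBMC pileups
#'   (e.g. after depth downsampling) for Fisher calling and filtering.
#' @return A list: `informed` (score table and ROCs for both criteria),
#'   `agnostic` (score table, cutoff, ROCs for the three criteria).
#' @export
classify_cohort <- function(cohort, caller = "shearwater_and",
                            multiplicity = 3L, pairing_seed = 1L,
                            fpr_rate = 5e-4, pon_mask = TRUE,
                            quality_cap = 100, case_pbmc = NULL) {
  stopifnot(cohort$level == "counts")
  pon <- pon_from_cohort(cohort)
  panel <- cohort$config$panel
  emodel <- fit_error_model(pon_error_observations(pon, panel))
  tlod_e <- pon_mismatch_rate(pon)
  st <- cohort$sample_table
  cases <- st[role == "case_plasma"]
  controls <- st[role == "control_plasma"]
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("classification needs both cases and controls", call. = FALSE)

  normal_of <- function(pid, is_case) {
    id <- paste0(pid, "_pbmc_deep")
    if (is_case && !is.null(case_pbmc) && id %in% names(case_pbmc))
      case_pbmc[[id]] else cohort$samples[[id]]
  }
  stats_for <- function(sample_id, pid, is_case, candidates = NULL) {
    call_variants(cohort$samples[[sample_id]], caller, pon = pon,
                  normal = normal_of(pid, is_case), error_model = emodel,
                  panel = panel, tlod_error = tlod_e,
                  candidates = candidates, sample_id = sample_id)
  }

  # ---- tumor-informed ----
  ck <- combine_kind(caller); rk <- rank_kind(caller)
  informed_rows <- list()
  for (i in seq_len(nrow(cases))) {
    tt <- tumor_truth_of(cohort, cases$patient[i])
    if (!nrow(tt)) next
    s <- stats_for(cases$sample_id[i], cases$patient[i], TRUE,
                   candidates = tt[, .(site, alt)])
    informed_rows[[length(informed_rows) + 1L]] <- data.table(
      sample = cases$sample_id[i], label = "case",
      combined = combine_statistics(combine_values(s, caller), ck),
      top = as.numeric(highest_ranking(s$statistic, rk)))
  }
  pairing <- pair_controls(controls$patient, cases$patient, multiplicity,
                           pairing_seed)
  for (j in seq_len(nrow(pairing))) {
    ct <- pairing$control[j]; donor <- pairing$donor[j]
    tt <- tumor_truth_of(cohort, donor)
    if (!nrow(tt)) next
    s <- stats_for(paste0(ct, "_plasma"), ct, FALSE,
                   candidates = tt[, .(site, alt)])
    informed_rows[[length(informed_rows) + 1L]] <- data.table(
      sample = paste0(ct, "_plasma:", donor), label = "control",
      combined = combine_statistics(combine_values(s, caller), ck),
      top = as.numeric(highest_ranking(s$statistic, rk)))
  }
  informed <- rbindlist(informed_rows)
  informed_roc <- if (nrow(informed) &&
                      length(unique(informed$label)) == 2L) {
    list(combined = roc_curve(informed$combined, informed$label),
         top = roc_curve(informed$top, informed$label))
  } else NULL

  # ---- tumor-agnostic ----
  plasma <- rbind(cases[, .(sample_id, patient, label = "case")],
                  controls[, .(sample_id, patient, label = "control")])
  pooled <- vector("list", nrow(plasma))
  for (i in seq_len(nrow(plasma))) {
    is_case <- plasma$label[i] == "case"
    s <- stats_for(plasma$sample_id[i], plasma$patient[i], is_case)
    s <- filter_by_pbmc(s, normal_of(plasma$patient[i], is_case), "deep")$kept
    if (pon_mask) s <- filter_by_pon_recurrence(s, pon)$kept
    tt <- if (is_case) tumor_truth_of(cohort, plasma$patient[i])
          else data.table(site = integer(), alt = character())
    pooled[[i]] <- label_truth(s, tt[, .(site, alt)])
  }
  ag <- rbindlist(pooled)
  ag[, quality := as.numeric(variant_quality(statistic, kind,
                                             cap = quality_cap))]
  cut <- fpr_cutoff(ag$quality, ag$label, rate = fpr_rate)
  sc <- agnostic_scores(ag, ag$quality, cut$cutoff,
                        samples = plasma$sample_id)
  sc <- sc[plasma[, .(sample_id, label)], on = c(sample = "sample_id")]
  agnostic_roc <- list(count = roc_curve(sc$count, sc$label),
                       mean_vaf = roc_curve(sc$mean_vaf, sc$label),
                       top = roc_curve(sc$top, sc$label))

  list(informed = list(scores = informed, roc = informed_roc,
                       pairing = pairing),
       agnostic = list(scores = sc[], cutoff = cut, roc = agnostic_roc,
                       labeled = ag[]))
}

#' UMI grouping / consensus benchmark on a read-level cohort
#'
#' For each grouping method and minimum family size: collapse every UMI
#' sample of a read-level cohort to consensus pileups, score case plasma
#' candidates with the strand-aware beta-binomial caller (AND mode) against a
#' PON collapsed the same way, and report the pooled mutation-level PR-AUC
#' together with the fraction of reads retained.
#'
#' @param cohort A reads-level `umivar_cohort`.
#' @param methods Grouping methods to compare.
#' @param min_reads_values Minimum family sizes to compare.
#' @return A `data.table`: `method`, `min_reads`, `pr_auc`, `retained`,
#'   `positives`.
#' @export
umi_grouping_benchmark <- function(cohort,
                                   methods = c("unique", "percentile",
                                               "cluster", "adjacency",
                                               "directional"),
                                   min_reads_values = c(1L, 3L)) {
  stopifnot(cohort$level == "reads")
  st <- cohort$sample_table
  panel <- cohort$config$panel
  cases <- st[role == "case_plasma"]
  pon_ids <- st[role == "pon", sample_id]
  grid <- data.table(expand.grid(method = methods,
                                 min_reads = min_reads_values,
                                 stringsAsFactors = FALSE))
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m <- grid$method[g]; mr <- grid$min_reads[g]
    collapse <- function(id) pileup_from_consensus(
      umi_collapse(cohort$samples[[id]], method = m, min_reads = mr), panel)
    pon <- pon_matrix(setNames(lapply(pon_ids, collapse), pon_ids))
    pooled <- vector("list", nrow(cases))
    detectable <- 0L
    for (i in seq_len(nrow(cases))) {
      pu <- collapse(cases$sample_id[i])
      tt <- tumor_truth_of(cohort, cases$patient[i])
      cnt <- pileup_counts(pu, tt$site, tt$alt)
      detectable <- detectable + sum(cnt$k_fwd + cnt$k_rev >= 1L)
      s <- call_variants(pu, "shearwater_and", pon = pon,
                         sample_id = cases$sample_id[i])
      pooled[[i]] <- label_truth(s, tt[, .(site, alt)])
    }
    lab <- rbindlist(pooled)
    qual <- as.numeric(variant_quality(lab$statistic, lab$kind))
    auc <- if (detectable > 0 && nrow(lab))
      pr_curve(qual, lab$label, positives = detectable)$auc else NA_real_
    ret <- mean(vapply(cases$sample_id, function(id)
      retained_fraction(cohort$samples[[id]], mr, method = m), numeric(1)))
    res[[g]] <- data.table(method = m, min_reads = mr, pr_auc = auc,
                           retained = ret, positives = detectable)
  }
  rbindlist(res)
}
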