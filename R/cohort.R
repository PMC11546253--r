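#' Cohort configuration for the synthetic study
#'
#' Bundles everything the simulator needs: the panel, the error profile, the
#' number of case patients, healthy classification controls and panel-of-
#' normals (PON) donors, per-role mean collapsed depths, the tumor / CHIP /
#' germline variant composition, and the UMI library parameters.
#'
#' Defaults are the package's working scale: a 2 kb panel, 20 cases, 10
#' controls and 10 PON donors, 2,000X collapsed plasma depth, deep PBMC at
#' 3,000X, WES-like PBMC at 78X, ten tumor mutations per case with plasma VAFs
#' log-uniform on `[1e-5, 0.1]`, two CHIP-like clonal hematopoiesis variants
#' per patient (VAF 0.5-3 percent, present in both plasma and PBMC), and three
#' germline SNPs per person drawn from a shared population set (VAF 0.5 or 1).
#'
#' @param panel A `umivar_panel`.
#' @param profile A `umivar_error_profile`.
#' @param n_cases,n_controls,n_pon Cohort sizes.
#' @param depths Named list of mean collapsed molecule depths per role.
#' @param tumor_per_case Tumor mutations injected per case plasma.
#' @param tumor_vaf_range Plasma VAF range; VAFs are drawn log-uniformly.
#' @param chip_per_case,chip_per_control CHIP variants per patient.
#' @param chip_vaf_range Uniform VAF range for CHIP variants.
#' @param germline_per_patient Germline SNPs carried per person.
#' @param n_population_snps Size of the shared population SNP pool.
#' @param hom_prob Probability a carried SNP is homozygous (VAF 1 vs 0.5).
#' @param family_size_mean,family_size_dispersion Negative-binomial replicate
#'   count parameters (truncated at 1).
#' @param min_reads Minimum family size assumed retained by consensus
#'   filtering; calibrates the consensus-count error bridge.
#' @param umi_length UMI tag length in bases.
#' @param fragment_length Fragment span in panel sites for read-level output.
#' @return A list of class `umivar_cohort_config`.
#' @export
cohort_config <- function(panel = panel_preset("desk"),
                          profile = default_error_profile(panel),
                          n_cases = 20L, n_controls = 10L, n_pon = 10L,
                          depths = list(case_plasma = 2000,
                                        case_pbmc_wes = 78,
                                        case_pbmc_deep = 3000,
                                        control_plasma = 2000,
                                        control_pbmc_deep = 3000,
                                        pon = 2000),
                          tumor_per_case = 10L,
                          tumor_vaf_range = c(1e-5, 0.1),
                          chip_per_case = 2L, chip_per_control = 1L,
                          chip_vaf_range = c(0.005, 0.03),
                          germline_per_patient = 3L,
                          n_population_snps = 8L,
                          hom_prob = 0.25,
                          family_size_mean = 4,
                          family_size_dispersion = 2,
                          min_reads = 3L,
                          umi_length = 9L,
                          fragment_length = 150L) {
  validate_panel(panel)
  stopifnot(inherits(profile, "umivar_error_profile"))
  if (any(unlist(depths) <= 0)) stop("depths must be positive", call. = FALSE)
  if (any(tumor_vaf_range <= 0) || any(tumor_vaf_range > 1))
    stop("tumor VAFs must lie in (0, 1]", call. = FALSE)
  if (any(chip_vaf_range <= 0) || any(chip_vaf_range > 1))
    stop("CHIP VAFs must lie in (0, 1]", call. = FALSE)
  stopifnot(n_cases >= 0, n_controls >= 0, n_pon >= 0,
            family_size_mean > 0, family_size_dispersion > 0,
            min_reads >= 1, umi_length >= 1, fragment_length >= 1)
  structure(list(panel = panel, profile = profile,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_pon = as.integer(n_pon), depths = depths,
                 tumor_per_case = as.integer(tumor_per_case),
                 tumor_vaf_range = tumor_vaf_range,
                 chip_per_case = as.integer(chip_per_case),
                 chip_per_control = as.integer(chip_per_control),
                 chip_vaf_range = chip_vaf_range,
                 germline_per_patient = as.integer(germline_per_patient),
                 n_population_snps = as.integer(n_population_snps),
                 hom_prob = hom_prob,
                 family_size_mean = family_size_mean,
                 family_size_dispersion = family_size_dispersion,
                 min_reads = as.integer(min_reads),
                 umi_length = as.integer(umi_length),
                 fragment_length = as.integer(fragment_length)),
            class = "umivar_cohort_config")
}

patient_ids <- function(config) {
  list(cases = sprintf("case%02d", seq_len(config$n_cases)),
       controls = sprintf("control%02d", seq_len(config$n_controls)),
       pon = sprintf("pon%02d", seq_len(config$n_pon)))
}

#' Sample roster of a cohort configuration
#'
#' @param config A `umivar_cohort_config`.
#' @return `data.table` with columns `sample_id`, `patient`, `role`.
#' @export
cohort_samples <- function(config) {
  ids <- patient_ids(config)
  rbindlist(list(
    data.table(patient = ids$cases, role = "case_plasma"),
    data.table(patient = ids$cases, role = "case_pbmc_wes"),
    data.table(patient = ids$cases, role = "case_pbmc_deep"),
    data.table(patient = ids$controls, role = "control_plasma"),
    data.table(patient = ids$controls, role = "control_pbmc_deep"),
    data.table(patient = ids$pon, role = "pon")
  ))[, .(sample_id = ifelse(role == "pon", patient,
                            paste(patient, sub("^(case|control)_", "", role),
                                  sep = "_")),
         patient, role)]
}

#' Draw the mutation truth table for a cohort
#'
#' Tumor mutations are private to each case's plasma; CHIP variants are shared
#' between a patient's plasma and PBMC; germline SNPs come from a shared
#' population pool carried by cases, controls and PON donors alike. Hotspot
#' positions are excluded from variant placement so that recurrent artifacts
#' and true variants remain distinguishable by construction.
#'
#' @param config A `umivar_cohort_config`.
#' @param seed Integer seed.
#' @return `data.table` with columns `patient`, `group` (case/control/pon),
#'   `site` (1-based panel index), `alt`, `vaf`, `origin`
#'   (tumor/chip/germline).
#' @export
simulate_truth <- function(config, seed) {
  panel <- config$panel
  L <- panel_size(panel)
  ids <- patient_ids(config)
  with_seed(derive_seed(seed, "truth"), {
    blocked <- unique(config$profile$hotspots$site)
    pool <- setdiff(seq_len(L), blocked)
    snp_sites <- sort(sample(pool, min(config$n_population_snps, length(pool))))
    snp_alt <- random_alt(panel$ref[snp_sites])
    pool <- setdiff(pool, snp_sites)

    draw_patient <- function(patient, group) {
      out <- list()
      if (config$germline_per_patient > 0L && length(snp_sites) > 0L) {
        k <- min(config$germline_per_patient, length(snp_sites))
        pick <- sort(sample(seq_along(snp_sites), k))
        out$germline <- data.table(
          site = snp_sites[pick], alt = snp_alt[pick],
          vaf = ifelse(runif(k) < config$hom_prob, 1, 0.5),
          origin = "germline")
      }
      n_chip <- if (group == "case") config$chip_per_case
                else if (group == "control") config$chip_per_control else 0L
      used <- integer()
      if (n_chip > 0L) {
        s <- sample(pool, n_chip)
        used <- s
        out$chip <- data.table(
          site = s, alt = random_alt(panel$ref[s]),
          vaf = runif(n_chip, config$chip_vaf_range[1], config$chip_vaf_range[2]),
          origin = "chip")
      }
      if (group == "case" && config$tumor_per_case > 0L) {
        s <- sample(setdiff(pool, used), config$tumor_per_case)
        lo <- log(config$tumor_vaf_range[1]); hi <- log(config$tumor_vaf_range[2])
        out$tumor <- data.table(
          site = s, alt = random_alt(panel$ref[s]),
          vaf = exp(runif(config$tumor_per_case, lo, hi)),
          origin = "tumor")
      }
      if (length(out) == 0L) return(NULL)
      cbind(data.table(patient = patient, group = group), rbindlist(out))
    }

    truth <- rbindlist(c(
      list(data.table(patient = character(), group = character(),
                      site = integer(), alt = character(), vaf = numeric(),
                      origin = character())),
      lapply(ids$cases, draw_patient, group = "case"),
      lapply(ids$controls, draw_patient, group = "control"),
      lapply(ids$pon, draw_patient, group = "pon")
    ), use.names = TRUE)
    if (nrow(truth)) {
      setorder(truth, patient, site, alt)
      if (any(truth$vaf <= 0 | truth$vaf > 1))
        stop("truth VAFs must lie in (0, 1]", call. = FALSE)
    }
    truth[]
  })
}

# truth rows applicable to one sample role
truth_for_role <- function(truth, patient_id, role) {
  pt <- truth[patient == patient_id]
  if (role == "case_plasma") pt
  else if (role %in% c("case_pbmc_wes", "case_pbmc_deep"))
    pt[origin != "tumor"]
  else if (role %in% c("control_plasma", "control_pbmc_deep")) pt
  else if (role == "pon") pt[origin == "germline"]
  else stop("unknown role: ", role, call. = FALSE)
}

#' Simulate one sample's consensus pileup counts
#'
#' Draws per-site, per-strand collapsed molecule counts directly: depth is
#' Poisson around the role's mean, each molecule independently carries a given
#' alternative with probability equal to the applicable truth VAF plus the
#' per-molecule error rate (split uniformly over the three non-reference
#' bases, plus any hotspot excess). For UMI-consensus samples the per-molecule
#' error rate is `pre_umi_damage` plus the analytic residual consensus error;
#' for raw (non-UMI, WES-like) samples it is `seq_error + pre_umi_damage`.
#'
#' @param panel A `umivar_panel`.
#' @param depth Mean collapsed depth per site.
#' @param truth Truth rows applicable to this sample (columns `site`, `alt`,
#'   `vaf`); may be empty.
#' @param profile A `umivar_error_profile`.
#' @param seed Integer seed for this sample's stream.
#' @param consensus Logical; `FALSE` for raw WES-like data.
#' @param base_error Optional override of the per-molecule error rate.
#' @param family_size_mean,family_size_dispersion,min_reads Family-size model
#'   used to derive the residual consensus error when `consensus = TRUE`.
#' @return A pileup `data.table` (class `umivar_pileup`): `site`, `contig`,
#'   `pos`, `ref`, eight `<base>_<strand>` count columns, and strand / total
#'   depths.
#' @export
simulate_sample_counts <- function(panel, depth, truth, profile, seed,
                                   consensus = TRUE, base_error = NULL,
                                   family_size_mean = 4,
                                   family_size_dispersion = 2,
                                   min_reads = 3L) {
  validate_panel(panel)
  L <- panel_size(panel)
  if (!is.null(truth) && nrow(truth) && any(truth$vaf <= 0 | truth$vaf > 1))
    stop("truth VAFs must lie in (0, 1]", call. = FALSE)
  eps <- base_error %||% if (consensus) {
    profile$pre_umi_damage +
      consensus_error_rate(profile$seq_error, family_size_mean,
                           family_size_dispersion, min_reads)
  } else {
    profile$seq_error + profile$pre_umi_damage
  }

  # per-site alt probability matrix over A,C,G,T (ref column stays 0)
  p <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  for (b in BASES) p[panel$ref != b, b] <- eps / 3
  hs <- profile$hotspots
  if (nrow(hs)) p[cbind(hs$site, match(hs$alt, BASES))] <-
      p[cbind(hs$site, match(hs$alt, BASES))] + hs$rate
  if (!is.null(truth) && nrow(truth)) {
    tt <- as.data.table(truth)[, .(vaf = sum(vaf)), by = .(site, alt)]
    p[cbind(tt$site, match(tt$alt, BASES))] <-
      p[cbind(tt$site, match(tt$alt, BASES))] + tt$vaf
  }
  rs <- rowSums(p)
  scale <- pmin(1, 1 / pmax(rs, 1e-12))
  p <- p * scale

  with_seed(seed, {
    draw_strand <- function(n) {
      cnt <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
      rem_n <- n
      rem_p <- rep(1, L)
      for (b in BASES) {
        pb <- p[, b]
        cond <- ifelse(rem_p > 0, pmin(1, pb / rem_p), 0)
        k <- rbinom(L, rem_n, cond)
        cnt[, b] <- k
        rem_n <- rem_n - k
        rem_p <- rem_p - pb
      }
      cnt[cbind(seq_len(L), match(panel$ref, BASES))] <- rem_n
      cnt
    }
    n_f <- rpois(L, depth / 2)
    n_r <- rpois(L, depth / 2)
    cf <- draw_strand(n_f)
    cr <- draw_strand(n_r)
    out <- data.table(site = seq_len(L), contig = panel$contig,
                      pos = panel$pos, ref = panel$ref)
    for (b in BASES) {
      out[, (paste0(b, "_fwd")) := cf[, b]]
      out[, (paste0(b, "_rev")) := cr[, b]]
    }
    out[, depth_fwd := n_f][, depth_rev := n_r][, depth := n_f + n_r]
    setattr(out, "class", c("umivar_pileup", class(out)))
    out[]
  })
}

#' Simulate one sample's UMI-tagged read families
#'
#' The generative model: fragments of fixed span are placed uniformly over the
#' panel (clipped at the edges so expected coverage is flat), each fragment is
#' one original molecule with a strand, a true UMI tag, and per-site alleles
#' (reference, a truth variant with probability VAF, hotspot or single-strand
#' damage errors); each molecule is then observed as a negative-binomial
#' (truncated at 1) number of replicate reads, every read applying independent
#' per-base sequencing errors and per-base UMI-tag errors.
#'
#' @inheritParams simulate_sample_counts
#' @param family_size_mean,family_size_dispersion Replicate-count model.
#' @param umi_length UMI tag length.
#' @param fragment_length Fragment span in sites (clipped at panel edges).
#' @return A `data.table` (class `umivar_families`) with one row per read-site
#'   observation: `molecule_id`, `frag_start`, `frag_end`, `strand`,
#'   `true_umi`, `read_id`, `umi`, `site`, `base`, `qual`, plus the molecule's
#'   true `allele` at the site (ground truth kept for diagnostics).
#' @export
simulate_sample_reads <- function(panel, depth, truth, profile, seed,
                                  family_size_mean = 4,
                                  family_size_dispersion = 2,
                                  umi_length = 9L, fragment_length = 150L) {
  validate_panel(panel)
  L <- panel_size(panel)
  fl <- min(as.integer(fragment_length), L)
  if (!is.null(truth) && nrow(truth) && any(truth$vaf <= 0 | truth$vaf > 1))
    stop("truth VAFs must lie in (0, 1]", call. = FALSE)
  qual <- if (profile$seq_error > 0)
    min(93L, as.integer(round(-10 * log10(profile$seq_error)))) else 93L

  with_seed(seed, {
    n_frag <- rpois(1L, depth * (L + fl - 1) / fl)
    if (n_frag == 0L) n_frag <- 1L
    s0 <- sample.int(L + fl - 1L, n_frag, replace = TRUE) - (fl - 1L)
    frag_start <- pmax(1L, s0)
    frag_end <- pmin(L, s0 + fl - 1L)
    strand <- sample(c("+", "-"), n_frag, replace = TRUE)
    umi_mat <- matrix(sample(BASES, n_frag * umi_length, replace = TRUE),
                      nrow = n_frag)
    true_umi <- do.call(paste0, as.data.frame(umi_mat))

    len <- frag_end - frag_start + 1L
    mol <- data.table(molecule_id = rep(seq_len(n_frag), len),
                      site = unlist(lapply(seq_len(n_frag), function(i)
                        seq.int(frag_start[i], frag_end[i]))))
    mol[, allele := panel$ref[site]]

    apply_event <- function(sites, alts, rates) {
      for (j in seq_along(sites)) {
        idx <- which(mol$site == sites[j] & mol$allele == panel$ref[sites[j]])
        if (!length(idx)) next
        hit <- idx[runif(length(idx)) < rates[j]]
        if (length(hit)) mol[hit, allele := alts[j]]
      }
    }
    if (!is.null(truth) && nrow(truth))
      apply_event(truth$site, truth$alt, truth$vaf)
    hs <- profile$hotspots
    if (nrow(hs)) apply_event(hs$site, hs$alt, hs$rate)
    if (profile$pre_umi_damage > 0) {
      dmg <- which(runif(nrow(mol)) < profile$pre_umi_damage &
                     mol$allele == panel$ref[mol$site])
      if (length(dmg)) mol[dmg, allele := random_alt(panel$ref[site])]
    }

    # truncated-NB family sizes via inverse CDF
    p0 <- pnbinom(0, mu = family_size_mean, size = family_size_dispersion)
    fam <- qnbinom(runif(n_frag, p0, 1), mu = family_size_mean,
                   size = family_size_dispersion)
    fam <- pmax(1L, as.integer(fam))

    mol_rep <- mol[rep(seq_len(nrow(mol)), fam[mol$molecule_id])]
    mol_rep[, read_id := rowid(molecule_id, site)]
    mol_rep[, base := allele]
    err <- runif(nrow(mol_rep)) < profile$seq_error
    if (any(err)) mol_rep[err, base := random_alt(allele)]
    mol_rep[, qual := qual]

    # observed UMI per read (molecule_id x read_id)
    reads <- data.table(molecule_id = rep(seq_len(n_frag), fam),
                        read_id = sequence(fam))
    obs_mat <- umi_mat[reads$molecule_id, , drop = FALSE]
    flip <- matrix(runif(nrow(reads) * umi_length) < profile$umi_error,
                   nrow = nrow(reads))
    if (any(flip)) {
      pos <- which(flip)
      obs_mat[pos] <- vapply(obs_mat[pos],
                             function(b) BASES[BASES != b][sample.int(3L, 1L)],
                             character(1))
    }
    reads[, umi := do.call(paste0, as.data.frame(obs_mat))]

    fams <- data.table(molecule_id = mol_rep$molecule_id,
                       frag_start = frag_start[mol_rep$molecule_id],
                       frag_end = frag_end[mol_rep$molecule_id],
                       strand = strand[mol_rep$molecule_id],
                       true_umi = true_umi[mol_rep$molecule_id],
                       read_id = mol_rep$read_id,
                       site = mol_rep$site,
                       base = mol_rep$base,
                       qual = mol_rep$qual,
                       allele = mol_rep$allele)
    fams <- reads[fams, on = c("molecule_id", "read_id")]
    setcolorder(fams, c("molecule_id", "frag_start", "frag_end", "strand",
                        "true_umi", "read_id", "umi", "site", "base", "qual",
                        "allele"))
    setorder(fams, molecule_id, read_id, site)
    setattr(fams, "class", c("umivar_families", class(fams)))
    fams[]
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates every sample named by [cohort_samples()] from a single master
#' seed, each on its own derived RNG stream. `level = "counts"` (default)
#' yields collapsed consensus pileups per sample and is the scale used for the
#' evaluation studies; `level = "reads"` yields full UMI read-family tables
#' for the UMI processing studies (the WES-like PBMC role, which carries no
#' UMIs, is always emitted as a pileup).
#'
#' @param config A `umivar_cohort_config`.
#' @param seed Integer master seed; identical (config, seed) pairs give
#'   byte-identical cohorts.
#' @param level `"counts"` or `"reads"`.
#' @return A list of class `umivar_cohort`: `samples` (named list of pileups
#'   or family tables), `sample_table`, `truth`, `config`, `level`, `seed`.
#' @export
#' @examples
#' cfg <- cohort_config(panel_design(50), n_cases = 1, n_controls = 1,
#'                      n_pon = 1, tumor_per_case = 2,
#'                      depths = list(case_plasma = 50, case_pbmc_wes = 30,
#'                                    case_pbmc_deep = 60, control_plasma = 50,
#'                                    control_pbmc_deep = 60, pon = 50))
#' ch <- simulate_cohort(cfg, seed = 1)
#' names(ch$samples)[1:3]
simulate_cohort <- function(config, seed, level = c("counts", "reads")) {
  level <- match.arg(level)
  stopifnot(inherits(config, "umivar_cohort_config"))
  truth <- simulate_truth(config, seed)
  roster <- cohort_samples(config)
  samples <- vector("list", nrow(roster))
  names(samples) <- roster$sample_id
  # the residual consensus error is a property of the error profile and
  # family-size model: derive it once for the whole cohort
  eps_consensus <- config$profile$pre_umi_damage +
    consensus_error_rate(config$profile$seq_error, config$family_size_mean,
                         config$family_size_dispersion, config$min_reads)
  eps_raw <- config$profile$seq_error + config$profile$pre_umi_damage
  for (i in seq_len(nrow(roster))) {
    role <- roster$role[i]
    tr <- truth_for_role(truth, roster$patient[i], role)
    d <- config$depths[[role]]
    s <- derive_seed(seed, roster$sample_id[i])
    if (level == "reads" && role != "case_pbmc_wes") {
      samples[[i]] <- simulate_sample_reads(
        config$panel, d, tr, config$profile, s,
        family_size_mean = config$family_size_mean,
        family_size_dispersion = config$family_size_dispersion,
        umi_length = config$umi_length,
        fragment_length = config$fragment_length)
    } else {
      samples[[i]] <- simulate_sample_counts(
        config$panel, d, tr, config$profile, s,
        consensus = role != "case_pbmc_wes",
        base_error = if (role == "case_pbmc_wes") eps_raw else eps_consensus)
    }
  }
  structure(list(samples = samples, sample_table = roster, truth = truth,
                 config = config, level = level, seed = seed),
            class = "umivar_cohort")
}

#' @export
print.umivar_cohort <- function(x, ...) {
  cat("umivar synthetic cohort:", nrow(x$sample_table), "samples,",
      panel_size(x$config$panel), "panel sites, level =", x$level, "\n")
  cat("  truth variants:", nrow(x$truth), "(",
      sum(x$truth$origin == "tumor"), "tumor /",
      sum(x$truth$origin == "chip"), "CHIP /",
      sum(x$truth$origin == "germline"), "germline )\n")
  invisible(x)
}

#' Write cohort interchange files
#'
#' `write_truth_tsv()` writes the truth table; `write_families_tsv()` /
#' `read_families_tsv()` round-trip a read-family table (one row per read-site
#' observation).
#'
#' @param truth,families Tables as produced by the simulator.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  fwrite(as.data.table(truth), path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
write_families_tsv <- function(families, path) {
  fwrite(as.data.table(families), path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_families_tsv <- function(path) {
  fams <- fread(path)
  setattr(fams, "class", c("umivar_families", class(fams)))
  fams[]
}
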