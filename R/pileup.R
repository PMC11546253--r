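#' Build per-site, per-allele, per-strand pileup counts from consensus reads
#'
#' Tallies consensus observations into the wide pileup layout used by every
#' caller: one row per panel site with `<base>_<strand>` count columns.
#' Consensus `N` calls are excluded from both allele counts and depth.
#'
#' @param cons Consensus observations as from [umi_collapse()] (columns
#'   `site`, `strand`, `base`; a `qual` column is ignored here).
#' @param panel A `umivar_panel`; observations outside it are rejected.
#' @return A pileup `data.table` of class `umivar_pileup` covering every panel
#'   site (zero counts where uncovered).
#' @export
pileup_from_consensus <- function(cons, panel) {
  validate_panel(panel)
  cons <- as.data.table(cons)
  stopifnot(all(c("site", "strand", "base") %in% names(cons)))
  L <- panel_size(panel)
  if (nrow(cons) && (any(cons$site < 1L) || any(cons$site > L)))
    stop("observations outside the panel", call. = FALSE)
  if (nrow(cons) && !all(cons$base %in% c(BASES, "N")))
    stop("bases must be in {A,C,G,T,N}", call. = FALSE)
  keep <- cons[base != "N"]
  out <- data.table(site = seq_len(L), contig = panel$contig, pos = panel$pos,
                    ref = panel$ref)
  for (b in BASES) for (s in c("fwd", "rev")) {
    sym <- if (s == "fwd") "+" else "-"
    cnt <- keep[base == b & strand == sym, .N, by = site]
    col <- paste0(b, "_", s)
    out[, (col) := 0L]
    if (nrow(cnt)) out[cnt$site, (col) := cnt$N]
  }
  fwd <- as.matrix(out[, paste0(BASES, "_fwd"), with = FALSE])
  rev <- as.matrix(out[, paste0(BASES, "_rev"), with = FALSE])
  out[, depth_fwd := rowSums(fwd)][, depth_rev := rowSums(rev)]
  out[, depth := depth_fwd + depth_rev]
  setattr(out, "class", c("umivar_pileup", class(out)))
  out[]
}

# count accessors -------------------------------------------------------------

# alt counts (fwd, rev) for vectors of sites and alt bases
pileup_counts <- function(pileup, sites, alts) {
  kf <- numeric(length(sites)); kr <- numeric(length(sites))
  for (b in BASES) {
    idx <- alts == b
    if (!any(idx)) next
    kf[idx] <- pileup[[paste0(b, "_fwd")]][sites[idx]]
    kr[idx] <- pileup[[paste0(b, "_rev")]][sites[idx]]
  }
  list(k_fwd = kf, k_rev = kr,
       n_fwd = pileup$depth_fwd[sites], n_rev = pileup$depth_rev[sites])
}

#' Candidate (site, alt) pairs with alternative support in a pileup
#'
#' The benchmarking candidate set is every possible SNV at every panel
#' position where at least one alternative consensus read is seen.
#'
#' @param pileup A `umivar_pileup`.
#' @return `data.table` with columns `site`, `ref`, `alt`.
#' @export
alt_supported_candidates <- function(pileup) {
  cand <- rbindlist(lapply(BASES, function(b) {
    k <- pileup[[paste0(b, "_fwd")]] + pileup[[paste0(b, "_rev")]]
    sites <- which(k > 0 & pileup$ref != b)
    data.table(site = sites, ref = pileup$ref[sites], alt = b)
  }))
  setorder(cand, site, alt)
  cand[]
}

#' Panel of normals count matrix
#'
#' Stores the per-sample PON pileups together with their pooled per-site,
#' per-allele, per-strand sums used for beta-binomial error calibration.
#'
#' @param pileups Named list of `umivar_pileup` objects, one per PON sample.
#' @return A list of class `umivar_pon`: `samples` (the input list) and
#'   `pooled` (a summed pileup-like table).
#' @export
pon_matrix <- function(pileups) {
  stopifnot(is.list(pileups), length(pileups) >= 1L)
  pooled <- pool_pileups(pileups)
  structure(list(samples = pileups, pooled = pooled, n_samples =
                   length(pileups)), class = "umivar_pon")
}

pool_pileups <- function(pileups) {
  cols <- c(as.vector(outer(BASES, c("_fwd", "_rev"), paste0)),
            "depth_fwd", "depth_rev", "depth")
  pooled <- copy(as.data.table(pileups[[1L]]))
  for (p in pileups[-1L]) {
    for (cl in cols) pooled[, (cl) := pooled[[cl]] + p[[cl]]]
  }
  pooled
}

#' Pooled PON counts, optionally excluding one sample (leave-one-out)
#'
#' @param pon A `umivar_pon`.
#' @param exclude Optional name or index of a PON sample to leave out, used
#'   when scoring a PON sample against the remaining normals.
#' @return A pooled pileup-like `data.table`.
#' @export
pon_pool <- function(pon, exclude = NULL) {
  stopifnot(inherits(pon, "umivar_pon"))
  if (is.null(exclude)) return(pon$pooled)
  keep <- setdiff(seq_along(pon$samples),
                  if (is.character(exclude))
                    match(exclude, names(pon$samples)) else exclude)
  if (length(keep) == 0L) stop("cannot exclude every PON sample", call. = FALSE)
  pool_pileups(pon$samples[keep])
}

#' Read/write pileup tables as TSV
#'
#' @param pileup A `umivar_pileup`.
#' @param path File path.
#' @return `read_pileup_tsv()` returns a `umivar_pileup`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  fwrite(as.data.table(pileup), path, sep = "\t")
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  p <- fread(path)
  setattr(p, "class", c("umivar_pileup", class(p)))
  p[]
}
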