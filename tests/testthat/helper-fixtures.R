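library(data.table)

# tiny panel with known reference bases for hand-checked fixtures
tiny_panel <- function(n = 20L, ref = NULL) {
  panel_design(n, ref = ref %||% rep_len(c("A", "C", "G", "T"), n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

noiseless_profile <- function() {
  error_profile(seq_error = 0, pre_umi_damage = 0, umi_error = 0)
}

# hand-build a read-family table: one molecule with given reads
# reads: list of list(umi=, bases=named vector site->base, qual=)
make_family <- function(molecule_id, frag_start, frag_end, strand = "+",
                        true_umi = "AAAAAAAAA", reads) {
  rbindlist(lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    sites <- seq.int(frag_start, frag_end)
    data.table(molecule_id = molecule_id, frag_start = frag_start,
               frag_end = frag_end, strand = strand, true_umi = true_umi,
               read_id = i, umi = r$umi %||% true_umi, site = sites,
               base = rep_len(r$bases, length(sites)),
               qual = r$qual %||% 30, allele = rep_len(r$bases, length(sites)))
  }))
}

# a small counts-level cohort reused across tests (lazy, cached)
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    p <- panel_design(300)
    cfg <- cohort_config(
      p, default_error_profile(p), n_cases = 3L, n_controls = 2L, n_pon = 4L,
      depths = list(case_plasma = 400, case_pbmc_wes = 78,
                    case_pbmc_deep = 1500, control_plasma = 400,
                    control_pbmc_deep = 1500, pon = 400),
      tumor_per_case = 5L, tumor_vaf_range = c(1e-3, 0.1))
    .fixture_env$small <- simulate_cohort(cfg, seed = 20L)
  }
  .fixture_env$small
}

# uniform simple pileup builder: one row per site with given counts
manual_pileup <- function(panel, counts = list()) {
  L <- nrow(panel)
  cols <- list(site = seq_len(L), contig = panel$contig,
               pos = panel$pos, ref = panel$ref)
  for (b in c("A", "C", "G", "T")) for (s in c("fwd", "rev")) {
    cn <- paste0(b, "_", s)
    # default: 100 reference reads per strand, zero elsewhere
    cols[[cn]] <- counts[[cn]] %||% ifelse(panel$ref == b, 100L, 0L)
  }
  fwd <- do.call(cbind, cols[paste0(c("A", "C", "G", "T"), "_fwd")])
  rev <- do.call(cbind, cols[paste0(c("A", "C", "G", "T"), "_rev")])
  cols$depth_fwd <- rowSums(fwd)
  cols$depth_rev <- rowSums(rev)
  cols$depth <- cols$depth_fwd + cols$depth_rev
  out <- as.data.table(cols)
  data.table::setattr(out, "class", c("umivar_pileup", class(out)))
  out[]
}
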