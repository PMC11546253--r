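#' Hamming distance between equal-length UMI tags
#'
#' UMI networks connect tags that differ by single substitutions; for
#' fixed-length tags the relevant metric is the Hamming distance.
#'
#' @param u1,u2 Character vectors of equal-length tags (recycled pairwise).
#' @return Integer vector of distances.
#' @export
#' @examples
#' umi_distance("AAA", "AAT")
umi_distance <- function(u1, u2) {
  if (any(nchar(u1) != nchar(u2)))
    stop("UMI tags must have equal length", call. = FALSE)
  n <- max(length(u1), length(u2))
  u1 <- rep_len(u1, n); u2 <- rep_len(u2, n)
  mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, u1, u2, USE.NAMES = FALSE)
}

# pairwise Hamming distance matrix over a set of equal-length tags
umi_distance_matrix <- function(tags) {
  L <- unique(nchar(tags))
  if (length(L) != 1L) stop("UMI tags must have equal length", call. = FALSE)
  m <- matrix(unlist(lapply(tags, utf8ToInt)), nrow = L)
  n <- length(tags)
  d <- matrix(0L, n, n)
  for (p in seq_len(L)) d <- d + outer(m[p, ], m[p, ], "!=")
  d
}

#' Group UMI tags at one locus
#'
#' Partitions the observed tags of one (fragment position, strand) locus into
#' molecule groups by one of the five classic strategies:
#' \describe{
#'   \item{unique}{one group per distinct tag.}
#'   \item{percentile}{as `unique`, discarding tags whose read count is below
#'     1 percent of the mean tag count.}
#'   \item{cluster}{connected components of the Hamming-distance-1 graph.}
#'   \item{adjacency}{repeatedly seed on the unassigned tag with the highest
#'     count and claim its unassigned distance-1 neighbours.}
#'   \item{directional}{grow components from the highest-count unassigned tag
#'     along directed edges A to B present when distance is 1 and
#'     `count(A) >= 2 * count(B) - 1`, followed transitively.}
#' }
#' Ties in seeding order are broken by the lexicographically smallest tag, so
#' partitions are deterministic. The representative of a group is its
#' highest-count member (ties again lexicographic).
#'
#' @param tag_counts Named integer vector: read count per observed tag.
#' @param method One of `"unique"`, `"percentile"`, `"cluster"`,
#'   `"adjacency"`, `"directional"`.
#' @param percentile_frac Discard threshold for `percentile`, as a fraction of
#'   the mean tag count.
#' @return A `data.table` with columns `tag`, `count`, `group`,
#'   `representative`; discarded tags (percentile only) are returned in
#'   attribute `"discarded"`.
#' @export
#' @examples
#' group_umis(c(AAA = 10, AAT = 3, TTT = 5), "directional")
group_umis <- function(tag_counts,
                       method = c("unique", "percentile", "cluster",
                                  "adjacency", "directional"),
                       percentile_frac = 0.01) {
  method <- match.arg(method)
  empty <- data.table(tag = character(), count = integer(), group = integer(),
                      representative = character())
  if (length(tag_counts) == 0L) return(empty)
  if (any(tag_counts < 1)) stop("tag counts must be >= 1", call. = FALSE)
  tags <- names(tag_counts)
  if (is.null(tags) || any(is.na(tags)))
    stop("tag_counts must be a named vector", call. = FALSE)
  counts <- as.integer(tag_counts)
  ord <- order(-counts, tags)

  discarded <- character()
  if (method == "percentile") {
    keep <- counts >= percentile_frac * mean(counts)
    discarded <- tags[!keep]
    tags <- tags[keep]; counts <- counts[keep]
    ord <- order(-counts, tags)
  }
  n <- length(tags)
  grp <- integer(n)

  if (method %in% c("unique", "percentile")) {
    grp <- seq_len(n)
  } else {
    d <- umi_distance_matrix(tags)
    if (method == "cluster") {
      adj <- d == 1L
      grp <- rep(NA_integer_, n)
      g <- 0L
      for (i in ord) {
        if (!is.na(grp[i])) next
        g <- g + 1L
        frontier <- i
        while (length(frontier)) {
          grp[frontier] <- g
          nb <- which(apply(adj[, frontier, drop = FALSE], 1, any) & is.na(grp))
          frontier <- nb
        }
      }
    } else if (method == "adjacency") {
      grp <- rep(NA_integer_, n)
      g <- 0L
      for (i in ord) {
        if (!is.na(grp[i])) next
        g <- g + 1L
        grp[i] <- g
        nb <- which(d[i, ] == 1L & is.na(grp))
        grp[nb] <- g
      }
    } else { # directional
      grp <- rep(NA_integer_, n)
      g <- 0L
      for (i in ord) {
        if (!is.na(grp[i])) next
        g <- g + 1L
        frontier <- i
        grp[i] <- g
        while (length(frontier)) {
          nxt <- integer()
          for (a in frontier) {
            nb <- which(d[a, ] == 1L & is.na(grp) &
                          counts[a] >= 2L * counts - 1L)
            grp[nb] <- g
            nxt <- c(nxt, nb)
          }
          frontier <- unique(nxt)
        }
      }
    }
  }

  out <- data.table(tag = tags, count = counts, group = grp)
  out[, representative := tag[order(-count, tag)][1L], by = group]
  # renumber groups in seeding order for stable output
  lev <- unique(out$group[order(-out$count, out$tag)])
  out[, group := match(group, lev)]
  setorder(out, group, -count, tag)
  setattr(out, "discarded", discarded)
  out[]
}

#' Call a consensus read from one UMI group
#'
#' Per site, the consensus base is the base with the highest summed Phred
#' quality among the group's reads; its quality is the winning sum minus the
#' runner-up sum, capped at 93. Exact ties yield base `N` with quality 0.
#' Groups smaller than `min_reads` yield no consensus.
#'
#' @param reads A data.frame with columns `site`, `base`, `qual`; one row per
#'   read-site observation of a single UMI group.
#' @param min_reads Minimum number of reads required.
#' @return A `data.table` (`site`, `base`, `qual`, `family_size`) or `NULL`
#'   when the group is filtered out.
#' @export
#' @examples
#' r <- data.frame(site = c(1, 1, 1), base = c("A", "A", "C"), qual = 30)
#' call_consensus(r, min_reads = 1)
call_consensus <- function(reads, min_reads = 3L) {
  stopifnot(min_reads >= 1L)
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) stop("group has no reads", call. = FALSE)
  # family size = reads per site (all reads cover all of the group's sites)
  size <- reads[, .N, by = site][, max(N)]
  if (size < min_reads) return(NULL)
  cons <- consensus_votes(reads)
  cons[, family_size := size]
  cons[]
}

# vectorised quality-sum vote over (gid, site); input needs cols gid, site,
# base, qual; returns one row per (gid, site)
consensus_votes <- function(obs) {
  v <- as.data.table(obs)
  if (!"gid" %in% names(v)) v[, gid := 1L]
  s <- v[, .(qs = sum(qual)), by = .(gid, site, base)]
  setorder(s, gid, site, -qs, base)
  s[, rank := seq_len(.N), by = .(gid, site)]
  top <- s[rank <= 2L,
           .(base = base[1L],
             qual = if (.N > 1L) qs[1L] - qs[2L] else qs[1L],
             tie = .N > 1L && qs[1L] == qs[2L]),
           by = .(gid, site)]
  top[tie == TRUE, `:=`(base = "N", qual = 0)]
  top[, qual := pmin(qual, 93)]
  top[, tie := NULL]
  if (length(unique(top$gid)) == 1L && top$gid[1L] == 1L &&
      !"gid" %in% names(obs)) top[, gid := NULL]
  top[]
}

#' Collapse a sample's read families into consensus observations
#'
#' Full per-sample UMI processing: reads are grouped per (fragment start,
#' strand) locus by the chosen strategy applied to their observed UMI tags,
#' groups below `min_reads` are dropped, and a quality-sum consensus is called
#' per group and site.
#'
#' @param families A `umivar_families` table.
#' @param method Grouping strategy, see [group_umis()].
#' @param min_reads Minimum family size retained.
#' @param percentile_frac See [group_umis()].
#' @return A `data.table` of consensus observations: `locus` (fragment start),
#'   `strand`, `group_id`, `family_size`, `site`, `base`, `qual`.
#' @export
umi_collapse <- function(families, method = "directional", min_reads = 3L,
                         percentile_frac = 0.01) {
  fams <- as.data.table(families)
  stopifnot(all(c("molecule_id", "frag_start", "strand", "read_id", "umi",
                  "site", "base", "qual") %in% names(fams)))
  # one row per read
  reads <- unique(fams[, .(molecule_id, frag_start, strand, read_id, umi)])
  gid_counter <- 0L
  maps <- reads[, {
    tc <- table(umi)
    part <- group_umis(setNames(as.integer(tc), names(tc)), method,
                      percentile_frac)
    if (nrow(part) == 0L) {
      data.table(umi = character(), gid_local = integer())
    } else {
      part[, .(umi = tag, gid_local = group)]
    }
  }, by = .(frag_start, strand)]
  maps[, group_id := .GRP, by = .(frag_start, strand, gid_local)]
  reads <- maps[reads, on = c("frag_start", "strand", "umi"), nomatch = NULL]
  reads[, family_size := .N, by = group_id]
  reads <- reads[family_size >= min_reads]
  if (nrow(reads) == 0L) {
    return(data.table(locus = integer(), strand = character(),
                      group_id = integer(), family_size = integer(),
                      site = integer(), base = character(), qual = numeric()))
  }
  obs <- fams[reads[, .(molecule_id, read_id, frag_start, strand,
                        group_id, family_size)],
              on = c("molecule_id", "read_id", "frag_start", "strand"),
              nomatch = NULL]
  setnames(obs, "group_id", "gid")
  cons <- consensus_votes(obs[, .(gid, site, base, qual)])
  meta <- unique(obs[, .(gid, locus = frag_start, strand, family_size)])
  out <- meta[cons, on = "gid"]
  setnames(out, "gid", "group_id")
  setcolorder(out, c("locus", "strand", "group_id", "family_size", "site",
                     "base", "qual"))
  setorder(out, locus, strand, group_id, site)
  out[]
}

#' Fraction of reads retained by a minimum family-size filter
#'
#' Reads are grouped per locus by the chosen strategy; the retained fraction
#' is the share of reads that belong to groups of size at least `min_reads`
#' (percentile-discarded reads count as lost). Non-increasing in `min_reads`.
#'
#' @inheritParams umi_collapse
#' @return A single fraction in `[0, 1]`.
#' @export
retained_fraction <- function(families, min_reads, method = "directional",
                              percentile_frac = 0.01) {
  fams <- as.data.table(families)
  if (nrow(fams) == 0L) stop("no reads to account for", call. = FALSE)
  reads <- unique(fams[, .(molecule_id, frag_start, strand, read_id, umi)])
  total <- nrow(reads)
  maps <- reads[, {
    tc <- table(umi)
    part <- group_umis(setNames(as.integer(tc), names(tc)), method,
                      percentile_frac)
    part[, .(umi = tag, gid_local = group)]
  }, by = .(frag_start, strand)]
  reads <- maps[reads, on = c("frag_start", "strand", "umi"), nomatch = NULL]
  reads[, family_size := .N, by = .(frag_start, strand, gid_local)]
  sum(reads$family_size >= min_reads) / total
}
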