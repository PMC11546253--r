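test_that("Hamming distance handles identity, substitutions and bad input", {
  expect_identical(umi_distance("AAA", "AAA"), 0L)
  expect_identical(umi_distance("AAA", "AAT"), 1L)
  expect_identical(umi_distance("AAA", "TTA"), 2L)
  expect_identical(umi_distance(c("ACGT", "ACGT"), c("ACGA", "TGCA")),
                   c(1L, 4L))
  expect_error(umi_distance("AAA", "AAAA"), "equal length")
})

test_that("grouping strategies follow their rules on worked examples", {
  tc <- c(AAA = 10, AAT = 3, TTT = 5)
  g <- group_umis(tc, "directional")
  grp_of <- function(g, tag) g$group[g$tag == tag]
  # 10 >= 2*3-1 so AAT joins AAA; TTT is unreachable
  expect_identical(grp_of(g, "AAA"), grp_of(g, "AAT"))
  expect_false(grp_of(g, "AAA") == grp_of(g, "TTT"))
  expect_identical(g$representative[g$tag == "AAT"], "AAA")

  u <- group_umis(tc, "unique")
  expect_identical(length(unique(u$group)), 3L)

  # equal counts: directional refuses the merge (10 < 2*10-1), cluster accepts
  eq <- c(AAA = 10, AAT = 10)
  expect_identical(length(unique(group_umis(eq, "directional")$group)), 2L)
  expect_identical(length(unique(group_umis(eq, "cluster")$group)), 1L)

  # percentile discards tags below 1% of the mean count
  pc <- group_umis(c(AAA = 1000, AAT = 2), "percentile")
  expect_identical(pc$tag, "AAA")
  expect_identical(attr(pc, "discarded"), "AAT")

  expect_identical(nrow(group_umis(setNames(integer(), character()),
                                   "cluster")), 0L)
})

test_that("directional grouping is transitive through intermediate tags", {
  # AAA(100) -> AAT(40) -> ATT(15): both reachable from the seed stepwise
  g <- group_umis(c(AAA = 100, AAT = 40, ATT = 15), "directional")
  expect_identical(length(unique(g$group)), 1L)
  # but a direct 2-step neighbour without the intermediate stays separate
  g2 <- group_umis(c(AAA = 100, ATT = 15), "directional")
  expect_identical(length(unique(g2$group)), 2L)
})

# independent oracle: direct rule evaluation from a pairwise distance matrix
oracle_partition <- function(tags, counts, method) {
  n <- length(tags)
  d <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    sum(strsplit(tags[i], "")[[1]] != strsplit(tags[j], "")[[1]])))
  grp <- rep(NA_integer_, n)
  ord <- order(-counts, tags)
  g <- 0L
  if (method == "cluster") {
    for (s in ord) {
      if (!is.na(grp[s])) next
      g <- g + 1L
      comp <- s
      repeat {
        nb <- which(is.na(grp) & !(seq_len(n) %in% comp) &
                      apply(d[, comp, drop = FALSE] == 1, 1, any))
        if (!length(nb)) break
        comp <- c(comp, nb)
      }
      grp[comp] <- g
    }
  } else if (method == "adjacency") {
    for (s in ord) {
      if (!is.na(grp[s])) next
      g <- g + 1L
      grp[s] <- g
      grp[which(d[s, ] == 1 & is.na(grp))] <- g
    }
  } else if (method == "directional") {
    for (s in ord) {
      if (!is.na(grp[s])) next
      g <- g + 1L
      grp[s] <- g
      frontier <- s
      while (length(frontier)) {
        nxt <- integer()
        for (a in frontier) {
          nb <- which(d[a, ] == 1 & is.na(grp) & counts[a] >= 2 * counts - 1)
          grp[nb] <- g
          nxt <- c(nxt, nb)
        }
        frontier <- nxt
      }
    }
  }
  split(tags, grp)
}

test_that("network groupings match exhaustive rule evaluation on random loci", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    tags <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), 4,
                                             replace = TRUE), collapse = "")))
    counts <- sample(1:30, length(tags), replace = TRUE)
    names(counts) <- tags
    for (m in c("cluster", "adjacency", "directional")) {
      got <- group_umis(counts, m)
      want <- oracle_partition(tags, unname(counts), m)
      got_sets <- unname(lapply(split(got$tag, got$group), sort))
      want_sets <- unname(lapply(want, sort))
      expect_setequal(sapply(got_sets, paste, collapse = ","),
                      sapply(want_sets, paste, collapse = ","))
    }
  }
})

test_that("every partition refines the cluster components", {
  set.seed(77)
  for (rep in 1:20) {
    tags <- unique(replicate(8, paste(sample(c("A", "C"), 3, replace = TRUE),
                                      collapse = "")))
    counts <- setNames(sample(1:20, length(tags), replace = TRUE), tags)
    comp <- group_umis(counts, "cluster")
    comp_of <- setNames(comp$group, comp$tag)
    for (m in c("unique", "adjacency", "directional")) {
      g <- group_umis(counts, m)
      # no group may span two cluster components
      spans <- tapply(comp_of[g$tag], g$group, function(x) length(unique(x)))
      expect_true(all(spans == 1L))
    }
  }
})

test_that("consensus voting follows the quality-sum rule", {
  r3 <- data.frame(site = 1, base = "A", qual = 30)[rep(1, 3), ]
  cons <- call_consensus(r3, min_reads = 3)
  expect_identical(cons$base, "A")
  expect_identical(as.numeric(cons$qual), 90)

  mixed <- data.frame(site = 1, base = c("A", "A", "C"), qual = 30)
  cons2 <- call_consensus(mixed, min_reads = 1)
  expect_identical(cons2$base, "A")
  expect_identical(as.numeric(cons2$qual), 30)  # 60 - 30

  # two reads under a min size of three yield nothing
  expect_null(call_consensus(mixed[1:2, ], min_reads = 3))
  expect_error(call_consensus(mixed[0, ], min_reads = 1), "no reads")

  tie <- data.frame(site = 1, base = c("A", "C"), qual = 30)
  cons3 <- call_consensus(tie, min_reads = 1)
  expect_identical(cons3$base, "N")
  expect_identical(as.numeric(cons3$qual), 0)

  # unanimous qualities are capped at 93
  big <- data.frame(site = 1, base = "A", qual = 40)[rep(1, 5), ]
  expect_identical(as.numeric(call_consensus(big, min_reads = 1)$qual), 93)
})

test_that("retained fraction is exact on known family sizes and monotone", {
  # four molecules with distinct tags, sizes 1, 2, 3, 5 -> no tag collisions
  fams <- rbindlist(list(
    make_family(1, 1, 2, reads = rep(list(list(bases = "A")), 1),
                true_umi = "AAAAAAAAA"),
    make_family(2, 1, 2, reads = rep(list(list(bases = "A")), 2),
                true_umi = "CCCCCCCCC"),
    make_family(3, 1, 2, reads = rep(list(list(bases = "A")), 3),
                true_umi = "GGGGGGGGG"),
    make_family(4, 1, 2, reads = rep(list(list(bases = "A")), 5),
                true_umi = "TTTTTTTTT")))
  fams[, umi := true_umi]
  expect_equal(retained_fraction(fams, 3, method = "unique"), 8 / 11)
  expect_equal(retained_fraction(fams, 1, method = "unique"), 1)
  expect_equal(retained_fraction(fams, 6, method = "unique"), 0)
  fr <- vapply(1:6, function(m) retained_fraction(fams, m, "unique"),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(retained_fraction(fams[0], 1), "no reads")
})

test_that("consensus suppresses sequencing errors, more so for larger families", {
  # analytic enumeration vs Monte-Carlo vote, then monotonicity in family size
  e <- 0.02
  p_analytic <- consensus_error_by_size(e, c(1, 3, 5, 7))
  expect_equal(p_analytic[1], e, tolerance = 1e-12)
  expect_true(all(diff(p_analytic) < 0))
  expect_true(all(p_analytic[-1] < e))

  set.seed(19)
  mc_error <- function(m, reps = 4e4) {
    wrong <- 0L; called <- 0L
    bases <- c("A", "C", "G", "T")
    for (r in seq_len(reps)) {
      obs <- ifelse(runif(m) < e,
                    sample(c("C", "G", "T"), m, replace = TRUE), "A")
      tab <- table(obs)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) {
        called <- called + 1L
        if (top != "A") wrong <- wrong + 1L
      }
    }
    c(wrong = wrong, reps = reps)
  }
  mc3 <- mc_error(3)
  p3 <- p_analytic[2]
  se <- sqrt(p3 * (1 - p3) / mc3["reps"])
  expect_lt(abs(mc3["wrong"] / mc3["reps"] - p3), 3 * se + 1e-6)
})

test_that("network grouping recovers molecule counts better than unique", {
  # tag errors inflate the apparent molecule count under exact matching
  p <- panel_design(6)
  prof <- error_profile(seq_error = 0, pre_umi_damage = 0, umi_error = 0.02)
  fams <- simulate_sample_reads(p, 120, NULL, prof, seed = 13,
                                fragment_length = 3, family_size_mean = 6)
  true_n <- fams[, data.table::uniqueN(molecule_id),
                 by = .(frag_start, strand)]
  err_of <- function(method) {
    est <- fams[, {
      reads <- unique(.SD[, .(molecule_id, read_id, umi)])
      tc <- table(reads$umi)
      g <- group_umis(setNames(as.integer(tc), names(tc)), method)
      .(n_est = length(unique(g$group)))
    }, by = .(frag_start, strand)]
    merged <- merge(true_n, est, by = c("frag_start", "strand"))
    mean(abs(merged$n_est - merged$V1))
  }
  e_unique <- err_of("unique")
  for (m in c("directional", "adjacency", "cluster")) {
    expect_lt(err_of(m), e_unique)
  }
})

test_that("umi_collapse produces consensus observations consistent with truth", {
  p <- panel_design(12)
  prof <- error_profile(seq_error = 0.01, pre_umi_damage = 0, umi_error = 0)
  fams <- simulate_sample_reads(p, 60, NULL, prof, seed = 4,
                                fragment_length = 6, family_size_mean = 5)
  cons <- umi_collapse(fams, method = "unique", min_reads = 3)
  expect_true(all(cons$family_size >= 3))
  # with clean tags, groups are molecules: consensus should equal the
  # molecule allele except where voting failed
  key <- unique(fams[, .(frag_start, strand, site, allele)])
  merged <- merge(cons, key,
                  by.x = c("locus", "strand", "site"),
                  by.y = c("frag_start", "strand", "site"))
  agree <- mean(merged$base == merged$allele)
  expect_gt(agree, 0.999)
  pu <- pileup_from_consensus(cons, p)
  expect_equal(sum(pu$depth), nrow(cons[base != "N"]))
})
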