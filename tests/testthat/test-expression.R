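# transcript pools for k-mer tests: paralogs diverged from one ancestor
mk_tx <- function(n_paralogs = 3, len = 600, inter = 0.02, seed = 1) {
  set.seed(seed)
  anc <- rdna(len)
  setNames(lapply(seq_len(n_paralogs), function(i)
    mutate_seq(anc, inter)), paste0("P", seq_len(n_paralogs)))
}

test_that("a single substitution yields at most k unique positions per side", {
  set.seed(111)
  base <- rdna(400)
  ch <- strsplit(base, "")[[1]]
  ch[200] <- setdiff(c("A", "C", "G", "T"), ch[200])[1]
  tx <- list(P1 = base, P2 = paste(ch, collapse = ""))
  idx <- build_kmer_index(tx, background = character(0), k = 31)
  expect_lte(idx$unique_positions[["P1"]], 31L)
  expect_lte(idx$unique_positions[["P2"]], 31L)
  expect_gte(idx$unique_positions[["P1"]], 25L)  # interior substitution
})

test_that("identical transcripts have zero unique positions and background k-mers are purged", {
  set.seed(112)
  s <- rdna(400)
  idx <- build_kmer_index(list(P1 = s, P2 = s), background = character(0),
                          k = 31)
  expect_equal(unname(idx$unique_positions), c(0L, 0L))
  # a transcript fully contained in the background indexes nothing
  idx2 <- build_kmer_index(list(P1 = s), background = paste0(rdna(100), s),
                           k = 31)
  expect_equal(length(idx2$kmers), 0L)
  expect_gt(idx2$background_excluded, 0L)
  expect_error(build_kmer_index(list(P1 = "ACGT"), character(0), k = 31),
               "shorter than k")
  expect_error(build_kmer_index(list(P1 = s), character(0), k = 30),
               "odd")
})

test_that("well-separated paralogs keep the identity partition", {
  tx <- mk_tx(3, seed = 113)
  idx <- merge_groups(build_kmer_index(tx, character(0)), min_unique = 5)
  expect_equal(sort(names(idx$groups)), c("P1", "P2", "P3"))
  expect_true(all(idx$group_unique >= 5))
})

test_that("a near-identical pair merges into a joint group", {
  set.seed(114)
  anc <- rdna(600)
  a6 <- mutate_seq(anc, 0.02)
  tx <- list(A6 = a6, A9 = a6, B1 = mutate_seq(anc, 0.02))
  idx <- merge_groups(build_kmer_index(tx, character(0)), min_unique = 5)
  expect_true("A6/A9" %in% names(idx$groups))
  expect_true(all(idx$group_unique >= 5))
  # all-identical paralogs collapse to a single group
  tx2 <- list(X = anc, Y = anc, Z = anc)
  idx2 <- merge_groups(build_kmer_index(tx2, character(0)), min_unique = 5)
  expect_equal(length(idx2$groups), 1L)
  expect_equal(names(idx2$groups), "X/Y/Z")
})

test_that("merging is deterministic and bounded by the paralog count", {
  tx <- mk_tx(5, inter = 0.004, seed = 115)
  i1 <- merge_groups(build_kmer_index(tx, character(0)), min_unique = 5)
  i2 <- merge_groups(build_kmer_index(tx, character(0)), min_unique = 5)
  expect_identical(names(i1$groups), names(i2$groups))
  expect_gte(length(i1$groups), 1L)
})

test_that("read classification is exact on error-free reads", {
  set.seed(116)
  tx <- mk_tx(3, len = 800, seed = 116)
  idx <- merge_groups(build_kmer_index(tx, character(0)), min_unique = 5)
  rs <- simulate_reads(unlist(tx), mode = "short", read_length = 80,
                       n_reads = 400, error_rate = 0, seed = 117)
  cl <- classify_reads(rs$reads, idx)
  assigned <- !is.na(cl$assignments) & cl$assignments != "ambiguous"
  expect_gt(sum(assigned), 0L)
  member_of <- unlist(lapply(names(idx$groups), function(g)
    setNames(rep(g, length(idx$groups[[g]])), idx$groups[[g]])))
  truth_grp <- member_of[rs$truth$source]
  expect_true(all(cl$assignments[assigned] == truth_grp[assigned]))
  # non-family reads are ignored
  noise <- setNames(replicate(20, rdna(80)), paste0("x", 1:20))
  cl2 <- classify_reads(noise, idx)
  expect_equal(cl2$ignored, 20L)
})

test_that("reads with identifying k-mers from two groups are ambiguous", {
  set.seed(122)
  # construct a chimeric read carrying a k-mer unique to P1 followed by
  # a k-mer unique to P2
  base <- rdna(200)
  p1 <- base
  ch <- strsplit(base, "")[[1]]
  ch[40] <- setdiff(c("A", "C", "G", "T"), ch[40])[1]
  ch[160] <- setdiff(c("A", "C", "G", "T"), ch[160])[1]
  p2 <- paste(ch, collapse = "")
  idx <- merge_groups(build_kmer_index(list(P1 = p1, P2 = p2),
                                       character(0)), min_unique = 5)
  chimera <- paste0(substr(p1, 20, 70), substr(p2, 140, 190))
  cl <- classify_reads(setNames(chimera, "r1"), idx)
  expect_equal(unname(cl$assignments), "ambiguous")
})

test_that("recovered expression shares track simulated truth", {
  set.seed(118)
  tx <- mk_tx(3, len = 800, seed = 118)
  idx <- merge_groups(build_kmer_index(tx, character(0)), min_unique = 5)
  weights <- c(P1 = 0.6, P2 = 0.3, P3 = 0.1)
  rs <- simulate_reads(unlist(tx), weights = weights[names(tx)],
                       mode = "short", read_length = 80, n_reads = 6000,
                       error_rate = 0.005, seed = 119)
  cl <- classify_reads(rs$reads, idx)
  share <- cl$counts / sum(cl$counts)
  for (p in names(weights)) {
    expect_lte(abs(share[[p]] - weights[[p]]), 0.03)
  }
})

test_that("enrichment flags a simulated brain-enriched group", {
  set.seed(120)
  groups <- c("G1", "G2", "G3")
  tissues <- c(paste0("brain", 1:3), paste0("other", 1:32))
  rates <- matrix(100, nrow = 3, ncol = 35,
                  dimnames = list(groups, tissues))
  rates["G2", 1:3] <- 500     # 5x brain enrichment
  counts <- matrix(rpois(length(rates), rates), nrow = 3,
                   dimnames = dimnames(rates))
  e <- enrichment(counts)
  expect_true(all(e$p["G2", 1:3] < 0.05))
  expect_true(all(e$z["G2", 1:3] > 0))
  # uniform counts give near-zero z everywhere
  flat <- matrix(rpois(3 * 35, 200), nrow = 3,
                 dimnames = list(groups, tissues))
  ef <- enrichment(flat)
  expect_lt(max(abs(ef$z), na.rm = TRUE), 3.5)
})

test_that("UPGMA joins identical profiles first", {
  counts <- rbind(A = c(10, 50, 10, 50, 10, 50),
                  B = c(11, 52, 9, 49, 10, 51),
                  C = c(50, 10, 50, 10, 50, 10))
  colnames(counts) <- paste0("s", 1:6)
  e <- enrichment(counts)
  merge1 <- e$group_tree$merge[1, ]
  expect_equal(sort(e$group_tree$labels[-merge1]), c("A", "B"))
})

test_that("developmental trends detect a ramp and ignore constants", {
  set.seed(121)
  groups <- c("G1", "G2")
  info <- data.frame(sample = paste0("s", 1:12),
                     tissue = "testis",
                     timepoint = rep(1:4, each = 3))
  lam <- matrix(200, nrow = 2, ncol = 12,
                dimnames = list(groups, info$sample))
  lam["G1", ] <- 100 * rep(c(1, 2, 3, 4), each = 3)  # 4x ramp
  counts <- matrix(rpois(length(lam), lam), nrow = 2,
                   dimnames = dimnames(lam))
  prof <- developmental_profile(counts, info)
  tr <- attr(prof, "trends")
  g1 <- tr[tr$group == "G1", ]
  expect_gt(g1$rho, 0)
  expect_lt(g1$p_value, 0.05)
  # the ramped group's share profile is monotone across timepoints
  expect_true(all(diff(prof$share[prof$group == "G1"]) > 0))
})

test_that("group assignment of unambiguous reads is robust to k", {
  set.seed(123)
  tx <- mk_tx(3, len = 800, seed = 123)
  rs <- simulate_reads(unlist(tx), mode = "short", read_length = 80,
                       n_reads = 500, error_rate = 0, seed = 124)
  assign_at <- function(k) {
    idx <- merge_groups(build_kmer_index(tx, character(0), k = k),
                        min_unique = 5)
    classify_reads(rs$reads, idx)$assignments
  }
  a31 <- assign_at(31L)
  a25 <- assign_at(25L)
  both <- !is.na(a31) & !is.na(a25) &
    a31 != "ambiguous" & a25 != "ambiguous"
  expect_gt(sum(both), 0)
  expect_true(all(a31[both] == a25[both]))
})
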