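test_that("exact copies are found at exact coordinates on both strands", {
  set.seed(1)
  query <- rdna(16000)
  hap <- paste0(rdna(50000), query, rdna(50000), revcomp(query),
                rdna(50000), query, rdna(30000))
  fc <- find_copies(hap, query, contig = "h1")
  expect_equal(nrow(fc), 3L)
  expect_equal(fc$start, c(50000L, 116000L, 182000L))
  expect_equal(fc$end, c(66000L, 132000L, 198000L))
  expect_equal(fc$strand, c("+", "-", "+"))
  expect_true(all(fc$sequence == query))
})

test_that("diverged simulated copies are recovered with >= 99% overlap", {
  cfg <- tiny_config(seed = 31, n_samples = 2, igc_rate = 0)
  sim <- simulate_family(cfg)
  fc <- find_copies_all(sim$assemblies, sim$truth$ancestral,
                        min_len = 3000)
  cc <- sim$truth$copy_coordinates
  expect_equal(nrow(fc), nrow(cc))
  for (i in seq_len(nrow(cc))) {
    hit <- fc[fc$contig == cc$contig[i] &
                pmin(fc$end, cc$end[i]) - pmax(fc$start, cc$start[i]) > 0, ]
    expect_equal(nrow(hit), 1L)
    ov <- min(hit$end, cc$end[i]) - max(hit$start, cc$start[i])
    expect_gte(ov / (cc$end[i] - cc$start[i]), 0.99)
    expect_gte(ov / (hit$end - hit$start), 0.99)
    expect_equal(hit$strand, cc$strand[i])
  }
})

test_that("fragments below min_len are not reported", {
  set.seed(2)
  query <- rdna(16000)
  hap <- paste0(rdna(30000), substr(query, 1, 10000), rdna(30000))
  fc <- find_copies(hap, query)
  expect_equal(nrow(fc), 0L)
  expect_error(find_copies(rdna(1000), rdna(1000), min_len = 15000),
               "shorter than min_len")
})

test_that("locus validation requires clean flanks on both sides", {
  copies <- data.frame(
    contig = c("h1", "h1", "h2", "h2"),
    start = c(100000L, 10000L, 40000L, 72000L),
    end = c(120000L, 30000L, 70000L, 102000L),
    strand = "+", validation = "untested",
    stringsAsFactors = FALSE)
  lens <- c(h1 = 200000L, h2 = 200000L)
  v <- validate_locus(copies, lens, flank = 30000)
  expect_equal(v$validation[1], "pass")     # clean 30 kbp+ flanks
  expect_equal(v$validation[2], "fail")     # 10 kbp from contig start
  # two abutting copies fail on the shared side
  expect_equal(v$validation[3], "fail")
  expect_equal(v$validation[4], "fail")
  v2 <- validate_locus(copies, c(h2 = 200000L), flank = 30000)
  expect_equal(v2$validation[1], "untested")
})

test_that("collapse flagging is silent on clean data and fires on a collapse", {
  set.seed(3)
  copyA <- rdna(8000)
  copyB <- mutate_seq(copyA, 0.01)   # 1% diverged paralog
  # error-free reads from the correct single-copy assembly: no flags
  rsA <- simulate_reads(c(A = copyA), mode = "short", read_length = 100,
                        depth = 40, error_rate = 0, seed = 4)
  pile <- pileup_from_reads(rsA$reads, rsA$truth, 8000)
  expect_equal(nrow(flag_collapse(pile)), 0L)
  # reads from both copies mapped onto one collapsed copy: flagged
  rsB <- simulate_reads(c(A = copyA, B = copyB), mode = "short",
                        read_length = 100, depth = 40, error_rate = 0,
                        seed = 5)
  pile2 <- pileup_from_reads(rsB$reads, rsB$truth, 8000)
  flags <- flag_collapse(pile2)
  expect_gt(nrow(flags), 0L)
  expect_gt(sum(flags$end - flags$start), 1000)
  # 0.5% sequencing error at 20x stays below 1 flagged interval / 100 kbp
  rsE <- simulate_reads(c(A = copyA), mode = "short", read_length = 100,
                        depth = 20, error_rate = 0.005, seed = 6)
  pileE <- pileup_from_reads(rsE$reads, rsE$truth, 8000)
  expect_lte(nrow(flag_collapse(pileE)), 0.08)
})

test_that("read-depth copy number recovers diploid truth", {
  set.seed(8)
  copy <- rdna(5000)
  control <- rdna(10000)
  reference <- paste0(copy, control)
  control_windows <- data.frame(start = 5000L, end = 15000L)
  genome_for <- function(cn1, cn2) {
    h1 <- paste0(rdna(500), strrep(copy, cn1), control, rdna(500))
    h2 <- paste0(rdna(500), strrep(copy, cn2), control, rdna(500))
    c(h1 = h1, h2 = h2)
  }
  cn_of <- function(cn1, cn2, seed) {
    g <- genome_for(cn1, cn2)
    rs <- simulate_reads(g, mode = "short", read_length = 108, depth = 20,
                         error_rate = 0, seed = seed)
    cw <- estimate_copy_number(rs$reads, reference, control_windows,
                               window = 1000L)
    gene_copy_number(cw, 0L, 5000L)
  }
  expect_equal(cn_of(1, 1, 11), 2.0, tolerance = 0.15)
  expect_equal(cn_of(4, 2, 12), 6.0, tolerance = 0.09)
})

test_that("control-only reads give zero gene copy number", {
  set.seed(9)
  copy <- rdna(5000)
  control <- rdna(10000)
  reference <- paste0(copy, control)
  rs <- simulate_reads(c(c1 = control, c2 = control), mode = "short",
                       read_length = 108, depth = 20, error_rate = 0,
                       seed = 13)
  cw <- estimate_copy_number(rs$reads, reference,
                             data.frame(start = 5000L, end = 15000L),
                             window = 1000L)
  expect_equal(gene_copy_number(cw, 0L, 5000L), 0)
  expect_error(estimate_copy_number(rs$reads, reference,
                                    data.frame(start = 0L, end = 1000L),
                                    window = 1000L),
               "zero control depth")
})

test_that("copy-number estimates are linear in true copy number", {
  set.seed(10)
  copy <- rdna(4000)
  control <- rdna(8000)
  reference <- paste0(copy, control)
  control_windows <- data.frame(start = 4000L, end = 12000L)
  cns <- c(1, 3, 6, 10)
  est <- vapply(seq_along(cns), function(i) {
    g <- c(h1 = paste0(strrep(copy, cns[i]), control),
           h2 = paste0(strrep(copy, cns[i]), control))
    rs <- simulate_reads(g, mode = "short", read_length = 108, depth = 20,
                         error_rate = 0, seed = 20 + i)
    cw <- estimate_copy_number(rs$reads, reference, control_windows,
                               window = 1000L)
    gene_copy_number(cw, 0L, 4000L)
  }, numeric(1))
  fit <- stats::lm(est ~ I(2 * cns))
  expect_equal(unname(stats::coef(fit)[2]), 1.0, tolerance = 0.1)
})
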