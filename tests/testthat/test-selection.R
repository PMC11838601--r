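test_that("variant calling is exact on anchored haplotypes", {
  set.seed(81)
  ref <- rdna(500)
  haps <- c(h1 = ref, h2 = ref)
  expect_equal(ncol(call_variants(haps, ref)$G), 0L)
  ch <- strsplit(ref, "")[[1]]
  for (p in c(50L, 200L, 321L)) ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
  haps2 <- c(h1 = paste(ch, collapse = ""), h2 = ref)
  vm <- call_variants(haps2, ref)
  expect_equal(vm$positions, c(49L, 199L, 320L))
  expect_equal(unname(vm$G["h1", ]), rep(1L, 3))
  expect_equal(unname(vm$G["h2", ]), rep(0L, 3))
  # outgroup polarity: matches ref -> ancestral 0; matches alt -> 1
  og <- ch
  og[50] <- strsplit(ref, "")[[1]][50]
  vm2 <- call_variants(haps2, ref, outgroup = paste(og, collapse = ""))
  expect_equal(vm2$ancestral, c(0L, 1L, 1L))
  expect_error(call_variants(character(0), ref), "anchorable")
})

test_that("Tajima's D matches an independent closed-form oracle", {
  expect_true(is.na(tajimas_d(sim_coalescent_window(10, 0, seed = 1),
                              contig_length = 30000)$value))
  set.seed(82)
  for (rep in 1:150) {
    n <- sample(c(6, 10, 20), 1)
    vm <- sim_coalescent_window(n, runif(1, 2, 15),
                               sample(c("neutral", "star"), 1))
    got <- tajimas_d(vm, contig_length = 30000)$value
    want <- tajima_oracle(vm$G)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("neutral windows centre near zero and star windows are strongly negative", {
  set.seed(83)
  dn <- replicate(800, tajimas_d(sim_coalescent_window(20, 10, "neutral"),
                                 contig_length = 30000)$value)
  ds <- replicate(300, tajimas_d(sim_coalescent_window(20, 10, "star"),
                                 contig_length = 30000)$value)
  expect_gt(mean(dn, na.rm = TRUE), -0.2)
  expect_lt(mean(dn, na.rm = TRUE), 0.1)
  expect_lt(mean(ds, na.rm = TRUE), -1)
})

test_that("nS_L is positive when the ancestral background is the long one", {
  # constructed complete-sweep-like pattern: derived carriers are diverse,
  # ancestral carriers identical over a long stretch -> SL_A >> SL_D
  n <- 10
  S <- 21
  G <- matrix(0L, n, S)
  G[6:10, 11] <- 1L                      # focal site, derived 5/10
  for (k in 1:5) G[5 + k, seq(k, S, 7)] <- 1L  # derived class scrambled
  G[6:10, 11] <- 1L
  vm <- variant_matrix("c", seq(0, by = 100, length.out = S), G,
                       rep(0L, S))
  sc <- segfam:::nsl_site_scores(vm)
  focal <- sc[sc$position == 1000, ]
  expect_gt(focal$score, 0)
})

test_that("standardised scores are calibrated within frequency bins", {
  set.seed(84)
  vn <- lapply(1:120, function(i) {
    v <- sim_coalescent_window(20, 10, "neutral")
    v$contig <- paste0("w", i)
    v
  })
  res <- nsl_scan(vn)
  s <- res$sites[!is.na(res$sites$z), ]
  bins <- split(s$z, floor(s$freq * 100))
  bins <- bins[vapply(bins, length, integer(1)) >= 30]
  for (b in bins) {
    expect_lte(abs(mean(b)), 0.05)
    expect_gte(var(b), 0.9)
    expect_lte(var(b), 1.1)
  }
})

test_that("sweep windows outrank neutral windows", {
  set.seed(85)
  vn <- lapply(1:120, function(i) {
    v <- sim_coalescent_window(20, 10, "neutral"); v$contig <- paste0("n", i); v
  })
  vs <- lapply(1:120, function(i) {
    v <- sim_coalescent_window(20, 10, "sweep"); v$contig <- paste0("s", i); v
  })
  ns <- nsl_bin_stats(vn)
  res <- nsl_scan(c(vn, vs), norm_stats = ns)
  w <- res$windows
  sweep_mean <- mean(w$value[grepl("^s", w$contig)], na.rm = TRUE)
  neutral_mean <- mean(w$value[grepl("^n", w$contig)], na.rm = TRUE)
  expect_gt(sweep_mean, neutral_mean)
})

test_that("window ranking flags percentiles and gene overlap", {
  set.seed(86)
  stats_df <- data.frame(contig = "c", start = seq(0, by = 30000,
                                                   length.out = 200))
  stats_df$end <- stats_df$start + 30000
  stats_df$n_snps <- 10L
  stats_df$statistic <- "tajima_d"
  stats_df$value <- rnorm(200)
  stats_df$value[7] <- min(stats_df$value) - 1
  genes <- data.frame(contig = "c",
                      start = c(stats_df$start[3] + 25001,
                                stats_df$start[5]),
                      end = c(stats_df$start[3] + 30000 + 20000,
                              stats_df$start[5] + 30000),
                      label = c("gA", "gB"))
  rk <- rank_windows(stats_df, genes, min_overlap = 5000)
  expect_lte(rk$percentile[7], 1)
  expect_equal(rk$extreme[7], "low1")
  expect_equal(rk$genes[3], "")          # 4,999 bp overlap: not flagged
  expect_equal(rk$genes[5], "gB")
  expect_equal(rk$genes[4], "gA")        # the 20 kbp tail overlaps window 4
})

test_that("IGC exclusion shortens the left tail when IGC windows carry rare variants", {
  set.seed(87)
  mk <- function(mode, n) {
    vapply(seq_len(n), function(i)
      tajimas_d(sim_coalescent_window(20, 10, mode),
                contig_length = 30000)$value, numeric(1))
  }
  neutral <- mk("neutral", 250)
  igc_like <- mk("star", 50)   # rare-variant-loaded windows, IGC-flagged
  stats_df <- data.frame(value = c(neutral, igc_like),
                         igc_overlap = rep(c(FALSE, TRUE), c(250, 50)))
  sens <- igc_sensitivity(stats_df)
  all_p1 <- sens$p1[sens$regime == "all"]
  ex_p1 <- sens$p1[sens$regime == "igc_excluded"]
  expect_gt(ex_p1, all_p1)
  # no flagged windows: identical thresholds
  sens2 <- igc_sensitivity(data.frame(value = neutral,
                                      igc_overlap = FALSE))
  expect_equal(sens2$p1[1], sens2$p1[2])
  # everything flagged: exclusion regime undefined
  sens3 <- igc_sensitivity(data.frame(value = neutral,
                                      igc_overlap = TRUE))
  expect_true(is.na(sens3$p1[sens3$regime == "igc_excluded"]))
})
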