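test_that("PSV catalog counts disagreeing columns only", {
  s <- strrep("ACGT", 25)
  expect_equal(length(build_psv_catalog(c(P = s, Q = s))$positions), 0L)
  ch <- strsplit(s, "")[[1]]
  pos <- c(3L, 10L, 20L, 33L, 47L, 55L, 61L, 80L, 90L, 99L)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  cat2 <- build_psv_catalog(c(P = s, Q = paste(ch, collapse = "")))
  expect_equal(cat2$positions, pos - 1L)
  expect_error(build_psv_catalog(c(P = s)), "at least 2")
})

test_that("simulator PSVs are recovered exactly", {
  cfg <- tiny_config(seed = 61, n_samples = 2)
  sim <- simulate_family(cfg)
  cons <- sim$truth$paralog_consensus
  cat1 <- build_psv_catalog(cons)
  M <- do.call(rbind, strsplit(cons, ""))
  truth_pos <- which(apply(M, 2, function(x) length(unique(x)) > 1)) - 1L
  expect_equal(cat1$positions, truth_pos)
  expect_equal(rownames(cat1$alleles), names(cons))
})

test_that("a converted tract is called with its donor and support", {
  set.seed(62)
  mk <- make_paralog_copies(n_paralogs = 3, copies_per = 1, len = 4000,
                            inter = 0.02, intra = 0)
  cons <- mk$consensus
  catp <- build_psv_catalog(cons)
  # replace a tract of P1 with P3 material covering >= 8 discriminating PSVs
  disc <- catp$positions[catp$alleles["P1", ] != catp$alleles["P3", ]]
  tr_start <- disc[10]; tr_end <- disc[17] + 1L
  ch <- strsplit(cons[["P1"]], "")[[1]]
  donor_ch <- strsplit(cons[["P3"]], "")[[1]]
  ch[(tr_start + 1L):tr_end] <- donor_ch[(tr_start + 1L):tr_end]
  tracts <- detect_igc(paste(ch, collapse = ""), "P1", catp, min_run = 5)
  expect_equal(nrow(tracts), 1L)
  expect_equal(tracts$donor, "P3")
  expect_equal(tracts$n_psvs, 8L)
  expect_lte(tracts$start, tr_start)
  expect_gte(tracts$end, tr_end - 1L)
  # an unconverted copy yields nothing
  expect_equal(nrow(detect_igc(cons[["P1"]], "P1", catp)), 0L)
  # runs below min_run are not called
  ch2 <- strsplit(cons[["P1"]], "")[[1]]
  short <- disc[3:6]  # 4 consecutive discriminating PSVs
  for (p in short) ch2[p + 1L] <- donor_ch[p + 1L]
  expect_equal(nrow(detect_igc(paste(ch2, collapse = ""), "P1", catp,
                               min_run = 5)), 0L)
})

test_that("simulated IGC tracts are recovered with precision/recall >= 0.9", {
  cfg <- tiny_config(seed = 63, n_samples = 10, igc_rate = 1.2,
                     intra_diversity = 2e-4)
  sim <- simulate_family(cfg)
  catp <- build_psv_catalog(sim$truth$paralog_consensus)
  cc <- sim$truth$copy_coordinates
  cc$sequence <- unname(extract_truth_copies(sim))
  called <- detect_igc_all(cc, catp, min_run = 5)
  truth <- sim$truth$igc_events
  # only truth events with enough discriminating PSVs are detectable
  detectable <- vapply(seq_len(nrow(truth)), function(i) {
    disc <- catp$positions[
      catp$alleles[truth$acceptor[i], ] != catp$alleles[truth$donor[i], ]]
    sum(disc >= truth$start[i] & disc < truth$end[i]) >= 5
  }, logical(1))
  truth_d <- truth[detectable, , drop = FALSE]
  match_truth <- function(i) {
    any(truth_d$copy_id == called$copy_id[i] &
          truth_d$donor == called$donor[i] &
          pmin(truth_d$end, called$end[i]) -
            pmax(truth_d$start, called$start[i]) > 0)
  }
  if (nrow(called)) {
    precision <- mean(vapply(seq_len(nrow(called)), match_truth,
                             logical(1)))
    expect_gte(precision, 0.9)
  }
  recall <- mean(vapply(seq_len(nrow(truth_d)), function(i) {
    any(called$copy_id == truth_d$copy_id[i] &
          called$donor == truth_d$donor[i] &
          pmin(called$end, truth_d$end[i]) -
            pmax(called$start, truth_d$start[i]) > 0)
  }, logical(1)))
  expect_gte(recall, 0.9)
  # IGC was configured within-subfamily: no cross-subfamily calls
  called_sub <- substr(called$donor, 1, 1) == substr(called$acceptor, 1, 1)
  expect_true(all(called_sub))
})

test_that("directionality summarises ordered pairs and asymmetry", {
  tracts <- data.frame(
    donor = c("B1", "B1", "B1", "B2", "A1"),
    acceptor = c("B2", "B3", "B2", "B3", "A2"),
    stringsAsFactors = FALSE)
  d <- igc_directionality(tracts)
  expect_equal(d$pairs$n[d$pairs$donor == "B1" & d$pairs$acceptor == "B2"],
               2L)
  b1 <- d$asymmetry[d$asymmetry$paralog == "B1", ]
  expect_equal(b1$asymmetry, 1.0)        # donor only
  a2 <- d$asymmetry[d$asymmetry$paralog == "A2", ]
  expect_equal(a2$asymmetry, -1.0)       # acceptor only
  expect_equal(nrow(igc_directionality(tracts[0, ])$pairs), 0L)
})

test_that("symmetric simulated exchange stays within the binomial band", {
  set.seed(64)
  paralogs <- paste0("B", 1:4)
  n <- 200
  tracts <- data.frame(donor = character(n), acceptor = character(n),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pick <- sample(paralogs, 2)
    tracts$donor[i] <- pick[1]
    tracts$acceptor[i] <- pick[2]
  }
  d <- igc_directionality(tracts)
  expect_true(all(d$asymmetry$p_value > 0.001))
})

test_that("hotspot binning flags concentrated tracts only", {
  one_bin <- data.frame(start = rep(5100L, 8), end = rep(5400L, 8))
  h <- igc_hotspots(one_bin, bin_width = 1000)
  expect_equal(sum(h$hotspot), 1L)
  expect_equal(h$bin_start[h$hotspot], 5000L)
  set.seed(65)
  unif <- data.frame(start = sample.int(50000L, 60))
  unif$end <- unif$start + 200L
  hu <- igc_hotspots(unif, bin_width = 1000)
  expect_lte(sum(hu$hotspot), 0.15 * sum(hu$n_tracts > 0))
  expect_equal(nrow(igc_hotspots(unif[0, ])), 0L)
})

test_that("window IGC flags follow interval intersection", {
  w <- data.frame(start = c(0L, 1000L, 2000L), end = c(1000L, 2000L, 3000L))
  tr <- data.frame(start = 1500L, end = 2200L)
  out <- annotate_windows_igc(w, tr)
  expect_equal(out$igc_overlap, c(FALSE, TRUE, TRUE))
  out0 <- annotate_windows_igc(w, tr[0, ])
  expect_equal(out0$igc_overlap, rep(FALSE, 3))
})
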