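mk_samples <- function(n, pops = NULL) {
  s <- sprintf("S%02d", seq_len(n))
  data.frame(sample = s,
             population = if (is.null(pops)) rep("POP", n) else pops,
             hap1 = paste0(s, "_h1"), hap2 = paste0(s, "_h2"),
             stringsAsFactors = FALSE)
}

test_that("copy counts per haplotype populate the table", {
  samples <- mk_samples(2)
  asn <- data.frame(haplotype = c("S01_h1", "S01_h2", "S02_h1", "S02_h2"),
                    label = "B2", stringsAsFactors = FALSE)
  tab <- copy_number_table(asn, samples)
  expect_equal(unname(tab$hap1[, "B2"]), c(1L, 1L))
  expect_equal(unname(tab$hap2[, "B2"]), c(1L, 1L))
  expect_equal(heterozygosity(tab, "B2"), 0)
})

test_that("QC-fail haplotypes become missing and are excluded", {
  samples <- mk_samples(2)
  asn <- data.frame(haplotype = rep(c("S01_h1", "S01_h2", "S02_h1",
                                      "S02_h2"), c(2, 1, 1, 1)),
                    label = "A1", stringsAsFactors = FALSE)
  qc <- c(S01_h1 = TRUE, S01_h2 = FALSE, S02_h1 = TRUE, S02_h2 = TRUE)
  tab <- copy_number_table(asn, samples, qc = qc)
  expect_true(is.na(tab$hap2["S01", "A1"]))
  expect_equal(heterozygosity(tab, "A1"), 0)   # only S02 is complete
  # a sample with both haplotypes failing stays in the table with NAs
  qc2 <- c(S01_h1 = FALSE, S01_h2 = FALSE)
  tab2 <- copy_number_table(asn, samples, qc = qc2)
  expect_true(all(is.na(tab2$hap1["S01", ])))
  expect_equal(nrow(tab2$hap1), 2L)
})

test_that("perfect assignment reproduces simulator truth exactly", {
  cfg <- tiny_config(seed = 71, n_samples = 6)
  sim <- simulate_family(cfg)
  cc <- sim$truth$copy_coordinates
  asn <- data.frame(haplotype = cc$haplotype, label = cc$paralog,
                    stringsAsFactors = FALSE)
  tab <- copy_number_table(asn, sim$truth$samples,
                           labels = colnames(sim$truth$copy_table))
  both <- rbind(tab$hap1, tab$hap2)
  truth <- sim$truth$copy_table
  for (s in sim$truth$samples$sample) {
    h1 <- sim$truth$samples$hap1[sim$truth$samples$sample == s]
    h2 <- sim$truth$samples$hap2[sim$truth$samples$sample == s]
    expect_equal(unname(tab$hap1[s, ]), unname(truth[h1, ]))
    expect_equal(unname(tab$hap2[s, ]), unname(truth[h2, ]))
  }
  # conservation: per-haplotype totals equal discovered copy counts
  expect_equal(sum(tab$hap1) + sum(tab$hap2), nrow(cc))
})

test_that("heterozygosity is the discordant-sample fraction", {
  samples <- mk_samples(50)
  hap1 <- rep(1L, 50); hap2 <- rep(1L, 50)
  hap2[1:37] <- 2L
  asn <- rbind(
    data.frame(haplotype = rep(samples$hap1, hap1), label = "X"),
    data.frame(haplotype = rep(samples$hap2, hap2), label = "X"))
  tab <- copy_number_table(asn, samples)
  expect_equal(heterozygosity(tab, "X"), 0.74)
  # all samples 1/2 discordant
  asn2 <- rbind(data.frame(haplotype = samples$hap1, label = "Y"),
                data.frame(haplotype = rep(samples$hap2, 2), label = "Y"))
  expect_equal(heterozygosity(copy_number_table(asn2, samples), "Y"), 1.0)
})

test_that("invariance classes follow the copy-number support", {
  samples <- mk_samples(4)
  mk_asn <- function(cns, label) {
    haps <- c(samples$hap1, samples$hap2)
    data.frame(haplotype = rep(haps, cns), label = label,
               stringsAsFactors = FALSE)
  }
  asn <- rbind(mk_asn(rep(1L, 8), "F"),            # fixed single copy
               mk_asn(c(1, 2, 3, 1, 2, 1, 1, 1), "P"),  # always present
               mk_asn(c(0, 1, 1, 1, 2, 1, 1, 1), "V"))  # sometimes absent
  tab <- copy_number_table(asn, samples, labels = c("F", "P", "V"))
  cls <- classify_invariance(tab)
  expect_equal(unname(cls), c("fixed_single_copy", "always_present",
                              "variable"))
  # heterozygosity 0 coincides with per-sample concordance of F
  expect_equal(heterozygosity(tab, "F"), 0)
})

test_that("subfamily roll-ups sum member columns before classification", {
  samples <- mk_samples(3)
  asn <- rbind(
    data.frame(haplotype = c(samples$hap1, samples$hap2), label = "A1"),
    data.frame(haplotype = samples$hap1[1:2], label = "A2"))
  tab <- copy_number_table(asn, samples, labels = c("A1", "A2"))
  roll <- rollup_subfamilies(tab, list(A = c("A1", "A2")))
  expect_equal(unname(roll$hap1[, "A"]), c(2, 2, 1))
  expect_equal(classify_invariance(roll)[["A"]], "always_present")
})

test_that("population comparison is a rank-sum test on total CN", {
  set.seed(72)
  samples <- mk_samples(60, pops = rep(c("AFR", "EUR"), each = 30))
  base <- sample(3:5, 60, replace = TRUE)
  shift <- ifelse(samples$population == "AFR", 5L, 0L)
  asn <- rbind(
    data.frame(haplotype = rep(samples$hap1, base + shift), label = "X"),
    data.frame(haplotype = rep(samples$hap2, base + shift), label = "X"))
  tab <- copy_number_table(asn, samples)
  ht <- compare_populations(tab, "AFR", "EUR")
  expect_lt(ht$p.value, 0.001)
  # identical groups: p in the null region
  asn2 <- rbind(data.frame(haplotype = samples$hap1, label = "X"),
                data.frame(haplotype = samples$hap2, label = "X"))
  ht2 <- compare_populations(copy_number_table(asn2, samples),
                             "AFR", "EUR")
  expect_gte(ht2$p.value, 0.5)
  # degenerate 1-vs-1 comparison cannot be significant
  s2 <- mk_samples(2, pops = c("AFR", "EUR"))
  asn3 <- rbind(data.frame(haplotype = s2$hap1, label = "X"),
                data.frame(haplotype = rep(s2$hap2, 2), label = "X"))
  ht3 <- compare_populations(copy_number_table(asn3, s2), "AFR", "EUR")
  expect_gte(ht3$p.value, 0.3)
  expect_error(compare_populations(tab, "AFR", "OCN"), "empty group")
})
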