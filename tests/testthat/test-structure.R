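feat <- function(names, strands, starts, len = 2000) {
  data.frame(name = names, strand = strands, start = starts,
             end = starts + len, stringsAsFactors = FALSE)
}

test_that("encoding reproduces the template and flips reverse haplotypes", {
  f <- feat(c("M1", "A1", "G1", "M2"), rep("+", 4),
            c(0, 5000, 10000, 15000))
  enc <- encode_configuration(f, distal = "M1", proximal = "M2",
                              haplotype = "h1")
  expect_equal(enc$tokens, c("+M1", "+A1", "+G1", "+M2"))
  # same locus assembled on the minus strand: tokens reversed and signed
  fr <- feat(c("M2", "G1", "A1", "M1"), rep("-", 4),
             c(0, 5000, 10000, 15000))
  encr <- encode_configuration(fr, distal = "M1", proximal = "M2")
  expect_equal(encr$tokens, c("+M1", "+A1", "+G1", "+M2"))
  # a middle block inverted in place
  fi <- feat(c("M1", "G1", "A1", "M2"), c("+", "-", "-", "+"),
             c(0, 5000, 10000, 15000))
  enci <- encode_configuration(fi, distal = "M1", proximal = "M2")
  expect_equal(enci$tokens, c("+M1", "-G1", "-A1", "+M2"))
  # sub-threshold features are dropped
  fs <- rbind(f, feat("tiny", "+", 7000, len = 500))
  encs <- encode_configuration(fs, distal = "M1", proximal = "M2")
  expect_equal(encs$tokens, c("+M1", "+A1", "+G1", "+M2"))
  expect_warning(
    expect_null(encode_configuration(feat("A1", "+", 0), "M1", "M2")),
    "boundary markers")
})

test_that("simulated inversion states are re-encoded exactly", {
  cfg <- tiny_config(seed = 41, n_samples = 6, igc_rate = 0)
  sim <- simulate_family(cfg)
  states <- sim$truth$inversion_states
  encs <- lapply(names(sim$assemblies), function(h) {
    ann <- sim$annotations[sim$annotations$contig == h, ]
    encode_configuration(ann, distal = "M1", proximal = "M2",
                         haplotype = h, locus = "L1")
  })
  ref_tokens <- c("+M1", "+A1", "+G1", "+A2", "+A3", "+G2", "+B1",
                  "+B2", "+B3", "+M2")
  calls <- detect_inversions(encs, ref_tokens,
                             markers = c("M1", "G1", "G2", "M2"))
  st <- attr(calls, "states")
  truth_state <- setNames(states$state, states$haplotype)
  expect_true(all(!is.na(st$state)))
  expect_equal(setNames(st$state, st$haplotype)[names(truth_state)],
               truth_state)
})

test_that("catalog groups, filters and weights configurations", {
  enc <- function(tokens, hap) configuration(tokens, "L1", hap)
  encs <- c(lapply(1:7, function(i) enc(c("+M1", "+A1", "+M2"),
                                        paste0("h", i))),
            lapply(8:10, function(i) enc(c("+M1", "-A1", "+M2"),
                                         paste0("h", i))),
            list(enc(c("+M1", "+M2"), "h11")))   # singleton: excluded
  cat1 <- catalog_configurations(encs, min_haplotypes = 2)
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$count, c(7L, 3L))
  expect_equal(cat1$frequency, c(7, 3) / 11)
  # a configuration seen only on QC-fail haplotypes is excluded
  val <- setNames(rep(TRUE, 11), paste0("h", 1:11))
  val[c("h8", "h9", "h10")] <- FALSE
  cat2 <- catalog_configurations(encs, min_haplotypes = 2, validated = val)
  expect_equal(nrow(cat2), 1L)
  # identical haplotypes collapse to a single configuration
  cat3 <- catalog_configurations(lapply(1:10, function(i)
    enc(c("+M1", "+A1", "+M2"), paste0("h", i))))
  expect_equal(nrow(cat3), 1L)
  expect_equal(cat3$count, 10L)
})

test_that("config trees are additive for small catalogs", {
  enc <- function(tokens, hap) configuration(tokens, "L1", hap)
  base <- c("+M1", "+A1", "+G1", "+A2", "+M2")
  inv <- c("+M1", "-G1", "-A1", "+A2", "+M2")      # one inversion from base
  del <- c("+M1", "+A1", "+G1", "+M2")             # one deletion from base
  encs <- c(lapply(1:4, function(i) enc(base, paste0("h", i))),
            lapply(5:7, function(i) enc(inv, paste0("h", i))),
            lapply(8:9, function(i) enc(del, paste0("h", i))))
  cat1 <- catalog_configurations(encs)
  tr <- config_tree(cat1)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), sort(cat1$config_id))
  # pairwise path lengths reproduce the DCJ distances (additive case)
  toks <- attr(cat1, "tokens_list")
  coph <- ape::cophenetic.phylo(tr)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(coph[cat1$config_id[i], cat1$config_id[j]],
                 dcj_indel_distance(toks[[i]], toks[[j]]),
                 tolerance = 1e-9)
  }
  # single configuration: trivial tree
  expect_null(config_tree(catalog_configurations(
    lapply(1:3, function(i) enc(base, paste0("h", i))))))
})

test_that("inversion allele frequencies are direct counts", {
  ref <- c("+M1", "+A1", "+G1", "+A2", "+M2")
  inv <- c("+M1", "+A1", "-A2", "-G1", "+M2")
  encs <- c(lapply(1:69, function(i) configuration(inv, "L1",
                                                   paste0("h", i))),
            lapply(70:100, function(i) configuration(ref, "L1",
                                                     paste0("h", i))))
  calls <- detect_inversions(encs, ref, markers = c("M1", "G1", "M2"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$af, 0.69)
  expect_equal(calls$n_inverted, 69L)
  # no inverted haplotype: no calls
  none <- detect_inversions(encs[70:100], ref, markers = c("M1", "G1", "M2"))
  expect_equal(nrow(none), 0L)
})

test_that("simulated inversion AF lands in the binomial interval of truth", {
  cfg <- tiny_config(seed = 43, n_samples = 15, igc_rate = 0,
                     inversions = list(list(id = "inv1", locus = "L1",
                                            span = c(3L, 5L), af = 0.4)))
  sim <- simulate_family(cfg)
  encs <- lapply(names(sim$assemblies), function(h) {
    ann <- sim$annotations[sim$annotations$contig == h, ]
    encode_configuration(ann, distal = "M1", proximal = "M2",
                         haplotype = h, locus = "L1")
  })
  ref_tokens <- c("+M1", "+A1", "+G1", "+A2", "+A3", "+G2", "+B1",
                  "+B2", "+B3", "+M2")
  calls <- detect_inversions(encs, ref_tokens,
                             markers = c("M1", "G1", "G2", "M2"))
  truth_af <- mean(sim$truth$inversion_states$state == "I")
  expect_equal(calls$af[1], truth_af)
  ci <- stats::binom.test(calls$n_inverted[1], calls$n_encodable[1],
                          0.4)$conf.int
  expect_true(ci[1] <= 0.4 && 0.4 <= ci[2])
})
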