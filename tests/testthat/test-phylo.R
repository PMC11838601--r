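test_that("p and JC69 distances match closed forms", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 90), strrep("C", 10))
  D <- pairwise_distance(c(x = a, y = b), model = "p")
  expect_equal(D["x", "y"], 0.10)
  expect_equal(unname(diag(D)), c(0, 0))
  Dj <- pairwise_distance(c(x = a, y = b), model = "JC69")
  expect_equal(Dj["x", "y"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  # saturated JC69 distance is an error, not a number
  c_ <- chartr("A", "G", a)
  expect_error(pairwise_distance(c(x = a, y = c_), model = "JC69"),
               "undefined")
  # identical sequences
  expect_equal(pairwise_distance(c(x = a, y = a))["x", "y"], 0)
})

test_that("NJ recovers additive matrices exactly", {
  # fixed 4-taxon additive case ((A,B),(C,D))
  bl <- c(A = 2, B = 3, C = 4, D = 5)
  internal <- 6
  D <- matrix(0, 4, 4, dimnames = list(names(bl), names(bl)))
  D["A", "B"] <- D["B", "A"] <- bl["A"] + bl["B"]
  D["C", "D"] <- D["D", "C"] <- bl["C"] + bl["D"]
  for (x in c("A", "B")) for (y in c("C", "D")) {
    D[x, y] <- D[y, x] <- bl[x] + bl[y] + internal
  }
  tr <- build_nj(D)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[names(bl),
                                                          names(bl)]),
               unname(D), tolerance = 1e-9)

  # property: 100 random additive matrices (n <= 10) are recovered
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    true_tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    Dt <- ape::cophenetic.phylo(true_tr)
    est <- build_nj(Dt)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(est), ape::unroot(true_tr))), 0)
  }
})

test_that("NJ tie-breaking is deterministic and degenerate input errors", {
  D <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  t1 <- build_nj(D)
  t2 <- build_nj(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(build_nj(D[1:2, 1:2]), "at least 3")
})

test_that("bootstrap gives full support to well-separated clades and none to ties", {
  base <- strrep("A", 150)
  diag50 <- function(ch) paste0(strrep(ch, 50), strrep("A", 100))
  seqs <- c(a1 = diag50("C"), a2 = diag50("C"),
            b1 = diag50("G"), b2 = diag50("G"),
            c1 = base, c2 = base)
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 2)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup == 100, na.rm = TRUE))
  # all-identical alignment: no resolved, supported bipartition
  same <- setNames(rep(strrep("ACGT", 40), 4), paste0("s", 1:4))
  tr2 <- bootstrap_support(same, n_reps = 50, seed = 3)
  sup2 <- suppressWarnings(as.numeric(tr2$node.label))
  expect_false(any(sup2 > 75, na.rm = TRUE))
})

test_that("simulated paralog clades get high support and correct labels", {
  set.seed(15)
  mk <- make_paralog_copies(n_paralogs = 4, copies_per = 5)
  tr <- bootstrap_support(mk$seqs, n_reps = 100, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  for (p in unique(mk$truth)) {
    tips <- names(mk$truth)[mk$truth == p]
    expect_true(ape::is.monophyletic(tr, tips))
  }
  # clade supports of the four paralog clades are >= 95
  ntip <- length(tr$tip.label)
  for (p in unique(mk$truth)) {
    tips <- names(mk$truth)[mk$truth == p]
    nd <- ape::getMRCA(tr, tips)
    expect_gte(sup[nd - ntip], 95)
  }
  anchors <- setNames(mk$truth[paste0("P", 1:4, "_c1")],
                      paste0("P", 1:4, "_c1"))
  asn <- assign_paralogs(tr, anchors)
  acc <- mean(asn$label[match(names(mk$truth), asn$copy)] == mk$truth)
  expect_gte(acc, 0.95)
  expect_true(all(asn$provenance %in%
                    c("anchor", "merged", "nearest-neighbor")))
})

test_that("anchorless supported clades get L-suffixed nearest-neighbour names", {
  set.seed(16)
  mk <- make_paralog_copies(n_paralogs = 3, copies_per = 5)
  tr <- bootstrap_support(mk$seqs, n_reps = 100, seed = 5)
  # anchor only P1 and P2; the P3 clade is anchorless and nearest to one
  anchors <- c(P1_c1 = "A1", P2_c1 = "A2")
  asn <- assign_paralogs(tr, anchors)
  p3 <- asn$label[asn$copy %in% names(mk$truth)[mk$truth == "P3"]]
  expect_equal(length(unique(p3)), 1L)
  expect_match(unique(p3), "^A[12]L1$")
  expect_true(all(asn$provenance[asn$copy %in%
                                   names(mk$truth)[mk$truth == "P3"]] ==
                    "nearest-neighbor"))
})

test_that("anchors closer than merge_distance collapse into a joint label", {
  set.seed(17)
  # P1 and P2 nearly identical, P3 distant
  anc <- rdna(3000)
  c1 <- mutate_seq(anc, 0.001)
  c2 <- mutate_seq(c1, 0.001)   # ~0.1% from c1
  c3 <- mutate_seq(anc, 0.05)
  seqs <- character(0)
  for (i in 1:4) seqs[paste0("x", i)] <- mutate_seq(c1, 5e-4)
  for (i in 1:4) seqs[paste0("y", i)] <- mutate_seq(c2, 5e-4)
  for (i in 1:4) seqs[paste0("z", i)] <- mutate_seq(c3, 5e-4)
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 6)
  anchors <- c(x1 = "X", y1 = "Y", z1 = "Z")
  asn <- assign_paralogs(tr, anchors, merge_distance = 0.003)
  expect_true(all(asn$label[asn$copy %in%
                              c(paste0("x", 1:4), paste0("y", 1:4))] ==
                    "X/Y"))
  expect_true(all(asn$label[asn$copy %in% paste0("z", 1:4)] == "Z"))
})

test_that("strict-clock dating is proportional, zero at tips, scale-invariant", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,o:4);")
  d <- date_nodes(tr, outgroup = "o", root_age = 28.8)
  expect_true(all(d$ages[c("a", "b", "c", "d", "o")] == 0))
  # the (a,b) node sits halfway down the ingroup root-to-tip path
  nd <- ape::getMRCA(d$tree, c("a", "b"))
  expect_equal(unname(d$ages[paste0("node", nd)]), 14.4, tolerance = 1e-6)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 7
  d2 <- date_nodes(tr2, outgroup = "o", root_age = 28.8)
  expect_equal(d$ages, d2$ages, tolerance = 1e-9)
  expect_error(date_nodes(ape::read.tree(text = "((a:0,b:0):0,o:0);"),
                          "o", 28.8), "zero root height")
})

test_that("clock simulations recover a known split age", {
  set.seed(18)
  # two clades splitting at 3.0 Myr within a 28.8 Myr root: simulate
  # sequences on an ultrametric tree with rate r subs/site/Myr
  root_age <- 28.8
  split_age <- 3.0
  rate <- 0.004
  est <- replicate(20, {
    anc <- rdna(2500)
    og <- mutate_seq(anc, root_age * rate)          # outgroup branch
    node <- mutate_seq(anc, (root_age - split_age) * rate)
    tips <- c(og = og,
              a = mutate_seq(node, split_age * rate),
              b = mutate_seq(node, split_age * rate),
              c = mutate_seq(mutate_seq(anc, (root_age - 10) * rate),
                             10 * rate))
    D <- pairwise_distance(tips, model = "JC69")
    tr <- build_nj(D)
    d <- date_nodes(tr, outgroup = "og", root_age = root_age)
    nd <- ape::getMRCA(d$tree, c("a", "b"))
    d$ages[paste0("node", nd)]
  })
  expect_equal(mean(est), 3.0, tolerance = 0.5 / 3.0)
})
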