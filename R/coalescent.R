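#' Haplotype-by-SNP variant matrix
#'
#' Container for biallelic SNPs over a set of haplotypes: 0 codes the
#' reference-matching allele, 1 the alternate. `ancestral` gives, per SNP,
#' which allele (0/1) is ancestral, or `NA` when polarity is unknown.
#'
#' @param contig contig name.
#' @param positions 0-based bp positions, strictly increasing.
#' @param G haplotype x SNP 0/1 matrix (rownames are haplotype ids).
#' @param ancestral integer vector (0, 1 or NA) per SNP.
#' @return an object of class `variant_matrix`.
#' @export
variant_matrix <- function(contig, positions, G,
                           ancestral = rep(0L, length(positions))) {
  positions <- as.integer(positions)
  if (length(positions) != ncol(G)) stop("positions/G dimension mismatch")
  if (length(positions) > 1L && any(diff(positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  if (ncol(G) > 0L) {
    mono <- colSums(G) %in% c(0L, nrow(G))
    if (any(is.na(G))) stop("missing alleles not supported")
  }
  obj <- list(contig = contig, positions = positions,
              G = G, ancestral = as.integer(ancestral))
  class(obj) <- "variant_matrix"
  obj
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("variant_matrix:", nrow(x$G), "haplotypes x", ncol(x$G),
      "biallelic SNPs on", x$contig, "\n")
  invisible(x)
}

#' Number of segregating sites
#' @param vm a `variant_matrix`.
#' @return integer count of segregating columns.
#' @export
n_seg_sites <- function(vm) {
  if (ncol(vm$G) == 0L) return(0L)
  sum(colSums(vm$G) > 0L & colSums(vm$G) < nrow(vm$G))
}

#' Simulate one window under a coalescent genealogy
#'
#' Draws a genealogy for `n` haplotypes without recombination and places
#' infinite-sites mutations as Poisson(theta x total branch length / 2),
#' the convention under which the expected mean pairwise difference of a
#' neutral sample equals `theta`.
#'
#' Modes:
#' \describe{
#'   \item{neutral}{the standard n-coalescent.}
#'   \item{star}{a star genealogy with equal terminal branches (default
#'     length `2 a1 / n`, `a1 = sum(1/i, i < n)`, so the expected number of
#'     segregating sites matches the neutral expectation `theta a1`); the
#'     limiting genealogy immediately after a completed hard sweep — every
#'     variant is a singleton.}
#'   \item{sweep}{a partial hard sweep: a fraction `sweep_freq` of the
#'     lineages coalesces in a recent star (time `sweep_time`), and the
#'     resulting stem lineage — the selected haplotype — joins the
#'     background lineages in a neutral coalescent only after
#'     `sweep_stem_min` additional units (the haplotype's pre-sweep
#'     history). The stem branch carries derived variants shared by the
#'     whole swept class, giving the high-frequency extended haplotypes
#'     that polarized homozygosity statistics detect.}
#' }
#'
#' @param n number of haplotypes (>= 2).
#' @param theta population mutation parameter for the window.
#' @param mode "neutral", "star" or "sweep".
#' @param seed optional seed; when `NULL` the current RNG stream is used so
#'   replicate windows can be drawn under one outer seed.
#' @param window_bp window width in bp (positions are drawn uniformly).
#' @param star_branch terminal branch length for star mode (coalescent
#'   units); default `2 a1 / n`.
#' @param sweep_freq swept-class frequency for sweep mode.
#' @param sweep_time star depth of the swept class, coalescent units.
#' @param sweep_stem_min minimum age of the selected haplotype beyond
#'   `sweep_time` before its stem lineage can coalesce with the
#'   background, coalescent units.
#' @param contig contig label for the output.
#' @return a [variant_matrix()] with ancestral polarity 0 at every SNP.
#' @export
sim_coalescent_window <- function(n, theta,
                                  mode = c("neutral", "star", "sweep"),
                                  seed = NULL, window_bp = 30000,
                                  star_branch = NULL, sweep_freq = 0.7,
                                  sweep_time = 0.02, sweep_stem_min = 0.7,
                                  contig = "simwin") {
  mode <- match.arg(mode)
  if (n < 2L) stop("n must be >= 2")
  if (theta < 0) stop("theta must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  branches <- list()  # each: list(leaves = integer vector, len = numeric)
  add_branch <- function(leaves, len) {
    branches[[length(branches) + 1L]] <<- list(leaves = leaves, len = len)
  }

  if (mode == "star") {
    a1 <- sum(1 / seq_len(n - 1L))
    t0 <- if (is.null(star_branch)) 2 * a1 / n else star_branch
    for (i in seq_len(n)) add_branch(i, t0)
  } else {
    ## run a neutral coalescent over `lineages` starting at time t0
    run_coalescent <- function(lineages, births, t0) {
      t <- t0
      while (length(lineages) > 1L) {
        k <- length(lineages)
        t <- t + rexp(1, rate = k * (k - 1) / 2)
        pick <- sample.int(k, 2L)
        for (p in pick) add_branch(lineages[[p]], t - births[[p]])
        merged <- sort(c(lineages[[pick[1]]], lineages[[pick[2]]]))
        lineages <- c(lineages[-pick], list(merged))
        births <- c(births[-pick], t)
      }
      invisible(NULL)
    }
    if (mode == "neutral") {
      run_coalescent(as.list(seq_len(n)), rep(0, n), 0)
    } else {
      k <- max(2L, min(n - 2L, round(sweep_freq * n)))
      for (i in seq_len(k)) add_branch(i, sweep_time)
      ## phase 1: background lineages coalesce among themselves until the
      ## stem (the selected haplotype) becomes available
      stem_entry <- sweep_time + sweep_stem_min
      bg <- as.list((k + 1L):n)
      bg_births <- rep(0, n - k)
      t <- 0
      while (length(bg) > 1L) {
        m <- length(bg)
        dt <- rexp(1, rate = m * (m - 1) / 2)
        if (t + dt >= stem_entry) break
        t <- t + dt
        pick <- sample.int(m, 2L)
        for (p in pick) add_branch(bg[[p]], t - bg_births[[p]])
        merged <- sort(c(bg[[pick[1]]], bg[[pick[2]]]))
        bg <- c(bg[-pick], list(merged))
        bg_births <- c(bg_births[-pick], t)
      }
      lineages <- c(list(sort(seq_len(k))), bg)
      births <- c(sweep_time, bg_births)
      run_coalescent(lineages, births, stem_entry)
    }
  }

  lens <- vapply(branches, `[[`, numeric(1), "len")
  total <- sum(lens)
  S <- if (theta > 0 && total > 0) rpois(1L, theta * total / 2) else 0L
  S <- min(S, window_bp)  # infinite-sites needs distinct positions
  if (S == 0L) {
    return(variant_matrix(contig, integer(0),
                          matrix(0L, nrow = n, ncol = 0L,
                                 dimnames = list(paste0("hap", seq_len(n)),
                                                 NULL)),
                          integer(0)))
  }
  on_branch <- sample.int(length(branches), S, replace = TRUE,
                          prob = lens / total)
  pos <- sort(sample.int(window_bp, S)) - 1L
  G <- matrix(0L, nrow = n, ncol = S,
              dimnames = list(paste0("hap", seq_len(n)), NULL))
  ## mutations sorted by position; branch draws are iid so order is free
  for (j in seq_len(S)) {
    G[branches[[on_branch[j]]]$leaves, j] <- 1L
  }
  ## drop mutations fixed in the sample (root-adjacent branches never
  ## produce them here, but sweep stems can when all background lineages
  ## coalesce into the stem first)
  keep <- colSums(G) < n & colSums(G) > 0L
  variant_matrix(contig, pos[keep], G[, keep, drop = FALSE],
                 rep(0L, sum(keep)))
}

#' Thread a variant matrix onto a reference sequence
#'
#' Materialises haplotype sequences: each haplotype equals `ref` except at
#' SNP positions with allele 1, where the base is substituted
#' deterministically (next base in A->C->G->T->A order). The round trip
#' through [call_variants()] recovers the matrix exactly.
#' @param vm a [variant_matrix()].
#' @param ref reference sequence covering the window.
#' @param offset 0-based offset of the window start within `ref`.
#' @return named character vector of haplotype sequences.
#' @export
thread_variants <- function(vm, ref, offset = 0L) {
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ref_ch <- seq_chars(ref)
  out <- character(nrow(vm$G))
  for (i in seq_len(nrow(vm$G))) {
    ch <- ref_ch
    alt_at <- vm$positions[vm$G[i, ] == 1L] + offset + 1L
    ch[alt_at] <- nxt[ch[alt_at]]
    out[i] <- chars_seq(ch)
  }
  setNames(out, rownames(vm$G))
}

#' Mean pairwise difference (pi) of a variant matrix
#'
#' Computed from per-site allele counts: `sum(2 j (n-j) / (n (n-1)))` over
#' segregating sites with derived count j.
#' @param vm a [variant_matrix()].
#' @return numeric pi (mean pairwise difference count).
#' @export
pairwise_pi <- function(vm) {
  n <- nrow(vm$G)
  if (ncol(vm$G) == 0L) return(0)
  j <- colSums(vm$G)
  sum(2 * j * (n - j) / (n * (n - 1)))
}
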