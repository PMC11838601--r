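#' Call biallelic SNPs from haplotype assemblies against a reference
#'
#' Haplotype sequences must be anchored (colinear, equal length) to the
#' reference window, as produced by the discovery module or the simulator.
#' Columns where at least one haplotype differs from the reference become
#' SNPs; columns with more than two observed alleles (haplotypes plus
#' reference) are dropped. Polarity is set from the outgroup base when it
#' matches one of the two alleles, otherwise unknown.
#'
#' @param haplotypes named character vector of anchored haplotype sequences.
#' @param reference reference sequence of the same length.
#' @param outgroup optional outgroup sequence of the same length.
#' @param contig contig name for the output.
#' @param offset 0-based offset of this window on the contig.
#' @return a [variant_matrix()]; `ancestral` is 0/1/NA per SNP and the
#'   `ref_allele`/`alt_allele` fields record the bases.
#' @export
call_variants <- function(haplotypes, reference, outgroup = NULL,
                          contig = "ref", offset = 0L) {
  if (length(haplotypes) == 0L) stop("no anchorable haplotypes")
  if (any(nchar(haplotypes) != nchar(reference))) {
    stop("haplotypes must be anchored to the reference (equal length)")
  }
  H <- do.call(rbind, strsplit(toupper(haplotypes), "", fixed = TRUE))
  rownames(H) <- names(haplotypes)
  ref <- seq_chars(toupper(reference))
  og <- if (!is.null(outgroup)) seq_chars(toupper(outgroup)) else NULL

  diff_any <- colSums(H != rep(ref, each = nrow(H))) > 0L
  cols <- which(diff_any)
  keep <- logical(length(cols))
  alt <- character(length(cols))
  for (k in seq_along(cols)) {
    obs <- unique(c(H[, cols[k]], ref[cols[k]]))
    obs <- obs[obs %in% DNA_BASES]
    if (length(obs) == 2L) {
      keep[k] <- TRUE
      alt[k] <- setdiff(obs, ref[cols[k]])
    }
  }
  cols <- cols[keep]; alt <- alt[keep]
  G <- matrix(0L, nrow = nrow(H), ncol = length(cols),
              dimnames = list(rownames(H), NULL))
  for (k in seq_along(cols)) G[, k] <- as.integer(H[, cols[k]] == alt[k])
  anc <- rep(NA_integer_, length(cols))
  if (!is.null(og)) {
    ogb <- og[cols]
    anc[ogb == ref[cols]] <- 0L
    anc[ogb == alt] <- 1L
  } else {
    anc <- rep(0L, length(cols))  # reference taken as ancestral by default
  }
  vm <- variant_matrix(contig, cols - 1L + offset, G, anc)
  vm$ref_allele <- ref[cols]
  vm$alt_allele <- alt
  vm
}

## Tajima (1989) normalising constants.
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D over windows of a variant matrix
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants; `pi` is the mean pairwise difference count in the window and
#' `S` the number of segregating sites. Windows without segregating sites
#' yield a missing value, not zero, so they do not dilute percentile tails.
#'
#' @param vm a [variant_matrix()] (n >= 4 haplotypes).
#' @param window tile width in bp; windows are non-overlapping tiles.
#' @param contig_length contig extent tiled; defaults to the last SNP
#'   position + 1 rounded up to a whole window.
#' @return data.frame: contig, start, end, n_snps, statistic ("tajima_d"),
#'   value.
#' @export
tajimas_d <- function(vm, window = 30000, contig_length = NULL) {
  n <- nrow(vm$G)
  if (n < 4L) stop("need >= 4 haplotypes")
  if (is.null(contig_length)) {
    contig_length <- if (length(vm$positions)) {
      ceiling((max(vm$positions) + 1) / window) * window
    } else window
  }
  starts <- seq.int(0L, max(0L, contig_length - 1L), by = window)
  k <- tajima_constants(n)
  rows <- lapply(starts, function(s) {
    sel <- vm$positions >= s & vm$positions < s + window
    j <- colSums(vm$G[, sel, drop = FALSE])
    seg <- j > 0L & j < n
    S <- sum(seg)
    val <- NA_real_
    if (S > 0L) {
      pi <- sum(2 * j[seg] * (n - j[seg]) / (n * (n - 1)))
      val <- (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    }
    data.frame(contig = vm$contig, start = s, end = s + window,
               n_snps = S, statistic = "tajima_d", value = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Per-site unstandardised nS_L scores for one variant matrix.
## For each polarised segregating site, SL_A (SL_D) is the mean, over
## haplotype pairs that both carry the ancestral (derived) allele, of the
## number of consecutive segregating sites in the maximal interval of
## pairwise identity containing the site; the score is ln(SL_A / SL_D).
nsl_site_scores <- function(vm) {
  n <- nrow(vm$G)
  scored <- which(!is.na(vm$ancestral))
  out0 <- data.frame(contig = character(0), position = integer(0),
                     dcount = integer(0), score = numeric(0))
  if (length(scored) < 1L) return(out0)
  M <- vm$G[, scored, drop = FALSE]
  flip <- vm$ancestral[scored] == 1L
  M[, flip] <- 1L - M[, flip, drop = FALSE]   # M = derived indicator
  j <- colSums(M)
  seg <- which(j >= 2L & j <= n - 2L)  # need pairs on both backgrounds
  if (length(seg) == 0L) return(out0)
  S <- ncol(M)
  sumD <- numeric(S); cntD <- numeric(S)
  sumA <- numeric(S); cntA <- numeric(S)
  for (i in seq_len(n - 1L)) {
    for (jj in (i + 1L):n) {
      agree <- M[i, ] == M[jj, ]
      r <- rle(agree)
      v <- rep(r$lengths, r$lengths)
      v[!agree] <- 0L
      bd <- M[i, ] == 1L & M[jj, ] == 1L
      ba <- M[i, ] == 0L & M[jj, ] == 0L
      sumD <- sumD + v * bd; cntD <- cntD + bd
      sumA <- sumA + v * ba; cntA <- cntA + ba
    }
  }
  keep <- seg[cntD[seg] > 0 & cntA[seg] > 0 &
                sumD[seg] > 0 & sumA[seg] > 0]
  if (length(keep) == 0L) return(out0)
  sla <- sumA[keep] / cntA[keep]
  sld <- sumD[keep] / cntD[keep]
  data.frame(contig = vm$contig, position = vm$positions[scored][keep],
             dcount = j[keep], score = log(sla / sld),
             stringsAsFactors = FALSE)
}

#' nS_L selection scan with frequency-bin standardisation
#'
#' Computes per-site unstandardised nS_L scores for each variant matrix,
#' standardises them to zero mean and unit variance within derived-allele
#' frequency bins (pooled across all input matrices, selscan-style), and
#' summarises windows as the fraction of sites with |standardised score|
#' greater than 2. Sites with unknown polarity are excluded; windows with
#' fewer than `min_snps` scored sites get no statistic.
#'
#' @param vms a [variant_matrix()] or a list of them (e.g. one per
#'   independently simulated window); identity runs never extend across
#'   list elements.
#' @param n_bins number of equal-width derived-frequency bins.
#' @param min_snps minimum scored sites per reported window.
#' @param window window width in bp.
#' @param norm_stats optional per-bin normalisation table from
#'   [nsl_bin_stats()], e.g. computed on chromosome-wide background
#'   windows; by default scores are standardised within the input itself.
#' @return list with `sites` (contig, position, dcount, freq, score, z)
#'   and `windows` (contig, start, end, n_snps, statistic "nsl_window",
#'   value).
#' @export
nsl_scan <- function(vms, n_bins = 100, min_snps = 10, window = 30000,
                     norm_stats = NULL) {
  if (inherits(vms, "variant_matrix")) vms <- list(vms)
  n <- nrow(vms[[1]]$G)
  sites <- do.call(rbind, lapply(vms, nsl_site_scores))
  if (is.null(sites) || nrow(sites) == 0L) {
    return(list(sites = data.frame(), windows = data.frame()))
  }
  sites$freq <- sites$dcount / n
  sites$bin <- pmin(n_bins - 1L, floor(sites$freq * n_bins))
  if (is.null(norm_stats)) {
    norm_stats <- nsl_bin_stats(sites, n_bins = n_bins)
  }
  m <- match(sites$bin, norm_stats$bin)
  sites$z <- (sites$score - norm_stats$mean[m]) / norm_stats$sd[m]
  win_rows <- list()
  for (vm in vms) {
    cl <- if (length(vm$positions)) {
      ceiling((max(vm$positions) + 1) / window) * window
    } else window
    for (s0 in seq.int(0L, max(0L, cl - 1L), by = window)) {
      sel <- sites$contig == vm$contig & sites$position >= s0 &
        sites$position < s0 + window & !is.na(sites$z)
      ns <- sum(sel)
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        contig = vm$contig, start = s0, end = s0 + window, n_snps = ns,
        statistic = "nsl_window",
        value = if (ns >= min_snps) mean(abs(sites$z[sel]) > 2) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(sites = sites[, c("contig", "position", "dcount", "freq",
                         "score", "z")],
       windows = do.call(rbind, win_rows))
}

#' Derived-frequency-bin normalisation table for nS_L
#'
#' Mean and standard deviation of the unstandardised score per
#' derived-frequency bin, typically computed on a chromosome-wide (mostly
#' neutral) background and then applied to windows of interest.
#' @param x a [variant_matrix()], a list of them, or a site data.frame
#'   from [nsl_scan()] (needs `freq` and `score` columns, or
#'   `dcount`/`score` plus haplotype count inferred from `freq`).
#' @param n_bins number of equal-width frequency bins.
#' @return data.frame: bin, n, mean, sd (bins with < 2 sites or zero
#'   variance are dropped).
#' @export
nsl_bin_stats <- function(x, n_bins = 100) {
  if (inherits(x, "variant_matrix")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) {
    n <- nrow(x[[1]]$G)
    x <- do.call(rbind, lapply(x, nsl_site_scores))
    if (is.null(x) || nrow(x) == 0L) {
      return(data.frame(bin = integer(0), n = integer(0),
                        mean = numeric(0), sd = numeric(0)))
    }
    x$freq <- x$dcount / n
  }
  if (!"bin" %in% names(x)) {
    x$bin <- pmin(n_bins - 1L, floor(x$freq * n_bins))
  }
  rows <- lapply(sort(unique(x$bin)), function(b) {
    v <- x$score[x$bin == b]
    if (length(v) < 2L || sd(v) == 0) return(NULL)
    data.frame(bin = b, n = length(v), mean = mean(v), sd = sd(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(bin = integer(0), n = integer(0),
                               mean = numeric(0), sd = numeric(0)) else out
}

#' Rank windows by chromosome-wide percentile and flag gene overlap
#'
#' Percentiles are computed over all non-missing windows of each statistic;
#' windows are flagged with the genes they overlap by at least
#' `min_overlap` bp, and classified into extreme sets at the 1st/5th and
#' 95th/99th percentiles.
#'
#' @param stats window data.frame (as from [tajimas_d()] or
#'   `nsl_scan()$windows`).
#' @param genes data.frame: contig, start, end, label of gene intervals.
#' @param min_overlap bp of intersection required to flag a window.
#' @return `stats` with added columns `percentile`, `genes`, `extreme`.
#' @export
rank_windows <- function(stats, genes = NULL, min_overlap = 5000) {
  stats$percentile <- NA_real_
  for (st in unique(stats$statistic)) {
    sel <- stats$statistic == st & !is.na(stats$value)
    v <- stats$value[sel]
    stats$percentile[sel] <- 100 * rank(v, ties.method = "average") /
      length(v)
  }
  stats$genes <- ""
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(stats))) {
      ov <- interval_overlap(stats$start[i], stats$end[i],
                             genes$start, genes$end) >= min_overlap &
        genes$contig == stats$contig[i]
      if (any(ov)) stats$genes[i] <- paste(genes$label[ov], collapse = ",")
    }
  }
  p <- stats$percentile
  stats$extreme <- ifelse(is.na(p), NA_character_,
                          ifelse(p <= 1, "low1",
                                 ifelse(p <= 5, "low5",
                                        ifelse(p >= 99, "high99",
                                               ifelse(p >= 95, "high95",
                                                      "none")))))
  stats
}

#' Sensitivity of percentile cutoffs to IGC-overlapping windows
#'
#' Recomputes the left-tail percentile cutoffs of a window statistic with
#' and without IGC-overlapping windows, the check that gene-conversion
#' driven rare-variant excess is not masquerading as a sweep signal.
#'
#' @param stats window data.frame with an `igc_overlap` logical column.
#' @param probs percentile cutoffs to report (fractions).
#' @return data.frame: regime ("all", "igc_excluded"), one column per
#'   cutoff, n_windows.
#' @export
igc_sensitivity <- function(stats, probs = c(0.01, 0.05)) {
  stopifnot("igc_overlap" %in% names(stats))
  cuts <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(rep(NA_real_, length(probs)))
    quantile(v, probs = probs, names = FALSE, type = 7)
  }
  all_q <- cuts(stats$value)
  ex <- stats[!stats$igc_overlap, , drop = FALSE]
  ex_q <- if (nrow(ex)) cuts(ex$value) else rep(NA_real_, length(probs))
  out <- data.frame(regime = c("all", "igc_excluded"),
                    rbind(all_q, ex_q),
                    n_windows = c(sum(!is.na(stats$value)),
                                  sum(!is.na(ex$value))),
                    row.names = NULL)
  names(out)[2:(1 + length(probs))] <- paste0("p", probs * 100)
  out
}
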