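#' Find gene-family copies in a haplotype contig
#'
#' Anchor-chaining homology search: exact k-mer anchors shared with the
#' ancestral query are collected on both strands, grouped by alignment
#' diagonal, and chained into candidate hits when consecutive anchors are
#' less than `chain_gap` apart. Because the mutation model downstream of
#' this package is substitution-dominated at <= 10% divergence, hits lie on
#' a single diagonal and coordinates follow directly from it. Hits shorter
#' than `min_len` or with estimated identity below `1 - max_divergence` are
#' dropped; overlapping candidates are resolved greedily by anchor count.
#'
#' @param haplotype one contig sequence.
#' @param query the ancestral duplicon sequence (length >= `min_len`).
#' @param min_len minimum hit length in bp.
#' @param max_divergence maximum estimated divergence of a reported hit.
#' @param k anchor k-mer size.
#' @param stride scan stride over the haplotype in bp (anchors are looked
#'   up every `stride` positions; the query is indexed at every position).
#' @param chain_gap maximum anchor gap within a chain, bp.
#' @param contig contig name recorded in the output.
#' @return data.frame of class `locus_copies`: contig, start, end (0-based
#'   half-open), strand, n_anchors, identity_est, paralog (NA until
#'   assigned), validation ("untested"), sequence (query orientation).
#' @export
find_copies <- function(haplotype, query, min_len = 15000,
                        max_divergence = 0.20, k = 21L, stride = 10L,
                        chain_gap = 5000, contig = "contig") {
  Lq <- nchar(query)
  if (Lq < min_len) stop("query shorter than min_len")
  Lh <- nchar(haplotype)
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_anchors = integer(0), identity_est = numeric(0),
                      paralog = character(0), validation = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("locus_copies", "data.frame")
  if (Lh < k) return(empty)

  qpos <- seq_len(Lq - k + 1L)
  q_fwd <- kmers_at(query, k, qpos)
  rcq <- revcomp(query)
  q_rev <- kmers_at(rcq, k, qpos)

  hpos <- seq.int(1L, Lh - k + 1L, by = stride)
  h_kmers <- kmers_at(haplotype, k, hpos)

  hits <- list()
  for (strand in c("+", "-")) {
    tab <- if (strand == "+") q_fwd else q_rev
    m <- match(h_kmers, tab)          # first occurrence on repeats
    ok <- !is.na(m)
    if (!any(ok)) next
    hp <- hpos[ok]; qp <- m[ok]
    diag <- hp - qp
    ## group anchors sharing a diagonal, then chain by haplotype gap
    grp <- round(diag / 200)
    for (g in unique(grp)) {
      sel <- which(grp == g)
      o <- order(hp[sel])
      sh <- hp[sel][o]; sq <- qp[sel][o]
      brk <- c(0L, which(diff(sh) > chain_gap), length(sh))
      for (b in seq_len(length(brk) - 1L)) {
        ii <- (brk[b] + 1L):brk[b + 1L]
        d <- as.integer(round(median(sh[ii] - sq[ii])))
        minq <- min(sq[ii]); maxq <- max(sq[ii])
        ## snap to the full query extent when anchors come close to the
        ## ends (small anchor-free margins arise from substitutions)
        snap <- 5L * k
        if (minq <= snap) minq <- 1L
        if (maxq >= Lq - k + 1L - snap) maxq <- Lq - k + 1L
        start0 <- max(0L, d + minq - 1L)
        end0 <- min(Lh, d + maxq + k - 1L)
        span <- end0 - start0
        if (span < min_len) next
        n_scanned <- max(1L, length(ii))
        expected <- max(1, span / stride)
        ident <- min(1, (length(ii) / expected))^(1 / k)
        if (ident < 1 - max_divergence) next
        hits[[length(hits) + 1L]] <- list(start = start0, end = end0,
                                          strand = strand,
                                          n_anchors = length(ii),
                                          identity = ident)
      }
    }
  }
  if (length(hits) == 0L) return(empty)

  ## greedy resolution of overlapping candidates by anchor support
  ord <- order(-vapply(hits, `[[`, integer(1), "n_anchors"))
  kept <- list()
  for (i in ord) {
    h <- hits[[i]]
    clash <- any(vapply(kept, function(kk)
      interval_overlap(h$start, h$end, kk$start, kk$end) > 0, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  kept <- kept[order(vapply(kept, `[[`, integer(1), "start"))]

  seqs <- vapply(kept, function(h) {
    s <- substr(haplotype, h$start + 1L, h$end)
    if (h$strand == "-") revcomp(s) else s
  }, character(1))
  out <- data.frame(
    contig = contig,
    start = vapply(kept, `[[`, integer(1), "start"),
    end = vapply(kept, `[[`, integer(1), "end"),
    strand = vapply(kept, `[[`, character(1), "strand"),
    n_anchors = vapply(kept, `[[`, integer(1), "n_anchors"),
    identity_est = vapply(kept, `[[`, numeric(1), "identity"),
    paralog = NA_character_, validation = "untested",
    sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("locus_copies", "data.frame")
  out
}

#' Find copies across a set of haplotype assemblies
#'
#' @param assemblies named character vector of contigs (one per haplotype).
#' @param query ancestral duplicon sequence.
#' @param ... passed to [find_copies()].
#' @return a `locus_copies` data.frame over all contigs with a `copy_id`
#'   column (`contig_f<i>`).
#' @export
find_copies_all <- function(assemblies, query, ...) {
  res <- lapply(names(assemblies), function(h) {
    fc <- find_copies(assemblies[[h]], query, contig = h, ...)
    if (nrow(fc)) fc$copy_id <- paste0(h, "_f", seq_len(nrow(fc)))
    fc
  })
  out <- do.call(rbind, res)
  class(out) <- c("locus_copies", "data.frame")
  out
}

#' Validate assembled loci by flanking unique sequence
#'
#' A copy passes when its contig extends at least `flank` bp beyond both
#' copy ends and no other detected copy overlaps those flanks; copies on
#' contigs of unknown length are left "untested".
#'
#' @param copies a `locus_copies` data.frame (possibly over many contigs).
#' @param contig_lengths named integer vector of contig lengths.
#' @param flank required unique flank, bp.
#' @return `copies` with the `validation` column set to "pass"/"fail" (or
#'   "untested").
#' @export
validate_locus <- function(copies, contig_lengths, flank = 30000) {
  if (nrow(copies) == 0L) return(copies)
  for (i in seq_len(nrow(copies))) {
    cl <- contig_lengths[copies$contig[i]]
    if (is.na(cl)) {
      copies$validation[i] <- "untested"
      next
    }
    ok <- copies$start[i] >= flank && (cl - copies$end[i]) >= flank
    if (ok) {
      others <- copies[-i, , drop = FALSE]
      others <- others[others$contig == copies$contig[i], , drop = FALSE]
      if (nrow(others)) {
        left <- any(interval_overlap(copies$start[i] - flank, copies$start[i],
                                     others$start, others$end) > 0)
        right <- any(interval_overlap(copies$end[i], copies$end[i] + flank,
                                      others$start, others$end) > 0)
        ok <- !(left || right)
      }
    }
    copies$validation[i] <- if (ok) "pass" else "fail"
  }
  copies
}

#' Tally a pileup from simulated reads placed on a reference
#'
#' Reads are placed at their (0-based) start coordinates on the reference
#' coordinate system; minus-strand reads are reverse-complemented before
#' tallying. Positions are 0-based.
#' @param reads named character vector of read sequences.
#' @param placements data.frame with columns `read`, `start`, `strand`.
#' @param ref_length reference length in bp.
#' @return integer matrix `ref_length x 4` (A/C/G/T counts).
#' @export
pileup_from_reads <- function(reads, placements, ref_length) {
  all_idx <- vector("list", nrow(placements))
  all_ch <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    s <- reads[[placements$read[i]]]
    if (placements$strand[i] == "-") s <- revcomp(s)
    ch <- seq_chars(s)
    idx <- placements$start[i] + seq_along(ch)
    keep <- idx >= 1L & idx <= ref_length
    all_idx[[i]] <- idx[keep]
    all_ch[[i]] <- ch[keep]
  }
  idx <- unlist(all_idx, use.names = FALSE)
  ch <- unlist(all_ch, use.names = FALSE)
  pile <- matrix(0L, nrow = ref_length, ncol = 4L,
                 dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES) {
    pile[, b] <- tabulate(idx[ch == b], nbins = ref_length)
  }
  pile
}

#' Flag candidate assembly collapses from a pileup
#'
#' A position is discordant when its second-most-frequent base is supported
#' by at least `min_reads` reads and at least `min_frac` of the coverage;
#' an interval is flagged when `min_sites` or more discordant positions
#' fall within `cluster_window` bp of each other. On a correctly assembled
#' region with error-free reads no position is discordant; a collapsed
#' duplication shows clustered discordant positions at the paralogous
#' sequence variants.
#'
#' @param pileup integer matrix positions x 4 (A/C/G/T counts), positions
#'   contiguous from `offset`.
#' @param min_frac minimum minor-base fraction.
#' @param min_reads minimum minor-base read count.
#' @param cluster_window clustering window, bp.
#' @param min_sites minimum discordant sites per flagged interval.
#' @param offset 0-based coordinate of the first pileup row.
#' @return data.frame: start, end (0-based half-open), n_sites.
#' @export
flag_collapse <- function(pileup, min_frac = 0.10, min_reads = 5,
                          cluster_window = 500, min_sites = 2,
                          offset = 0L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_sites = integer(0))
  if (is.null(pileup) || nrow(pileup) == 0L) return(empty)
  tot <- rowSums(pileup)
  top <- apply(pileup, 1L, max)
  second <- tot - top - apply(pileup, 1L, function(r) {
    sum(sort(r, decreasing = TRUE)[-(1:2)])
  })
  disc <- which(second >= min_reads & tot > 0 & second / tot >= min_frac)
  if (length(disc) < min_sites) return(empty)
  brk <- c(0L, which(diff(disc) > cluster_window), length(disc))
  rows <- list()
  for (b in seq_len(length(brk) - 1L)) {
    ii <- disc[(brk[b] + 1L):brk[b + 1L]]
    if (length(ii) >= min_sites) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = offset + min(ii) - 1L, end = offset + max(ii),
        n_sites = length(ii))
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Estimate copy number from short-read segment depth
#'
#' Reads are cut into non-overlapping `segment_len` bp pieces; each piece
#' is placed at every reference position (either strand) within Hamming
#' distance `max_mismatch`, contributing fractional weight `1/sites` to
#' each. Window copy number is `2 x window depth / mean control depth`,
#' with the control windows designated copy-number-2 (diploid unique)
#' regions of the reference.
#'
#' @param reads character vector of read sequences.
#' @param reference single reference sequence (one gene-family copy plus
#'   unique control regions).
#' @param control_windows data.frame start/end (0-based half-open) of the
#'   copy-number-2 control windows.
#' @param segment_len read segment length, bp.
#' @param max_mismatch maximum Hamming distance per placed segment.
#' @param window copy-number window width, bp.
#' @param excluded_windows optional data.frame start/end of windows to drop
#'   from gene-level summaries (e.g. VNTR-overlapping windows).
#' @return data.frame: start, end, depth, cn, excluded; attribute
#'   `control_depth` carries the normalisation factor.
#' @export
estimate_copy_number <- function(reads, reference, control_windows,
                                 segment_len = 36L, max_mismatch = 2L,
                                 window = 1000L, excluded_windows = NULL) {
  Lr <- nchar(reference)
  seed_len <- segment_len %/% (max_mismatch + 1L)  # pigeonhole seeding
  ref_pos <- seq_len(Lr - segment_len + 1L)
  ## hash index: seed k-mer -> candidate segment start positions, one map
  ## per seed offset, so a segment with <= max_mismatch errors always has
  ## at least one clean seed
  seed_maps <- lapply(0:max_mismatch, function(off) {
    keys <- kmers_at(reference, seed_len, ref_pos + off * seed_len)
    e <- new.env(hash = TRUE, parent = emptyenv(),
                 size = length(keys))
    grp <- split(ref_pos, keys)
    for (nm in names(grp)) assign(nm, grp[[nm]], envir = e)
    e
  })

  ## cut reads into segments
  segs <- unlist(lapply(reads, function(r) {
    np <- nchar(r) %/% segment_len
    if (np == 0L) return(character(0))
    substring(r, (seq_len(np) - 1L) * segment_len + 1L,
              seq_len(np) * segment_len)
  }), use.names = FALSE)
  if (length(segs) == 0L) stop("no read segments")
  segs <- c(segs, revcomp(segs))

  weight <- numeric(Lr)
  ref_raw <- charToRaw(reference)
  off_starts <- (0:max_mismatch) * seed_len + 1L
  for (s in segs) {
    cand <- integer(0)
    for (j in seq_along(off_starts)) {
      sk <- substr(s, off_starts[j], off_starts[j] + seed_len - 1L)
      hit <- get0(sk, envir = seed_maps[[j]], inherits = FALSE)
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- unique(cand)
    if (length(cand) == 0L) next
    sraw <- charToRaw(s)
    mm <- vapply(cand, function(p) {
      sum(ref_raw[p:(p + segment_len - 1L)] != sraw)
    }, numeric(1))
    sites <- cand[mm <= max_mismatch]
    if (length(sites)) weight[sites] <- weight[sites] + 1 / length(sites)
  }

  win_start <- seq.int(0L, Lr - 1L, by = window)
  win_end <- pmin(win_start + window, Lr)
  depth <- vapply(seq_along(win_start), function(i) {
    sum(weight[(win_start[i] + 1L):win_end[i]]) / (win_end[i] - win_start[i])
  }, numeric(1))

  ctl <- rep(FALSE, length(win_start))
  for (i in seq_len(nrow(control_windows))) {
    ctl <- ctl | (win_start >= control_windows$start[i] &
                    win_end <= control_windows$end[i])
  }
  ctl_depth <- mean(depth[ctl])
  if (!any(ctl) || is.na(ctl_depth) || ctl_depth == 0) {
    stop("zero control depth")
  }
  excl <- rep(FALSE, length(win_start))
  if (!is.null(excluded_windows) && nrow(excluded_windows)) {
    for (i in seq_len(nrow(excluded_windows))) {
      excl <- excl | interval_overlap(win_start, win_end,
                                      excluded_windows$start[i],
                                      excluded_windows$end[i]) > 0
    }
  }
  out <- data.frame(start = win_start, end = win_end, depth = depth,
                    cn = 2 * depth / ctl_depth,
                    control = ctl, excluded = excl)
  attr(out, "control_depth") <- ctl_depth
  out
}

#' Gene-level copy number from window estimates
#'
#' The median CN over non-excluded windows intersecting the gene interval
#' (the convention that makes the estimate robust to VNTR-driven depth
#' spikes, which are excluded upstream).
#' @param cn_windows output of [estimate_copy_number()].
#' @param gene_start,gene_end gene interval, 0-based half-open.
#' @return numeric copy number.
#' @export
gene_copy_number <- function(cn_windows, gene_start, gene_end) {
  sel <- interval_overlap(cn_windows$start, cn_windows$end,
                          gene_start, gene_end) > 0 & !cn_windows$excluded
  median(cn_windows$cn[sel])
}
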