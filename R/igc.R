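#' Catalog paralogous sequence variants (PSVs)
#'
#' Every ancestral-locus column at which at least two paralog consensus
#' sequences disagree becomes a PSV carrying the consensus allele of each
#' paralog. Only substitution PSVs exist because copies stay colinear with
#' the ancestral duplicon.
#'
#' @param consensus named character vector of equal-length paralog
#'   consensus sequences anchored to ancestral coordinates.
#' @return list of class `psv_catalog`: `positions` (0-based ancestral
#'   coordinates, strictly increasing), `alleles` (paralog x PSV character
#'   matrix), `paralogs`.
#' @export
build_psv_catalog <- function(consensus) {
  if (length(consensus) < 2L) stop("need at least 2 paralog consensuses")
  if (length(unique(nchar(consensus))) != 1L) {
    stop("consensus sequences must be equal length (anchored)")
  }
  M <- do.call(rbind, strsplit(toupper(consensus), "", fixed = TRUE))
  rownames(M) <- names(consensus)
  informative <- which(apply(M, 2L, function(col) length(unique(col)) > 1L))
  obj <- list(positions = informative - 1L,
              alleles = M[, informative, drop = FALSE],
              paralogs = names(consensus))
  class(obj) <- "psv_catalog"
  obj
}

#' @export
print.psv_catalog <- function(x, ...) {
  cat("psv_catalog:", length(x$positions), "PSVs across",
      length(x$paralogs), "paralogs\n")
  invisible(x)
}

#' Detect interlocus gene-conversion tracts in one copy
#'
#' Walking the PSVs that discriminate the copy's own paralog P from a
#' candidate donor Q, a tract is a maximal run of at least `min_run`
#' consecutive discriminating PSVs at which the copy carries Q's allele,
#' with the immediately flanking discriminating PSVs matching P.
#' Overlapping candidate donors are resolved by longest run, ties by
#' lexicographic donor label.
#'
#' @param copy_seq copy sequence in ancestral orientation (equal length to
#'   the consensus sequences).
#' @param label the copy's own paralog label P.
#' @param catalog a [build_psv_catalog()] result.
#' @param min_run minimum supporting PSV count per tract.
#' @param donors candidate donor labels (default: all other paralogs).
#' @return data.frame of class `igc_tracts`: donor, start, end (0-based
#'   half-open ancestral interval spanned by the supporting PSVs),
#'   n_psvs, flank_ok.
#' @export
detect_igc <- function(copy_seq, label, catalog, min_run = 5,
                       donors = NULL) {
  stopifnot(label %in% catalog$paralogs)
  empty <- data.frame(donor = character(0), start = integer(0),
                      end = integer(0), n_psvs = integer(0),
                      flank_ok = logical(0))
  class(empty) <- c("igc_tracts", "data.frame")
  if (length(catalog$positions) == 0L) return(empty)
  copy_ch <- seq_chars(toupper(copy_seq))
  copy_al <- copy_ch[catalog$positions + 1L]
  if (is.null(donors)) donors <- setdiff(catalog$paralogs, label)
  p_al <- catalog$alleles[label, ]

  cand <- list()
  for (q in donors) {
    q_al <- catalog$alleles[q, ]
    disc <- which(p_al != q_al)          # P/Q-discriminating PSVs
    if (length(disc) < min_run) next
    isq <- copy_al[disc] == q_al[disc]   # copy carries donor allele
    r <- rle(isq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      run_idx <- disc[starts[k]:ends[k]]
      ## flanking discriminating PSVs must match P
      left_ok <- starts[k] == 1L ||
        copy_al[disc[starts[k] - 1L]] == p_al[disc[starts[k] - 1L]]
      right_ok <- ends[k] == length(disc) ||
        copy_al[disc[ends[k] + 1L]] == p_al[disc[ends[k] + 1L]]
      if (!left_ok || !right_ok) next
      cand[[length(cand) + 1L]] <- data.frame(
        donor = q, start = catalog$positions[min(run_idx)],
        end = catalog$positions[max(run_idx)] + 1L,
        n_psvs = length(run_idx),
        flank_ok = starts[k] > 1L && ends[k] < length(disc),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  ## resolve overlaps: longest run first, then lexicographic donor
  cand <- cand[order(-cand$n_psvs, cand$donor), , drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0L ||
        all(interval_overlap(cand$start[i], cand$end[i],
                             kept$start, kept$end) == 0)) {
      kept <- rbind(kept, cand[i, ])
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("igc_tracts", "data.frame")
  kept
}

#' Detect IGC tracts across all copies of a call set
#'
#' @param copies data.frame with `copy_id`, `paralog`, `haplotype`,
#'   `sequence` columns (e.g. labelled discovery output or simulator
#'   truth extraction).
#' @param catalog a [build_psv_catalog()] result.
#' @param min_run minimum supporting PSV count.
#' @return data.frame: haplotype, copy_id, acceptor, donor, start, end,
#'   n_psvs, flank_ok.
#' @export
detect_igc_all <- function(copies, catalog, min_run = 5) {
  rows <- list()
  for (i in seq_len(nrow(copies))) {
    if (!copies$paralog[i] %in% catalog$paralogs) next
    tr <- detect_igc(copies$sequence[i], copies$paralog[i], catalog,
                     min_run = min_run)
    if (nrow(tr)) {
      tr$haplotype <- copies$haplotype[i]
      tr$copy_id <- copies$copy_id[i]
      tr$acceptor <- copies$paralog[i]
      rows[[length(rows) + 1L]] <- tr
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(haplotype = character(0), copy_id = character(0),
                      acceptor = character(0), donor = character(0),
                      start = integer(0), end = integer(0),
                      n_psvs = integer(0), flank_ok = logical(0)))
  }
  out <- do.call(rbind, rows)
  out[, c("haplotype", "copy_id", "acceptor", "donor", "start", "end",
          "n_psvs", "flank_ok")]
}

#' Donor/acceptor directionality of IGC
#'
#' Counts tracts per ordered (donor, acceptor) pair and summarises, per
#' paralog, the donor:acceptor asymmetry
#' `(donor events - acceptor events) / (donor + acceptor)` with a
#' two-sided binomial test against symmetric exchange.
#'
#' @param tracts data.frame with `donor` and `acceptor` columns.
#' @return list with `pairs` (donor, acceptor, n) and `asymmetry`
#'   (paralog, donor_events, acceptor_events, asymmetry, p_value).
#' @export
igc_directionality <- function(tracts) {
  if (nrow(tracts) == 0L) {
    return(list(pairs = data.frame(donor = character(0),
                                   acceptor = character(0), n = integer(0)),
                asymmetry = data.frame(paralog = character(0),
                                       donor_events = integer(0),
                                       acceptor_events = integer(0),
                                       asymmetry = numeric(0),
                                       p_value = numeric(0))))
  }
  tab <- as.data.frame(table(donor = tracts$donor,
                             acceptor = tracts$acceptor),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  rownames(tab) <- NULL
  paralogs <- sort(unique(c(tracts$donor, tracts$acceptor)))
  asym <- do.call(rbind, lapply(paralogs, function(p) {
    d <- sum(tracts$donor == p)
    a <- sum(tracts$acceptor == p)
    pv <- if (d + a > 0) stats::binom.test(d, d + a, 0.5)$p.value else NA_real_
    data.frame(paralog = p, donor_events = d, acceptor_events = a,
               asymmetry = if (d + a > 0) (d - a) / (d + a) else NA_real_,
               p_value = pv, stringsAsFactors = FALSE)
  }))
  list(pairs = tab, asymmetry = asym)
}

#' IGC hotspots by genomic bin
#'
#' Tract acceptor coordinates are binned at fixed width; hotspots are the
#' bins whose count exceeds the 95th percentile of non-zero bins.
#'
#' @param tracts data.frame with genomic `gstart`/`gend` columns (or
#'   ancestral `start`/`end` when all copies share a coordinate system).
#' @param bin_width bin width, bp.
#' @param percentile hotspot threshold over non-zero bins.
#' @return data.frame: bin_start, bin_end, n_tracts, hotspot.
#' @export
igc_hotspots <- function(tracts, bin_width = 1000, percentile = 0.95) {
  if (nrow(tracts) == 0L) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      n_tracts = integer(0), hotspot = logical(0)))
  }
  scol <- if ("gstart" %in% names(tracts)) "gstart" else "start"
  ecol <- if ("gend" %in% names(tracts)) "gend" else "end"
  lo <- 0L
  hi <- max(tracts[[ecol]])
  bins <- seq.int(lo, hi + bin_width, by = bin_width)
  counts <- vapply(head(seq_along(bins), -1L), function(i) {
    sum(interval_overlap(tracts[[scol]], tracts[[ecol]],
                         bins[i], bins[i + 1L]) > 0)
  }, integer(1))
  nz <- counts[counts > 0]
  thr <- if (length(nz)) quantile(nz, percentile, names = FALSE) else Inf
  hot <- counts > 0 & counts >= thr
  ## all non-zero bins tied: nothing stands out
  if (length(nz) > 1L && stats::var(nz) == 0) hot[] <- FALSE
  data.frame(bin_start = head(bins, -1L), bin_end = tail(bins, -1L),
             n_tracts = counts, hotspot = hot)
}

#' Flag windows overlapping IGC tracts
#'
#' @param windows data.frame with `start`/`end` columns (0-based
#'   half-open), e.g. selection-scan windows.
#' @param tracts data.frame with `start`/`end` tract intervals in the same
#'   coordinate system.
#' @return `windows` with a logical `igc_overlap` column.
#' @export
annotate_windows_igc <- function(windows, tracts) {
  windows$igc_overlap <- vapply(seq_len(nrow(windows)), function(i) {
    nrow(tracts) > 0L &&
      any(interval_overlap(windows$start[i], windows$end[i],
                           tracts$start, tracts$end) > 0)
  }, logical(1))
  windows
}
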