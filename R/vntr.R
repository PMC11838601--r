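## positions (1-based) where `motif` occurs in `protein`
motif_positions <- function(protein, motif) {
  hits <- gregexpr(motif, protein, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Segment the coding VNTR of a protein
#'
#' Scans the protein for tandem repeat units of the final-coding-exon
#' VNTR: units beginning "SADD" (two alternating unit lengths are allowed
#' within a SADD run) and units of the MIISR type (anchored on the "ISR"
#' substring at offset 2). Unit boundaries are the starts of consecutive
#' motifs; a trailing unit is counted when the remaining residues reach
#' its run's unit length. Maximal tandem runs are reported in order, and
#' the frame-switch structure is summarised as `(a, b, c)`: the unit
#' counts of the first SADD run, the MIISR run, and the second SADD run.
#'
#' @param protein protein sequence.
#' @param max_unit maximum residue span between consecutive unit starts
#'   still considered tandem.
#' @return list of class `vntr_profile`: `a`, `b`, `c`, `runs`
#'   (data.frame: type, n_units, start, unit_lengths),
#'   `sadd_unit_lengths`, `miisr_unit_lengths`, `domain_aa`.
#' @export
segment_vntr_protein <- function(protein, max_unit = 60L) {
  empty <- list(a = 0L, b = 0L, c = 0L,
                runs = data.frame(type = character(0), n_units = integer(0),
                                  start = integer(0),
                                  unit_lengths = character(0)),
                sadd_unit_lengths = integer(0),
                miisr_unit_lengths = integer(0), domain_aa = 0L)
  class(empty) <- "vntr_profile"
  if (is.na(protein) || nchar(protein) < 4L) return(empty)

  sadd <- motif_positions(protein, "SADD")
  isr <- motif_positions(protein, "ISR")
  miisr <- if (length(isr)) {
    (isr - 2L)[isr >= 3L &
                 substring(protein, isr - 2L, isr - 1L) == "MI"]
  } else integer(0)
  starts <- sort(c(sadd, miisr))
  if (length(starts) == 0L) return(empty)
  types <- ifelse(starts %in% sadd, "SADD", "MIISR")

  ## unit length = distance to the next unit start; tandem when within
  ## max_unit. The final unit of each tandem stretch takes its
  ## predecessor's length (or the stretch's modal length).
  n <- length(starts)
  lens <- integer(n)
  tandem_next <- logical(n)
  if (n > 1L) {
    d <- diff(starts)
    lens[-n] <- d
    tandem_next[-n] <- d <= max_unit
  }
  ## assign trailing-unit lengths and drop isolated motifs that cannot
  ## form a tandem array
  segments <- split(seq_len(n),
                    cumsum(c(1L, as.integer(!tandem_next[-n]))))
  runs <- list()
  for (seg in segments) {
    if (length(seg) < 2L) next   # an isolated motif is not an array
    seg_lens <- lens[head(seg, -1L)]
    remaining <- nchar(protein) - starts[seg[length(seg)]] + 1L
    keep <- seg
    ## the trailing unit counts when enough residues remain for the
    ## shortest unit type seen in this array (unit lengths may alternate)
    if (remaining < min(seg_lens)) keep <- head(seg, -1L)
    else lens[seg[length(seg)]] <- min(remaining, max(seg_lens))
    if (length(keep) < 2L) next
    ## split the segment into runs of one motif type
    r <- rle(types[keep])
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      idx <- keep[begins[k]:ends[k]]
      runs[[length(runs) + 1L]] <- data.frame(
        type = r$values[k], n_units = length(idx),
        start = starts[idx[1]],
        unit_lengths = paste(lens[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(runs) == 0L) return(empty)
  runs <- do.call(rbind, runs)

  ## (a, b, c): first SADD run, MIISR run, second SADD run
  abc <- c(a = 0L, b = 0L, c = 0L)
  phase <- 1L
  for (k in seq_len(nrow(runs))) {
    if (runs$type[k] == "SADD" && phase == 1L) {
      abc["a"] <- runs$n_units[k]; phase <- 2L
    } else if (runs$type[k] == "MIISR" && phase <= 2L) {
      abc["b"] <- runs$n_units[k]; phase <- 3L
    } else if (runs$type[k] == "SADD" && phase == 3L) {
      abc["c"] <- runs$n_units[k]; phase <- 4L
    }
  }
  unit_lens <- function(type) {
    sel <- runs$type == type
    sort(unique(as.integer(unlist(strsplit(runs$unit_lengths[sel], ",")))))
  }
  out <- list(a = unname(abc["a"]), b = unname(abc["b"]),
              c = unname(abc["c"]), runs = runs,
              sadd_unit_lengths = unit_lens("SADD"),
              miisr_unit_lengths = unit_lens("MIISR"),
              domain_aa = sum(as.integer(unlist(
                strsplit(runs$unit_lengths, ",")))))
  class(out) <- "vntr_profile"
  out
}

#' @export
print.vntr_profile <- function(x, ...) {
  cat("VNTR profile: (a, b, c) = (", x$a, ",", x$b, ",", x$c, ")\n")
  cat("  SADD unit lengths: ",
      paste(x$sadd_unit_lengths, collapse = "/"),
      "; MIISR unit lengths: ",
      paste(x$miisr_unit_lengths, collapse = "/"), "\n", sep = "")
  cat("  repeat domain:", x$domain_aa, "aa\n")
  invisible(x)
}

#' Find the longest DNA tandem array with a minimum period
#'
#' Offset self-matching: for each candidate period p, positions where
#' `seq[i] == seq[i + p]` are collected and the longest interval with at
#' least `min_frac` matching positions is taken; the longest array over
#' all periods with `p >= min_period` is returned (ties to the smallest
#' period, so a p-array is not reported as its own multiple).
#'
#' @param dna DNA sequence.
#' @param min_period minimum repeat period, bp.
#' @param max_period maximum period searched, bp.
#' @param min_frac minimum offset-match fraction within the array.
#' @param min_copies minimum copy number of a reported array.
#' @return data.frame with one row (start, end 0-based half-open, period,
#'   copies rounded to one decimal) or zero rows when nothing is found.
#' @export
find_vntr_dna <- function(dna, min_period = 40L, max_period = 250L,
                          min_frac = 0.9, min_copies = 2) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = numeric(0))
  L <- nchar(dna)
  if (L < 2L * min_period) return(empty)
  raw <- charToRaw(toupper(dna))
  best <- NULL
  for (p in min_period:min(max_period, L %/% 2L)) {
    m <- raw[seq_len(L - p)] == raw[(p + 1L):L]
    ## best-scoring window over match runs (match +1, mismatch -3, the
    ## weighting that stops arrays from bleeding into random flanks),
    ## then filtered on the offset-match fraction
    r <- rle(m)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    score <- ifelse(r$values, r$lengths, -3L * r$lengths)
    ## Kadane over runs, window anchored at match runs
    win_best <- NULL; best_sc <- 0L
    cur <- 0L; cur_start <- NA_integer_
    for (i in seq_along(score)) {
      if (cur <= 0L) {
        if (!r$values[i]) next
        cur <- 0L
        cur_start <- begins[i]
      }
      cur <- cur + score[i]
      if (r$values[i] && cur > best_sc) {
        best_sc <- cur
        win_best <- c(cur_start, ends[i])
      }
    }
    if (is.null(win_best)) next
    frac <- mean(m[win_best[1]:win_best[2]])
    if (frac < min_frac) next
    ## reject arrays whose fundamental period is below min_period (a
    ## q-periodic array also matches at every multiple of q)
    divs <- seq_len(p - 1L)
    divs <- divs[p %% divs == 0L & divs < min_period]
    sub_periodic <- FALSE
    for (q in divs) {
      i1 <- win_best[1]; i2 <- min(win_best[2], L - q)
      if (i2 > i1) {
        mq <- raw[i1:i2] == raw[(i1 + q):(i2 + q)]
        if (mean(mq) >= min_frac) {
          sub_periodic <- TRUE
          break
        }
      }
    }
    if (sub_periodic) next
    span <- win_best[2] - win_best[1] + 1L + p
    copies <- span / p
    if (copies < min_copies) next
    if (is.null(best) || span > best$span) {
      best <- list(start = win_best[1] - 1L,
                   end = win_best[1] - 1L + span,
                   period = p, span = span,
                   copies = round(copies, 1))
    }
  }
  if (is.null(best)) return(empty)
  data.frame(start = best$start, end = best$end, period = best$period,
             copies = best$copies)
}
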