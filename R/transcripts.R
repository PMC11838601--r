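## Seed-and-chain spliced alignment of a cDNA read to one locus.
## Exact k-mer anchors are grouped by diagonal into exon blocks; gaps of
## at least `min_intron` bp on the locus between consecutive blocks are
## treated as introns (free), smaller locus gaps are absorbed as
## mismatches. Adequate for clean junctions; not a general-purpose
## spliced aligner.
align_spliced <- function(read, locus, k = 15L, stride = 3L,
                          min_intron = 30L) {
  Lr <- nchar(read); Ll <- nchar(locus)
  if (Lr < k || Ll < k) return(NULL)
  ## index locus k-mers -> first position (duplicates rare at this k)
  lpos_all <- seq_len(Ll - k + 1L)
  lk <- kmers_at(locus, k, lpos_all)
  rpos <- seq.int(1L, Lr - k + 1L, by = stride)
  rk <- kmers_at(read, k, rpos)
  m <- match(rk, lk)
  ok <- !is.na(m)
  if (!any(ok)) return(NULL)
  rp <- rpos[ok]; lp <- m[ok]
  diag <- lp - rp
  ## blocks: consecutive anchors on one diagonal
  o <- order(diag, rp)
  rp <- rp[o]; lp <- lp[o]; diag <- diag[o]
  brk <- c(0L, which(diff(diag) != 0L | diff(rp) > 3L * k), length(rp))
  blocks <- list()
  for (b in seq_len(length(brk) - 1L)) {
    ii <- (brk[b] + 1L):brk[b + 1L]
    blocks[[b]] <- list(r1 = min(rp[ii]), r2 = max(rp[ii]) + k - 1L,
                        d = diag[ii][1], n = length(ii))
  }
  ## chain blocks left-to-right on the read, requiring increasing locus
  blocks <- blocks[order(vapply(blocks, `[[`, integer(1), "r1"))]
  chain <- list()
  last_r <- 0L; last_l <- 0L
  for (bl in blocks) {
    l1 <- bl$r1 + bl$d
    if (bl$r1 > last_r && l1 > last_l) {
      chain[[length(chain) + 1L]] <- bl
      last_r <- bl$r2
      last_l <- bl$r2 + bl$d
    }
  }
  if (length(chain) == 0L) return(NULL)
  covered <- sum(vapply(chain, function(b) b$r2 - b$r1 + 1L, integer(1)))
  if (covered < 0.5 * Lr) return(NULL)

  ## extend blocks to cover the whole read; uncovered gaps join the left
  ## block (or the first block for the 5' end)
  nb <- length(chain)
  exon_r1 <- integer(nb); exon_r2 <- integer(nb)
  for (i in seq_len(nb)) {
    exon_r1[i] <- if (i == 1L) 1L else chain[[i]]$r1
    exon_r2[i] <- if (i < nb) chain[[i + 1L]]$r1 - 1L else Lr
  }
  ## clip to locus bounds along each diagonal
  mism <- 0L
  exons <- matrix(0L, nrow = nb, ncol = 2L)
  aligned <- 0L
  for (i in seq_len(nb)) {
    d <- chain[[i]]$d
    r1 <- max(exon_r1[i], 1L - d)
    r2 <- min(exon_r2[i], Ll - d)
    if (r2 < r1) return(NULL)
    rs <- substr(read, r1, r2)
    ls <- substr(locus, r1 + d, r2 + d)
    mism <- mism + hamming(rs, ls)
    exons[i, ] <- c(r1 + d - 1L, r2 + d)   # 0-based half-open on locus
    aligned <- aligned + (r2 - r1 + 1L)
  }
  if (aligned < 0.5 * Lr) return(NULL)
  ## merge exon rows separated by less than min_intron on the locus
  keep <- list(exons[1, ])
  for (i in seq_len(nb)[-1]) {
    prev <- keep[[length(keep)]]
    if (exons[i, 1] - prev[2] < min_intron) {
      prev[2] <- exons[i, 2]
      keep[[length(keep)]] <- prev
    } else {
      keep[[length(keep) + 1L]] <- exons[i, ]
    }
  }
  exons <- do.call(rbind, keep)
  list(mismatches = mism, exons = exons, aligned = aligned,
       coverage = aligned / Lr)
}

#' Assign a cDNA read to its best-matching locus
#'
#' Spliced-aligns the read to every candidate locus and applies the
#' mismatch-delta rule: the assignment is `unique` only when the
#' second-best locus accumulates at least one more mismatch than the
#' best; equal mismatch counts give `ambiguous`, and reads aligning to
#' less than half their length everywhere are `unaligned`. FLNC cDNA is
#' orientation-resolved, so only the forward strand is aligned.
#'
#' @param read cDNA sequence.
#' @param loci named character vector of locus sequences.
#' @param min_delta mismatch margin required for a unique call.
#' @return list of class `read_assignment`: status
#'   ("unique"/"ambiguous"/"unaligned"), locus, mismatches,
#'   second_mismatches, exons (matrix of 0-based half-open locus
#'   intervals).
#' @export
assign_read <- function(read, loci, min_delta = 1L) {
  if (length(loci) == 0L) stop("no candidate loci")
  fits <- lapply(loci, function(l) align_spliced(read, l))
  ok <- !vapply(fits, is.null, logical(1))
  out <- list(status = "unaligned", locus = NA_character_,
              mismatches = NA_integer_, second_mismatches = NA_integer_,
              exons = NULL)
  class(out) <- "read_assignment"
  if (!any(ok)) return(out)
  mm <- vapply(fits[ok], `[[`, integer(1), "mismatches")
  names(mm) <- names(loci)[ok]
  o <- order(mm)
  best <- o[1]
  out$locus <- names(mm)[best]
  out$mismatches <- mm[[best]]
  out$exons <- fits[ok][[best]]$exons
  if (length(mm) == 1L) {
    out$status <- "unique"
    return(out)
  }
  out$second_mismatches <- mm[[o[2]]]
  out$status <- if (out$second_mismatches - out$mismatches >= min_delta)
    "unique" else "ambiguous"
  out
}

#' Assign many reads to loci
#' @param reads named character vector of cDNA reads.
#' @param loci named character vector of locus sequences.
#' @param min_delta mismatch margin for a unique call.
#' @return data.frame: read, status, locus, mismatches,
#'   second_mismatches, n_exons, exon_chain (junction string); exon
#'   matrices in `attr(, "exons")`.
#' @export
assign_reads <- function(reads, loci, min_delta = 1L) {
  res <- lapply(reads, assign_read, loci = loci, min_delta = min_delta)
  exon_chain <- vapply(res, function(r) {
    if (is.null(r$exons)) return("")
    paste(apply(r$exons, 1L, paste, collapse = "-"), collapse = ",")
  }, character(1))
  out <- data.frame(
    read = names(reads),
    status = vapply(res, `[[`, character(1), "status"),
    locus = vapply(res, `[[`, character(1), "locus"),
    mismatches = vapply(res, function(r) as.integer(r$mismatches),
                        integer(1)),
    second_mismatches = vapply(res, function(r)
      as.integer(r$second_mismatches), integer(1)),
    n_exons = vapply(res, function(r)
      if (is.null(r$exons)) 0L else nrow(r$exons), integer(1)),
    exon_chain = exon_chain,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exons") <- lapply(res, `[[`, "exons")
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Call the longest open reading frame
#'
#' Scans the three forward frames (full-length cDNA is
#' orientation-resolved) for ATG-initiated ORFs, keeping the longest;
#' ties go to the 5'-most start. An ORF without an in-frame stop runs
#' open to the end of the sequence.
#'
#' @param x nucleotide sequence.
#' @param min_codons minimum ORF length in codons (start included);
#'   shorter ORFs return `NA`.
#' @return the protein string without the terminal stop, or
#'   `NA_character_`.
#' @export
call_orf <- function(x, min_codons = 50L) {
  x <- toupper(x)
  L <- nchar(x)
  if (L < 3L) return(NA_character_)
  best <- NULL  # list(len, start_nt, protein)
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 1L) next
    starts_nt <- frame + (seq_len(n_cod) - 1L) * 3L + 1L
    codons <- substring(x, starts_nt, starts_nt + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    atg_idx <- which(codons == "ATG")
    for (a in atg_idx) {
      stp <- stop_idx[stop_idx > a]
      end_idx <- if (length(stp)) stp[1] - 1L else n_cod
      len <- end_idx - a + 1L
      if (len < min_codons) next
      if (is.null(best) || len > best$len ||
          (len == best$len && starts_nt[a] < best$start_nt)) {
        best <- list(len = len, start_nt = starts_nt[a],
                     protein = paste(vapply(
                       codons[a:end_idx],
                       function(cd) as.character(
                         Biostrings::GENETIC_CODE[[cd]]),
                       character(1)), collapse = ""))
      }
    }
  }
  if (is.null(best)) NA_character_ else best$protein
}

#' Classify a protein's translation start
#'
#' Matches the first four residues against the start classes observed in
#' the gene family: the canonical first coding exon (MFCC), the
#' alternate initiation co-opted from an acyl-CoA synthetase exon (MVKL),
#' the likely ancestral start (MRVR), and the signal-peptide-bearing
#' start (MRLR).
#' @param protein protein string.
#' @return one of "MFCC", "MVKL", "MRVR", "MRLR", "other".
#' @export
classify_start <- function(protein) {
  if (is.na(protein) || nchar(protein) < 4L) return("other")
  pre <- substr(protein, 1L, 4L)
  if (pre %in% c("MFCC", "MVKL", "MRVR", "MRLR")) pre else "other"
}

#' Build isoform gene models from unique read assignments
#'
#' Unique-status multi-exon reads are grouped by identical exon-junction
#' chain per locus; groups supported by at least `min_support` molecules
#' become isoforms, ranked by abundance (ties broken by length, longest
#' first) and suffixed `_1`, `_2`, ... Each isoform carries the consensus
#' ORF of its supporting reads. Mono-exonic chains are excluded.
#'
#' @param assignments data.frame from [assign_reads()].
#' @param reads named character vector of the read sequences (for ORF
#'   calling).
#' @param min_support minimum supporting molecules per isoform.
#' @param min_codons ORF floor passed to [call_orf()].
#' @return data.frame of class `gene_models`: locus, isoform, rank,
#'   n_support, n_exons, exon_chain, protein, start_class, orf_aa.
#' @export
build_gene_models <- function(assignments, reads, min_support = 5L,
                              min_codons = 50L) {
  sel <- assignments$status == "unique" & assignments$n_exons >= 2L
  a <- assignments[sel, , drop = FALSE]
  empty <- data.frame(locus = character(0), isoform = character(0),
                      rank = integer(0), n_support = integer(0),
                      n_exons = integer(0), exon_chain = character(0),
                      protein = character(0), start_class = character(0),
                      orf_aa = integer(0))
  class(empty) <- c("gene_models", "data.frame")
  if (nrow(a) == 0L) return(empty)
  ## junction chain: internal boundaries only (terminal ends may ragged)
  junc <- vapply(seq_len(nrow(a)), function(i) {
    iv <- strsplit(a$exon_chain[i], ",", fixed = TRUE)[[1]]
    b <- unlist(strsplit(iv, "-", fixed = TRUE))
    paste(a$locus[i], paste(b[-c(1L, length(b))], collapse = "|"),
          sep = ":")
  }, character(1))
  rows <- list()
  for (key in unique(junc)) {
    ii <- which(junc == key)
    if (length(ii) < min_support) next
    locus <- a$locus[ii[1]]
    prots <- vapply(a$read[ii], function(r)
      as.character(call_orf(reads[[r]], min_codons = min_codons)),
      character(1))
    prots <- prots[!is.na(prots)]
    protein <- if (length(prots)) names(sort(table(prots),
                                             decreasing = TRUE))[1] else
      NA_character_
    span <- sum(vapply(strsplit(strsplit(a$exon_chain[ii[1]], ",")[[1]],
                                "-"), function(b) {
      diff(as.integer(b))
    }, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      locus = locus, n_support = length(ii), n_exons = a$n_exons[ii[1]],
      exon_chain = a$exon_chain[ii[1]], protein = protein,
      start_class = classify_start(protein),
      orf_aa = ifelse(is.na(protein), NA_integer_, nchar(protein)),
      span = span, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  ## rank within locus by abundance, ties by span (longest first)
  out <- out[order(out$locus, -out$n_support, -out$span), , drop = FALSE]
  out$rank <- unlist(lapply(split(seq_len(nrow(out)), out$locus),
                            seq_along))[order(order(out$locus))]
  out$rank <- stats::ave(seq_len(nrow(out)), out$locus,
                         FUN = seq_along)
  out$isoform <- paste0(out$locus, "_", out$rank)
  out <- out[, c("locus", "isoform", "rank", "n_support", "n_exons",
                 "exon_chain", "protein", "start_class", "orf_aa")]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Detect fusion transcripts spanning an adjacent gene and the family
#' locus
#'
#' A read is a fusion when its exon chain (in haplotype coordinates)
#' overlaps exons of an adjacent annotated gene and exons of the family
#' locus, in that 5' to 3' order. Reports exon counts on each side and
#' the longest ORF of the read.
#'
#' @param assignments data.frame from [assign_reads()] run against the
#'   haplotype region containing both genes (exon coordinates in that
#'   region's system).
#' @param reads named character vector of read sequences.
#' @param partner_exons,family_exons data.frames with start/end (0-based
#'   half-open) exon intervals in region coordinates.
#' @param min_codons ORF floor for the fused ORF.
#' @return data.frame: read, n_partner_exons, n_family_exons, orf_aa.
#' @export
detect_fusions <- function(assignments, reads, partner_exons,
                           family_exons, min_codons = 50L) {
  exons_list <- attr(assignments, "exons")
  rows <- list()
  for (i in seq_len(nrow(assignments))) {
    ex <- exons_list[[i]]
    if (is.null(ex)) next
    hits_p <- vapply(seq_len(nrow(ex)), function(j) {
      any(interval_overlap(ex[j, 1], ex[j, 2], partner_exons$start,
                           partner_exons$end) > 0)
    }, logical(1))
    hits_f <- vapply(seq_len(nrow(ex)), function(j) {
      any(interval_overlap(ex[j, 1], ex[j, 2], family_exons$start,
                           family_exons$end) > 0)
    }, logical(1))
    if (!any(hits_p) || !any(hits_f)) next
    if (max(which(hits_p)) > min(which(hits_f))) next  # must be 5'->3'
    prot <- call_orf(reads[[assignments$read[i]]],
                     min_codons = min_codons)
    rows[[length(rows) + 1L]] <- data.frame(
      read = assignments$read[i],
      n_partner_exons = sum(hits_p), n_family_exons = sum(hits_f),
      orf_aa = ifelse(is.na(prot), NA_integer_, nchar(prot)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(read = character(0), n_partner_exons = integer(0),
                      n_family_exons = integer(0), orf_aa = integer(0)))
  }
  do.call(rbind, rows)
}
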