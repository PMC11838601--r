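#' Build a unique-k-mer index over paralog gene models
#'
#' Extracts all k-mers from each paralog's transcript models, discards
#' k-mers present anywhere in the background genome (either strand), and
#' annotates each surviving k-mer with the set of paralogs containing it.
#' A transcript position is "uniquely identifying" for a paralog when its
#' k-mer occurs in that paralog's models only. K-mers are
#' strand-collapsed (canonical form).
#'
#' @param transcripts named list: paralog label -> character vector of
#'   transcript sequences.
#' @param background character vector of background genome sequences
#'   (the genome minus the gene models themselves).
#' @param k k-mer length (odd, 15-63).
#' @return list of class `kmer_index`: `k`, `kmers` (canonical strings),
#'   `owners` (list of paralog sets per k-mer), `positions` (data.frame
#'   paralog/kmer_id, one row per transcript position),
#'   `unique_positions` (named count per paralog),
#'   `background_excluded` (count), `groups` (initial identity
#'   partition).
#' @export
build_kmer_index <- function(transcripts, background, k = 31L) {
  if (k %% 2L != 1L || k < 15L || k > 63L) stop("k must be odd in [15, 63]")
  if (any(vapply(transcripts, function(x) any(nchar(x) < k), logical(1)))) {
    stop("transcript shorter than k")
  }
  ## per-paralog k-mers at every position
  pos_rows <- list()
  for (p in names(transcripts)) {
    for (tx in transcripts[[p]]) {
      km <- canonical_kmer(kmers_at(tx, k, seq_len(nchar(tx) - k + 1L)))
      pos_rows[[length(pos_rows) + 1L]] <-
        data.frame(paralog = p, kmer = km, stringsAsFactors = FALSE)
    }
  }
  pos <- do.call(rbind, pos_rows)
  all_kmers <- unique(pos$kmer)

  ## background screen via PDict (both strands are covered because the
  ## patterns are canonical and we scan background plus its complement)
  if (length(background) && length(all_kmers)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_kmers))
    subj <- Biostrings::DNAStringSet(background)
    counts <- rowSums(Biostrings::vcountPDict(pd, subj)) +
      rowSums(Biostrings::vcountPDict(pd,
                                      Biostrings::reverseComplement(subj)))
    in_bg <- counts > 0L
  } else {
    in_bg <- rep(FALSE, length(all_kmers))
  }
  background_excluded <- sum(in_bg)
  kept <- all_kmers[!in_bg]
  pos <- pos[pos$kmer %in% kept, , drop = FALSE]
  pos$kmer_id <- match(pos$kmer, kept)

  owners <- lapply(split(pos$paralog, pos$kmer_id), function(x)
    sort(unique(x)))
  owners <- owners[as.character(seq_along(kept))]
  uniq <- vapply(seq_along(kept), function(i)
    length(owners[[i]]) == 1L, logical(1))
  unique_positions <- vapply(names(transcripts), function(p) {
    sum(pos$paralog == p & uniq[pos$kmer_id])
  }, integer(1))

  obj <- list(k = k, kmers = kept, owners = owners,
              positions = pos[, c("paralog", "kmer_id")],
              unique_positions = unique_positions,
              background_excluded = background_excluded,
              groups = as.list(setNames(names(transcripts),
                                        names(transcripts))))
  class(obj) <- "kmer_index"
  obj
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, ";", length(x$kmers), "family k-mers (",
      x$background_excluded, "background-excluded )\n")
  print(group_unique_counts(x))
  invisible(x)
}

## per-group uniquely identifying position counts under a partition
group_unique_counts <- function(index, groups = index$groups) {
  member_of <- unlist(lapply(names(groups), function(g) {
    setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  kmer_grp <- vapply(index$owners, function(ow) {
    gs <- unique(member_of[ow])
    if (length(gs) == 1L) gs else NA_character_
  }, character(1))
  vapply(names(groups), function(g) {
    sum(!is.na(kmer_grp[index$positions$kmer_id]) &
          kmer_grp[index$positions$kmer_id] == g)
  }, integer(1))
}

#' Merge paralogs into detectable groups
#'
#' While some group has fewer than `min_unique` uniquely identifying
#' k-mer positions, the deficient group with the fewest unique positions
#' (ties broken lexicographically) is merged with the group sharing the
#' greatest number of its k-mers (ties lexicographic); uniqueness is then
#' recomputed at group level. Terminates when every group passes or a
#' single group remains. Group labels join their member paralogs with
#' "/".
#'
#' @param index a [build_kmer_index()] result.
#' @param min_unique detectability floor (unique positions per group).
#' @return the index with `groups` replaced by the merged partition and a
#'   `group_unique` count vector.
#' @export
merge_groups <- function(index, min_unique = 5L) {
  groups <- index$groups
  repeat {
    counts <- group_unique_counts(index, groups)
    deficient <- names(counts)[counts < min_unique]
    if (length(deficient) == 0L || length(groups) == 1L) break
    g <- deficient[order(counts[deficient], deficient)][1]
    ## partner: group sharing the most k-mers with g
    member_of <- unlist(lapply(names(groups), function(gg) {
      setNames(rep(gg, length(groups[[gg]])), groups[[gg]])
    }))
    g_kmers <- which(vapply(index$owners, function(ow)
      any(member_of[ow] == g), logical(1)))
    others <- setdiff(names(groups), g)
    shared <- vapply(others, function(og) {
      sum(vapply(index$owners[g_kmers], function(ow)
        any(member_of[ow] == og), logical(1)))
    }, integer(1))
    partner <- others[order(-shared, others)][1]
    members <- sort(c(groups[[g]], groups[[partner]]))
    groups[[g]] <- NULL
    groups[[partner]] <- NULL
    groups[[paste(members, collapse = "/")]] <- members
    groups <- groups[order(names(groups))]
  }
  index$groups <- groups
  index$group_unique <- group_unique_counts(index, groups)
  index
}

#' Classify short RNA-seq reads by paralog group
#'
#' A read containing at least one k-mer unique to exactly one group, and
#' none unique to any other group, is assigned to that group; reads with
#' identifying k-mers from two or more groups, or only family-shared
#' k-mers, are counted as family-ambiguous; reads without any family
#' k-mer are ignored. Reads are scanned on both strands.
#'
#' @param reads named character vector of reads (length >= k).
#' @param index a merged [merge_groups()] index.
#' @return list of class `read_classification`: `counts` (named group
#'   counts), `ambiguous`, `ignored`, `assignments` (per-read group or
#'   NA).
#' @export
classify_reads <- function(reads, index) {
  if (any(nchar(reads) < index$k)) stop("read shorter than k")
  groups <- index$groups
  member_of <- unlist(lapply(names(groups), function(g) {
    setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  kmer_grp <- vapply(index$owners, function(ow) {
    gs <- unique(member_of[ow])
    if (length(gs) == 1L) gs else ""
  }, character(1))
  ## lookup by both orientations so read k-mers need no canonicalising
  keys <- c(index$kmers, revcomp(index$kmers))
  vals <- c(kmer_grp, kmer_grp)

  assignments <- rep(NA_character_, length(reads))
  k <- index$k
  chunk <- 5000L
  for (lo in seq.int(1L, length(reads), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(reads))
    idx <- lo:hi
    nk <- nchar(reads[idx]) - k + 1L
    km <- unlist(lapply(idx, function(i)
      kmers_at(reads[i], k, seq_len(nchar(reads[i]) - k + 1L))),
      use.names = FALSE)
    owner <- vals[match(km, keys)]
    read_of <- rep(idx, nk)
    keep <- !is.na(owner)
    if (!any(keep)) next
    by_read <- split(owner[keep], read_of[keep])
    for (nm in names(by_read)) {
      ug <- unique(by_read[[nm]][by_read[[nm]] != ""])
      assignments[as.integer(nm)] <-
        if (length(ug) == 1L) ug else "ambiguous"
    }
  }
  counts <- vapply(names(groups), function(g)
    sum(assignments == g, na.rm = TRUE), integer(1))
  out <- list(counts = counts,
              ambiguous = sum(assignments == "ambiguous", na.rm = TRUE),
              ignored = sum(is.na(assignments)),
              assignments = setNames(assignments, names(reads)))
  class(out) <- "read_classification"
  out
}

#' Tissue enrichment z-scores and UPGMA clustering
#'
#' Shares are classified counts over the family-classified total of each
#' sample; the z-score of a (group, sample) cell standardises the share
#' against the group's mean and standard deviation across samples, with a
#' one-sided normal p-value for positive enrichment. Groups and samples
#' are clustered by UPGMA on correlation distance (1 - Pearson) between
#' z-score profiles.
#'
#' @param counts group x sample matrix of classified read counts.
#' @return list of class `enrichment`: `share`, `z`, `p`, `group_tree`,
#'   `sample_tree` (hclust objects, NULL when too few rows/columns).
#' @export
enrichment <- function(counts) {
  if (ncol(counts) < 2L || nrow(counts) < 2L) {
    stop("need at least 2 groups and 2 samples")
  }
  totals <- colSums(counts)
  share <- sweep(counts, 2L, pmax(totals, 1L), "/")
  mu <- rowMeans(share)
  sdev <- apply(share, 1L, sd)
  z <- sweep(sweep(share, 1L, mu, "-"), 1L, sdev, "/")
  z[sdev == 0, ] <- NA_real_
  p <- 1 - stats::pnorm(z)
  cordist <- function(m) {
    cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    as.dist(1 - cc)
  }
  zc <- z
  zc[!is.finite(zc)] <- 0
  group_tree <- if (nrow(z) >= 3L)
    stats::hclust(cordist(zc), method = "average") else NULL
  sample_tree <- if (ncol(z) >= 3L)
    stats::hclust(cordist(t(zc)), method = "average") else NULL
  out <- list(share = share, z = z, p = p, group_tree = group_tree,
              sample_tree = sample_tree)
  class(out) <- "enrichment"
  out
}

#' Developmental expression trajectories with a monotonic-trend test
#'
#' For each group and tissue, the classified share is tracked over
#' ordered timepoints; the trend statistic is the Spearman correlation of
#' share with time order, with bootstrap 95% bands over replicate samples
#' within each timepoint. Missing timepoints are left missing, never
#' interpolated.
#'
#' @param counts group x sample matrix of classified counts.
#' @param sample_info data.frame: sample, tissue, timepoint (numeric
#'   order).
#' @param n_boot bootstrap replicates for the bands.
#' @return data.frame: group, tissue, timepoint, share, lo, hi, plus a
#'   `trends` attribute (group, tissue, rho, p_value).
#' @export
developmental_profile <- function(counts, sample_info, n_boot = 200L) {
  stopifnot(all(colnames(counts) %in% sample_info$sample))
  totals <- colSums(counts)
  share <- sweep(counts, 2L, pmax(totals, 1L), "/")
  rows <- list(); trends <- list()
  for (g in rownames(counts)) {
    for (ts in unique(sample_info$tissue)) {
      tps <- sort(unique(sample_info$timepoint[sample_info$tissue == ts]))
      pts <- lapply(tps, function(tp) {
        sm <- sample_info$sample[sample_info$tissue == ts &
                                   sample_info$timepoint == tp]
        share[g, sm]
      })
      est <- vapply(pts, mean, numeric(1))
      band <- t(vapply(pts, function(v) {
        if (length(v) < 2L) return(c(NA_real_, NA_real_))
        bs <- replicate(n_boot, mean(sample(v, replace = TRUE)))
        quantile(bs, c(0.025, 0.975), names = FALSE)
      }, numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, tissue = ts, timepoint = tps, share = est,
        lo = band[, 1], hi = band[, 2], stringsAsFactors = FALSE)
      if (length(tps) >= 2L) {
        per_sample <- unlist(pts)
        tp_of <- rep(tps, vapply(pts, length, integer(1)))
        ct <- suppressWarnings(
          stats::cor.test(per_sample, tp_of, method = "spearman"))
        trends[[length(trends) + 1L]] <- data.frame(
          group = g, tissue = ts, rho = unname(ct$estimate),
          p_value = ct$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trends") <- if (length(trends)) do.call(rbind, trends) else
    data.frame(group = character(0), tissue = character(0),
               rho = numeric(0), p_value = numeric(0))
  out
}
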