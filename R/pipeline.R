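#' Majority-rule consensus of assigned copies
#'
#' Per paralog label, the modal base at each anchored column across the
#' copies carrying that label — the per-paralog consensus used to build
#' PSV catalogs from a call set.
#' @param copies data.frame with `label` (or `paralog`) and `sequence`
#'   columns, sequences anchored to a common coordinate system.
#' @param core_length optional truncation (e.g. the duplicon core when
#'   copies carry VNTR tails).
#' @return named character vector label -> consensus.
#' @export
estimate_consensus <- function(copies, core_length = NULL) {
  lab <- if ("label" %in% names(copies)) copies$label else copies$paralog
  out <- character(0)
  for (l in sort(unique(lab))) {
    seqs <- copies$sequence[lab == l]
    if (!is.null(core_length)) seqs <- substr(seqs, 1L, core_length)
    len <- min(nchar(seqs))
    seqs <- substr(seqs, 1L, len)
    M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    out[l] <- paste(apply(M, 2L, function(col) {
      names(sort(table(col), decreasing = TRUE))[1]
    }), collapse = "")
  }
  out
}

#' Run the assembly-based family characterisation end to end
#'
#' Discovery (anchor chaining against the ancestral duplicon), locus
#' validation by flanking unique sequence, distance-based tree with
#' bootstrap support, anchored paralog assignment, and the per-sample
#' copy-number table. Anchors are taken from a designated reference
#' haplotype's copies labelled via the truth annotations when `sim` is a
#' simulation, or supplied explicitly.
#'
#' @param assemblies named character vector of haplotype contigs.
#' @param query ancestral duplicon sequence.
#' @param samples data.frame sample/population/hap1/hap2.
#' @param anchors named character vector: copy id (as produced by
#'   discovery, `<contig>_f<i>`) -> paralog label. When `NULL` and
#'   `truth_copies` is given, one anchor per paralog is chosen from the
#'   first haplotypes.
#' @param truth_copies optional truth coordinate table (haplotype,
#'   start, end, strand, paralog) used only to derive anchors.
#' @param min_len,flank discovery and validation parameters, bp.
#' @param n_boot bootstrap replicates for clade support.
#' @param seed RNG seed for the bootstrap.
#' @return list: `copies` (with validation + assigned labels), `tree`,
#'   `assignment`, `cn_table`, `qc`.
#' @export
analyze_family <- function(assemblies, query, samples, anchors = NULL,
                           truth_copies = NULL, min_len = 15000,
                           flank = 30000, n_boot = 100, seed = 1) {
  copies <- find_copies_all(assemblies, query, min_len = min_len)
  copies <- validate_locus(copies, nchar(assemblies), flank = flank)
  qc_copy <- setNames(copies$validation == "pass", copies$copy_id)
  ## haplotype-level QC: every copy on the haplotype validated
  qc <- vapply(names(assemblies), function(h) {
    sel <- copies$contig == h
    !any(copies$validation[sel] != "pass")
  }, logical(1))

  if (is.null(anchors)) {
    if (is.null(truth_copies)) stop("give anchors or truth_copies")
    anchors <- character(0)
    for (p in sort(unique(truth_copies$paralog))) {
      tc <- truth_copies[truth_copies$paralog == p, ][1, ]
      hit <- copies[copies$contig == tc$haplotype &
                      pmin(copies$end, tc$end) -
                        pmax(copies$start, tc$start) >
                        0.5 * (tc$end - tc$start), ]
      if (nrow(hit)) anchors[hit$copy_id[1]] <- p
    }
  }

  seqs <- setNames(copies$sequence, copies$copy_id)
  tree <- bootstrap_support(seqs, n_reps = n_boot, seed = seed)
  assignment <- assign_paralogs(tree, anchors)
  copies$paralog <- assignment$label[match(copies$copy_id,
                                           assignment$copy)]

  asn <- data.frame(haplotype = copies$contig, label = copies$paralog,
                    stringsAsFactors = FALSE)
  cn_table <- copy_number_table(asn, samples, qc = qc)
  list(copies = copies, tree = tree, assignment = assignment,
       cn_table = cn_table, qc = qc)
}
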