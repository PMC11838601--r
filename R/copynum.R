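#' Per-sample copy-number table from paralog assignments
#'
#' Counts labelled copies per haplotype and paralog, pairing the two
#' haplotypes of each sample. Haplotypes failing assembly QC are recorded
#' with missing values and excluded from all downstream statistics; they
#' are never imputed.
#'
#' @param assignments data.frame with `haplotype` and `label` columns (one
#'   row per assigned copy).
#' @param samples data.frame: sample, population, hap1, hap2.
#' @param qc named logical vector: haplotype -> QC pass. Haplotypes absent
#'   from the vector are treated as passing.
#' @param labels paralog labels to tabulate (default: all observed).
#' @return object of class `cn_table`: list with `samples`, `cn` (3-d
#'   array sample x paralog x haplotype-slot) exposed as the data.frame
#'   `long`, and accessors used by the summary functions.
#' @export
copy_number_table <- function(assignments, samples, qc = NULL,
                              labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(assignments$label))
  if (is.null(qc)) qc <- setNames(logical(0), character(0))
  hap_cn <- function(hap) {
    if (!is.na(hap) && hap %in% names(qc) && !qc[[hap]]) {
      return(setNames(rep(NA_integer_, length(labels)), labels))
    }
    sel <- assignments$haplotype == hap
    vapply(labels, function(l) sum(assignments$label[sel] == l),
           integer(1))
  }
  build <- function(haps) {
    m <- matrix(NA_integer_, nrow = length(haps), ncol = length(labels),
                dimnames = list(samples$sample, labels))
    for (i in seq_along(haps)) m[i, ] <- hap_cn(haps[i])
    m
  }
  cn1 <- build(samples$hap1)
  cn2 <- build(samples$hap2)
  obj <- list(samples = samples, labels = labels, hap1 = cn1, hap2 = cn2)
  class(obj) <- "cn_table"
  obj
}

#' @export
print.cn_table <- function(x, ...) {
  cat("cn_table:", nrow(x$samples), "samples x", length(x$labels),
      "paralogs\n")
  tot <- rowSums(x$hap1) + rowSums(x$hap2)
  cat("  total diploid CN range:",
      paste(range(tot, na.rm = TRUE), collapse = "-"), "\n")
  invisible(x)
}

#' Roll paralog columns up into subfamilies
#'
#' Sums member columns before classification, for statements of the form
#' "at least one member of the subfamily is always present".
#' @param table a [copy_number_table()] result.
#' @param subfamilies named list: subfamily label -> member paralogs.
#' @return a new `cn_table` over the subfamily labels.
#' @export
rollup_subfamilies <- function(table, subfamilies) {
  roll <- function(m) {
    out <- vapply(subfamilies, function(members) {
      rowSums(m[, intersect(members, colnames(m)), drop = FALSE])
    }, numeric(nrow(m)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(rownames(m),
                                                         names(subfamilies)))
    out
  }
  obj <- list(samples = table$samples, labels = names(subfamilies),
              hap1 = roll(table$hap1), hap2 = roll(table$hap2))
  class(obj) <- "cn_table"
  obj
}

#' Copy-number heterozygosity of a paralog
#'
#' The frequency of discordant copy numbers between the two haplotypes of
#' a sample, over samples with both haplotypes passing QC.
#' @param table a [copy_number_table()] result.
#' @param paralog paralog label.
#' @return fraction in [0, 1]; `NA` when no sample has both haplotypes.
#' @export
heterozygosity <- function(table, paralog) {
  a <- table$hap1[, paralog]
  b <- table$hap2[, paralog]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' Classify per-paralog copy-number invariance
#'
#' `fixed_single_copy` when every QC-pass haplotype carries exactly one
#' copy; `always_present` when every QC-pass haplotype carries at least
#' one copy but counts vary; otherwise `variable`.
#' @param table a [copy_number_table()] result.
#' @return named character vector per paralog.
#' @export
classify_invariance <- function(table) {
  vapply(table$labels, function(l) {
    v <- c(table$hap1[, l], table$hap2[, l])
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    if (all(v == 1L)) "fixed_single_copy"
    else if (all(v >= 1L)) "always_present"
    else "variable"
  }, character(1))
}

#' Compare total copy number between populations
#'
#' Two-sided Wilcoxon rank-sum test on per-haplotype total copy counts
#' (QC-pass haplotypes only).
#' @param table a [copy_number_table()] result.
#' @param group_a,group_b population labels.
#' @return `htest` from [stats::wilcox.test()].
#' @export
compare_populations <- function(table, group_a, group_b) {
  totals <- function(group) {
    sel <- table$samples$population == group
    if (!any(sel)) stop("empty group: ", group)
    v <- c(rowSums(table$hap1[sel, , drop = FALSE]),
           rowSums(table$hap2[sel, , drop = FALSE]))
    v[!is.na(v)]
  }
  a <- totals(group_a)
  b <- totals(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("empty group after QC")
  ht <- suppressWarnings(stats::wilcox.test(a, b,
                                            alternative = "two.sided"))
  ## complete ties leave the normal approximation undefined; the rank-sum
  ## statistic then sits exactly at its null centre
  if (is.na(ht$p.value)) ht$p.value <- 1
  ht
}
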