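#' Simulate sequencing reads with truth labels
#'
#' Short mode emits fixed-length substrings drawn from the source records
#' (position uniform, strand random); long mode emits full-length copies of
#' the source records, emulating full-length non-chimeric cDNA molecules.
#' Errors are substitutions applied per base at `error_rate`; no indels and
#' no base-quality model.
#'
#' @param source named character vector of source sequences (genome contigs
#'   or transcripts).
#' @param weights sampling weights over the source records. Default: record
#'   length in short mode (uniform coverage), uniform in long mode.
#' @param mode "short" or "long".
#' @param read_length short-read length in bp.
#' @param depth target per-base depth (short mode); used to compute
#'   `n_reads = depth * total_bp / read_length` when `n_reads` is missing.
#' @param n_reads explicit number of reads.
#' @param error_rate per-base substitution error rate in [0, 1).
#' @param seed optional seed (current stream used when `NULL`).
#' @param stranded if `FALSE` (default) short reads are drawn from either
#'   strand with equal probability; long reads are always emitted in source
#'   orientation (FLNC reads are orientation-resolved).
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read, source, start (0-based), strand, n_errors).
#' @export
simulate_reads <- function(source, weights = NULL,
                           mode = c("short", "long"),
                           read_length = 100, depth = NULL, n_reads = NULL,
                           error_rate = 0, seed = NULL, stranded = FALSE) {
  mode <- match.arg(mode)
  if (length(source) == 0L) stop("empty source")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(source)

  if (mode == "short") {
    if (any(lens < read_length)) {
      source <- source[lens >= read_length]
      lens <- nchar(source)
      if (length(source) == 0L) stop("no source record >= read_length")
    }
    if (is.null(weights)) weights <- lens
    if (is.null(n_reads)) {
      if (is.null(depth)) stop("give depth or n_reads")
      n_reads <- round(depth * sum(lens) / read_length)
    }
    src <- sample.int(length(source), n_reads, replace = TRUE,
                      prob = weights / sum(weights))
    start0 <- vapply(src, function(i) {
      sample.int(lens[i] - read_length + 1L, 1L) - 1L
    }, integer(1))
    seqs <- substring(source[src], start0 + 1L, start0 + read_length)
    strand <- if (stranded) rep("+", n_reads) else
      sample(c("+", "-"), n_reads, replace = TRUE)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  } else {
    if (is.null(weights)) weights <- rep(1, length(source))
    if (is.null(n_reads)) {
      if (is.null(depth)) stop("give depth or n_reads")
      n_reads <- round(depth * length(source))
    }
    src <- sample.int(length(source), n_reads, replace = TRUE,
                      prob = weights / sum(weights))
    seqs <- unname(source[src])
    start0 <- rep(0L, n_reads)
    strand <- rep("+", n_reads)
  }

  n_err <- integer(n_reads)
  if (error_rate > 0) {
    for (i in seq_len(n_reads)) {
      ne <- rbinom(1L, nchar(seqs[i]), error_rate)
      if (ne > 0L) {
        ch <- seq_chars(seqs[i])
        ch <- mutate_bases(ch, sample.int(length(ch), ne))
        seqs[i] <- chars_seq(ch)
      }
      n_err[i] <- ne
    }
  }

  ids <- sprintf("read%06d", seq_len(n_reads))
  list(reads = setNames(seqs, ids),
       truth = data.frame(read = ids,
                          source = names(source)[src],
                          start = start0, strand = strand,
                          n_errors = n_err, stringsAsFactors = FALSE))
}
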