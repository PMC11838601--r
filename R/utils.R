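#' @useDynLib segfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rexp rpois runif sd quantile cor
#'   setNames as.dist ave pnorm
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved for
#'   upper case; ambiguity codes other than N are not handled).
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate random DNA
#'
#' Draws from the current RNG stream; callers are expected to namespace
#' streams via [local_seed()].
#' @param n sequence length in bp.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Split a sequence into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(ch) paste(ch, collapse = "")

## Hamming distance between two equal-length strings (raw-byte compare).
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

## All k-mers of s starting at `at` (1-based); vectorised substring.
kmers_at <- function(s, k, at) substring(s, at, at + k - 1L)

#' Canonical form of k-mers
#'
#' The lexicographic minimum of a k-mer and its reverse complement, the
#' strand-collapsed key used by the expression k-mer index.
#' @param x character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## Derive a component-namespaced seed from a master seed, so that adding
## draws in one component never perturbs another's stream.
derive_seed <- function(seed, component) {
  h <- 0
  for (ci in utf8ToInt(component)) h <- (h * 131 + ci) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Evaluate expr under a namespaced seed, restoring the caller's RNG state.
local_seed <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, component))
  expr
}

## Apply substitutions to a char vector of bases at 1-based positions;
## each position is changed to a uniformly drawn *different* base.
mutate_bases <- function(ch, pos) {
  if (length(pos) == 0L) return(ch)
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  ch
}

## Draw substitution positions for a divergence fraction over length L.
draw_sub_positions <- function(L, divergence) {
  n <- rbinom(1L, L, divergence)
  if (n == 0L) integer(0) else sort(sample.int(L, n))
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings for plain in-memory named character vectors.
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write simple FASTQ
#'
#' Constant base qualities are emitted; the simulator does not model
#' quality strings.
#' @param x named character vector of reads.
#' @param path file path.
#' @export
write_fastq <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(x), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", names(x), "\n", x, "\n+\n", qual), con)
  invisible(path)
}

#' Export feature annotations as GFF3
#'
#' @param ann data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, `name`.
#' @param path file path.
#' @export
write_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  gr$type <- ann$type
  gr$ID <- ann$name
  gr$Name <- ann$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## 0-based half-open interval overlap length.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

## Translate DNA (forward frame 1) to protein, "*" for stop.
translate_dna <- function(s) {
  n <- (nchar(s) %/% 3L) * 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, n)),
    if.fuzzy.codon = "X"
  ))
}

## Reverse-translate a protein with a fixed deterministic codon choice.
.segfam_cache <- new.env(parent = emptyenv())
rev_codon_table <- function() {
  if (is.null(.segfam_cache$rev_codon)) {
    gc <- Biostrings::GENETIC_CODE
    split_codons <- split(names(gc), unname(gc))
    .segfam_cache$rev_codon <-
      vapply(split_codons, function(cs) sort(cs)[1], character(1))
  }
  .segfam_cache$rev_codon
}
reverse_translate <- function(protein) {
  tab <- rev_codon_table()
  aa <- seq_chars(protein)
  paste(tab[aa], collapse = "")
}
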