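# Independent closed-form oracle for Tajima's D: pi from an explicit
# pairwise haplotype loop, constants written out directly (second
# implementation, kept independent of the package's frequency-spectrum
# computation).
tajima_oracle <- function(G) {
  n <- nrow(G)
  seg <- colSums(G) > 0 & colSums(G) < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  Gs <- G[, seg, drop = FALSE]
  pi_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pi_tot <- pi_tot + sum(Gs[i, ] != Gs[j, ])
  }
  pi_ <- pi_tot / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_ - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exhaustive ORF oracle: try every ATG, walk codons to the first stop.
orf_oracle <- function(x, min_codons = 1L) {
  x <- toupper(x)
  best <- NULL
  for (i in seq_len(max(0, nchar(x) - 2))) {
    if (substr(x, i, i + 2) != "ATG") next
    j <- i
    prot <- ""
    repeat {
      cod <- substr(x, j, j + 2)
      if (nchar(cod) < 3) break
      aa <- as.character(Biostrings::GENETIC_CODE[[cod]])
      if (aa == "*") break
      prot <- paste0(prot, aa)
      j <- j + 3
    }
    len <- nchar(prot)
    if (len >= min_codons && (is.null(best) || len > nchar(best))) {
      best <- prot
    }
  }
  if (is.null(best)) NA_character_ else best
}

# mean AUC of value_b > value_a (probability a sweep window outranks a
# neutral one), over non-missing values
rank_auc <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  mean(outer(b, a, ">") + 0.5 * outer(b, a, "=="))
}
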