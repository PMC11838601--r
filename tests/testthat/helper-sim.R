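# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so single files stay fast.

# a compact family configuration: shorter duplicon and spacers than the
# package defaults, same structure
tiny_config <- function(seed = 11, n_samples = 4, ...) {
  sim_config(seed = seed, n_samples = n_samples,
             ancestral_locus_length = 4000,
             marker_length = 1500, spacer_length = 6000,
             igc_tract_mean = 600, igc_tract_min = 200,
             ...)
}

# random DNA under the current RNG stream
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# substitution-mutate a sequence at a given per-base rate
mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  n <- rbinom(1L, length(ch), rate)
  if (n > 0L) {
    pos <- sample(length(ch), n)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# random DCJ-indel instance: a 6-token configuration and a copy edited by
# 1..max_ops events (inversion, short deletion, single-token insertion,
# token move); distances stay small enough for the exhaustive oracle
rand_config_pair <- function(n_tokens = 6, max_ops = 3) {
  nm <- paste0("T", seq_len(n_tokens))
  sgn <- sample(c("+", "-"), n_tokens, replace = TRUE)
  a <- paste0(sgn, nm)
  b <- a
  next_new <- n_tokens + 1L
  flip <- function(x) ifelse(startsWith(x, "-"), sub("^-", "+", x),
                             sub("^\\+", "-", x))
  for (k in seq_len(sample.int(max_ops, 1L))) {
    op <- sample(c("inv", "del", "ins", "move"), 1L)
    L <- length(b)
    if (op == "inv" && L >= 2L) {
      ij <- sort(sample(L, 2L))
      b[ij[1]:ij[2]] <- rev(flip(b[ij[1]:ij[2]]))
    } else if (op == "del" && L >= 2L) {
      i <- sample(L, 1L)
      j <- min(L, i + sample(0:1, 1L))
      b <- b[-(i:j)]
    } else if (op == "ins") {
      tok <- paste0(sample(c("+", "-"), 1L), "T", next_new)
      next_new <- next_new + 1L
      b <- append(b, tok, after = sample(0:L, 1L))
    } else if (op == "move" && L >= 3L) {
      i <- sample(L, 1L)
      x <- b[i]
      b <- append(b[-i], x, after = sample(0:(L - 1L), 1L))
    }
  }
  list(a = a, b = b)
}

# consensus set for phylo/igc tests: paralogs at `inter` divergence from a
# shared ancestor, copies at `intra` on top
make_paralog_copies <- function(n_paralogs = 4, copies_per = 5,
                                len = 3000, inter = 0.025, intra = 0.0025) {
  anc <- rdna(len)
  cons <- setNames(lapply(seq_len(n_paralogs), function(i)
    mutate_seq(anc, inter)), paste0("P", seq_len(n_paralogs)))
  seqs <- character(0)
  truth <- character(0)
  for (p in names(cons)) {
    for (i in seq_len(copies_per)) {
      nm <- paste0(p, "_c", i)
      seqs[nm] <- mutate_seq(cons[[p]], intra)
      truth[nm] <- p
    }
  }
  list(ancestral = anc, consensus = unlist(cons), seqs = seqs,
       truth = truth)
}

# local copies of small utilities (package internals are not attached)
hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

translate_protein <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna)))
}
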