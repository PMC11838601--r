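#' Locus configuration as a signed token string
#'
#' The ordered sequence of gene-family copies and marker genes at one
#' locus on one haplotype, each token carrying an orientation sign.
#' @param tokens character vector like `c("+M1", "+A1", "-G1")`; a bare
#'   name means "+".
#' @param locus locus id.
#' @param haplotype source haplotype id.
#' @return object of class `configuration`.
#' @export
configuration <- function(tokens, locus = NA_character_,
                          haplotype = NA_character_) {
  if (length(tokens) < 1L) stop("configuration needs at least one token")
  obj <- list(tokens = config_tokens(tokens), locus = locus,
              haplotype = haplotype)
  class(obj) <- "configuration"
  obj
}

#' @export
print.configuration <- function(x, ...) {
  cat(x$locus, "[", x$haplotype, "]:",
      paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

flip_tokens <- function(tokens) {
  flipped <- ifelse(startsWith(tokens, "-"),
                    sub("^-", "+", tokens), sub("^\\+", "-", tokens))
  rev(flipped)
}

#' Encode one haplotype's locus structure as a configuration string
#'
#' Features (copies with paralog labels, marker genes) are ordered
#' left-to-right along the contig; features shorter than `min_token_len`
#' are dropped. Haplotypes assembled on the reverse strand are flipped so
#' the distal marker leads in forward orientation, making configurations
#' comparable across haplotypes.
#'
#' @param features data.frame: name, start, end (0-based half-open),
#'   strand for one locus on one haplotype.
#' @param distal,proximal marker gene names bounding the locus (distal
#'   leads after orientation).
#' @param min_token_len minimum feature length retained, bp.
#' @param locus,haplotype ids recorded on the result.
#' @return a [configuration()], or `NULL` (with a warning) when both
#'   boundary markers are missing.
#' @export
encode_configuration <- function(features, distal, proximal,
                                 min_token_len = 1000,
                                 locus = NA_character_,
                                 haplotype = NA_character_) {
  features <- features[features$end - features$start >= min_token_len, ,
                       drop = FALSE]
  if (nrow(features) == 0L ||
      (!distal %in% features$name && !proximal %in% features$name)) {
    warning("locus skipped: boundary markers missing for ", haplotype)
    return(NULL)
  }
  features <- features[order(features$start), , drop = FALSE]
  tokens <- paste0(ifelse(features$strand == "-", "-", "+"), features$name)
  di <- match(distal, features$name)
  pi_ <- match(proximal, features$name)
  flip <- FALSE
  if (!is.na(di)) {
    flip <- startsWith(tokens[di], "-") ||
      (!is.na(pi_) && di > pi_)
  } else if (!is.na(pi_)) {
    flip <- startsWith(tokens[pi_], "+") && pi_ == 1L
  }
  if (flip) tokens <- flip_tokens(tokens)
  configuration(tokens, locus = locus, haplotype = haplotype)
}

#' Catalog distinct configurations across haplotypes
#'
#' Distinct token strings are grouped and counted. Configurations seen in
#' fewer than `min_haplotypes` haplotypes, or never seen on a haplotype
#' passing assembly validation, are excluded; frequencies are computed
#' over all encodable haplotypes.
#'
#' @param encodings list of [configuration()] objects (NULL entries from
#'   unencodable haplotypes are tolerated).
#' @param min_haplotypes minimum haplotype count per retained
#'   configuration.
#' @param validated optional named logical vector (haplotype -> QC pass);
#'   when given, a configuration must be observed on at least one
#'   validated haplotype.
#' @return data.frame of class `config_catalog`: config_id, tokens
#'   (space-joined string), count, frequency, haplotypes; the token
#'   vectors are kept in `attr(, "tokens_list")`.
#' @export
catalog_configurations <- function(encodings, min_haplotypes = 2,
                                   validated = NULL) {
  encodings <- Filter(Negate(is.null), encodings)
  n_enc <- length(encodings)
  if (n_enc == 0L) {
    out <- data.frame(config_id = character(0), tokens = character(0),
                      count = integer(0), frequency = numeric(0),
                      haplotypes = character(0))
    class(out) <- c("config_catalog", "data.frame")
    return(out)
  }
  keys <- vapply(encodings, function(e) paste(e$tokens, collapse = " "),
                 character(1))
  haps <- vapply(encodings, function(e) e$haplotype, character(1))
  grp <- split(seq_along(keys), keys)
  rows <- lapply(grp, function(ii) {
    ok_val <- if (is.null(validated)) TRUE else {
      any(validated[haps[ii]], na.rm = TRUE)
    }
    data.frame(tokens = keys[ii[1]], count = length(ii),
               frequency = length(ii) / n_enc,
               haplotypes = paste(haps[ii], collapse = ","),
               keep = length(ii) >= min_haplotypes && ok_val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$tokens), , drop = FALSE]
  out <- out[out$keep, setdiff(names(out), "keep"), drop = FALSE]
  if (nrow(out)) {
    out$config_id <- paste0("C", seq_len(nrow(out)))
    out <- out[, c("config_id", "tokens", "count", "frequency",
                   "haplotypes")]
    rownames(out) <- NULL
  } else {
    out$config_id <- character(0)
  }
  attr(out, "tokens_list") <- lapply(out$tokens,
                                     function(s) strsplit(s, " ")[[1]])
  class(out) <- c("config_catalog", "data.frame")
  out
}

#' Midpoint-rooted NJ tree over a configuration catalog
#'
#' Neighbor joining on the pairwise DCJ-indel distance matrix; leaves are
#' the catalog's configuration ids, annotated with counts and frequencies.
#' With fewer than three configurations a trivial (2-tip or NULL) tree is
#' returned.
#'
#' @param catalog a [catalog_configurations()] result.
#' @return an `ape::phylo` tree (or `NULL` for a single configuration)
#'   with `frequency` and `count` attributes.
#' @export
config_tree <- function(catalog) {
  toks <- attr(catalog, "tokens_list")
  n <- nrow(catalog)
  if (n == 0L) return(NULL)
  if (n == 1L) {
    tr <- NULL
  } else if (n == 2L) {
    d <- dcj_indel_distance(toks[[1]], toks[[2]])
    tr <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE),
      tip.label = catalog$config_id,
      edge.length = c(d / 2, d / 2),
      Nnode = 1L), class = "phylo")
  } else {
    D <- matrix(0, n, n, dimnames = list(catalog$config_id,
                                         catalog$config_id))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- dcj_indel_distance(toks[[i]], toks[[j]])
      }
    }
    tr <- build_nj(D)
  }
  if (!is.null(tr)) {
    attr(tr, "frequency") <- setNames(catalog$frequency,
                                      catalog$config_id)
    attr(tr, "count") <- setNames(catalog$count, catalog$config_id)
  }
  tr
}

## match a haplotype's tokens against the reference with one candidate
## interval reversed; returns TRUE when tokens == ref with [i..j] flipped
matches_inverted <- function(tokens, ref, i, j) {
  cand <- ref
  cand[i:j] <- flip_tokens(ref[i:j])
  length(tokens) == length(cand) && all(tokens == cand)
}

#' Call inversion polymorphisms against a reference configuration
#'
#' Maximal token intervals whose order is reversed and orientations
#' flipped relative to the reference are reported once per locus. For
#' haplotypes whose copy-number expansion prevents an exact token match,
#' the orientation state is classified from the signs of the marker genes
#' inside the interval (an inversion flips every spanned feature).
#' Allele frequency is inverted haplotypes over encodable haplotypes.
#'
#' @param encodings list of [configuration()] objects.
#' @param reference reference configuration (or token vector).
#' @param markers character vector of marker-gene names (tokens that are
#'   not gene-family copies); used to classify non-exact haplotypes.
#' @param annotations optional per-feature coordinate data.frame (contig,
#'   name, start, end) to report the interval span in bp.
#' @param assemblies optional named character vector of haplotype
#'   sequences; with `annotations`, the mean sequence divergence of the
#'   inverted interval's marker genes vs the reference haplotype is
#'   reported.
#' @return data.frame of class `inversion_calls`: locus, ref_start,
#'   ref_end (token interval, 1-based), tokens, n_inverted, n_encodable,
#'   af, span_bp, divergence; per-haplotype states in
#'   `attr(, "states")`.
#' @export
detect_inversions <- function(encodings, reference, markers = NULL,
                              annotations = NULL, assemblies = NULL) {
  ref <- config_tokens(if (inherits(reference, "configuration"))
    reference$tokens else reference)
  encodings <- Filter(Negate(is.null), encodings)
  n_enc <- length(encodings)
  empty <- data.frame(locus = character(0), ref_start = integer(0),
                      ref_end = integer(0), tokens = character(0),
                      n_inverted = integer(0), n_encodable = integer(0),
                      af = numeric(0), span_bp = numeric(0),
                      divergence = numeric(0))
  class(empty) <- c("inversion_calls", "data.frame")
  if (n_enc == 0L) return(empty)

  ## inversion discovery on the marker-gene projection (marker content is
  ## copy-number invariant, unlike the full token string), refined to the
  ## full token interval when an exact-match haplotype exists
  if (is.null(markers)) {
    markers <- tok_name(ref)  # fall back: treat every token as a marker
  }
  project <- function(tokens) tokens[tok_name(tokens) %in% markers]
  ref_mk <- project(ref)
  ref_mk_idx <- which(tok_name(ref) %in% markers)

  intervals <- list()   # key -> list(mk = c(i, j), full = c(i, j) or NULL)
  state_rows <- list()
  for (e in encodings) {
    tk <- project(e$tokens)
    st <- NA_character_
    key <- NULL
    if (length(tk) == length(ref_mk)) {
      if (all(tk == ref_mk)) {
        st <- "D"
      } else {
        mism <- which(tk != ref_mk)
        i <- min(mism); j <- max(mism)
        if (matches_inverted(tk, ref_mk, i, j)) {
          st <- "I"
          key <- paste(i, j, sep = "-")
          if (is.null(intervals[[key]])) {
            intervals[[key]] <- list(mk = c(i, j), full = NULL)
          }
          ## refine to the full token interval when this haplotype's
          ## complete token string is an exact single-interval reversal
          if (length(e$tokens) == length(ref)) {
            fm <- which(e$tokens != ref)
            if (length(fm)) {
              fi <- min(fm); fj <- max(fm)
              if (matches_inverted(e$tokens, ref, fi, fj)) {
                intervals[[key]]$full <- c(fi, fj)
              }
            }
          }
        }
      }
    }
    state_rows[[length(state_rows) + 1L]] <- data.frame(
      haplotype = e$haplotype, locus = e$locus, state = st,
      stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, state_rows)

  if (length(intervals) == 0L) {
    attr(empty, "states") <- states
    return(empty)
  }

  rows <- lapply(names(intervals), function(key) {
    iv <- if (!is.null(intervals[[key]]$full)) intervals[[key]]$full else {
      mk <- intervals[[key]]$mk
      c(ref_mk_idx[mk[1]], ref_mk_idx[mk[2]])
    }
    inv_haps <- states$haplotype[!is.na(states$state) & states$state == "I"]
    span <- NA_real_
    divergence <- NA_real_
    if (!is.null(annotations) && length(inv_haps)) {
      spans <- vapply(inv_haps, function(h) {
        ann <- annotations[annotations$contig == h, , drop = FALSE]
        nm <- tok_name(ref[iv[1]:iv[2]])
        ann <- ann[ann$name %in% nm, , drop = FALSE]
        if (nrow(ann) == 0L) return(NA_real_)
        max(ann$end) - min(ann$start)
      }, numeric(1))
      span <- median(spans, na.rm = TRUE)
    }
    if (!is.null(assemblies) && !is.null(annotations) &&
        !is.null(markers) && length(inv_haps)) {
      ref_haps <- states$haplotype[!is.na(states$state) &
                                     states$state == "D"]
      if (length(ref_haps)) {
        mk <- intersect(tok_name(ref[iv[1]:iv[2]]), markers)
        divs <- c()
        for (h in inv_haps) {
          for (g in mk) {
            s1 <- feature_seq(assemblies, annotations, h, g)
            s2 <- feature_seq(assemblies, annotations, ref_haps[1], g)
            if (!is.null(s1) && !is.null(s2) && nchar(s1) == nchar(s2)) {
              divs <- c(divs, hamming(s1, s2) / nchar(s1))
            }
          }
        }
        if (length(divs)) divergence <- mean(divs)
      }
    }
    data.frame(locus = encodings[[1]]$locus, ref_start = iv[1],
               ref_end = iv[2],
               tokens = paste(ref[iv[1]:iv[2]], collapse = " "),
               n_inverted = length(inv_haps), n_encodable = n_enc,
               af = length(inv_haps) / n_enc, span_bp = span,
               divergence = divergence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("inversion_calls", "data.frame")
  attr(out, "states") <- states
  out
}

## extract a named feature's sequence from an assembly, forward strand
feature_seq <- function(assemblies, annotations, hap, name) {
  ann <- annotations[annotations$contig == hap & annotations$name == name, ,
                     drop = FALSE]
  if (nrow(ann) == 0L || !hap %in% names(assemblies)) return(NULL)
  s <- substr(assemblies[[hap]], ann$start[1] + 1L, ann$end[1])
  if (ann$strand[1] == "-") revcomp(s) else s
}
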