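#' Simulation configuration for a multicopy gene family
#'
#' Defines the generative conditions for a high-identity, interspersed
#' gene-family locus on phased haplotypes: an ancestral ~20 kbp duplicon,
#' paralog consensus sequences at configurable divergence, per-haplotype
#' copy-number variation, interlocus gene conversion (IGC), inversion
#' polymorphisms re-ordering marker genes, and an in-frame amino-acid VNTR
#' with a SADD-type / MIISR-type frame-switch structure.
#'
#' The defaults emulate the study conditions the analysis modules assume:
#' a 20 kbp duplicon at ~2% inter-paralog divergence (pairwise), low
#' intra-paralog diversity, six paralogs in two subfamilies (A and B) with
#' copy numbers between 0 and 3 per haplotype, IGC restricted to within
#' subfamilies, and one polymorphic inversion spanning interior marker
#' genes.
#'
#' @param seed master seed; every downstream draw is namespaced from it.
#' @param n_samples number of diploid samples (two haplotypes each).
#' @param populations named integer vector of per-population sample counts;
#'   must sum to `n_samples`.
#' @param ancestral_locus_length duplicon length in bp.
#' @param paralogs named numeric vector: paralog label -> divergence from
#'   the ancestral locus (substitutions/site). Pairwise inter-paralog
#'   divergence is approximately the sum of the two branch values.
#' @param markers character vector of marker-gene token names used in
#'   `locus_templates`; any template token must be a paralog or a marker.
#' @param intra_diversity per-copy substitution rate on top of the paralog
#'   consensus (haplotype-level diversity).
#' @param locus_templates named list of ordered token vectors (optionally
#'   prefixed "+"/"-") defining each locus structure.
#' @param marker_length,spacer_length bp lengths of marker genes and of the
#'   unique spacer sequence separating tokens.
#' @param cn_model named list: paralog -> list(cn = integer vector,
#'   p = probabilities) for the per-haplotype copy-number draw.
#' @param igc_rate expected IGC events per haplotype (Poisson).
#' @param igc_tract_mean,igc_tract_min IGC tract length parameters in bp.
#' @param igc_within_subfamily restrict donor/acceptor pairs to the same
#'   subfamily (first letter of the paralog label).
#' @param inversions list of inversion polymorphisms, each
#'   `list(id, locus, span = c(i, j), af)` where `span` indexes template
#'   tokens and `af` is the inverted-allele frequency.
#' @param vntr `NULL`, or `list(paralogs, counts = list(a =, b =, c =))`
#'   giving the paralogs carrying the exon-8-style VNTR and inclusive
#'   count ranges for the first SADD run, the MIISR run, and the second
#'   SADD run.
#' @param theta population mutation parameter per 30 kbp window (used by
#'   the coalescent window simulator defaults).
#' @param read_length,depth,error_rate short-read simulation defaults.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_samples = 20,
                       populations = c(AFR = ceiling(n_samples / 2),
                                       EUR = floor(n_samples / 2)),
                       ancestral_locus_length = 20000,
                       paralogs = c(A1 = 0.010, A2 = 0.010, A3 = 0.010,
                                    B1 = 0.010, B2 = 0.010, B3 = 0.010),
                       markers = c("M1", "G1", "G2", "M2"),
                       intra_diversity = 5e-4,
                       locus_templates = list(
                         L1 = c("M1", "A1", "G1", "A2", "A3",
                                "G2", "B1", "B2", "B3", "M2")),
                       marker_length = 5000,
                       spacer_length = 40000,
                       cn_model = list(
                         A1 = list(cn = 1L, p = 1),
                         A2 = list(cn = c(1L, 2L), p = c(0.6, 0.4)),
                         A3 = list(cn = c(0L, 1L, 2L), p = c(0.2, 0.6, 0.2)),
                         B1 = list(cn = 1L, p = 1),
                         B2 = list(cn = c(1L, 2L, 3L), p = c(0.5, 0.3, 0.2)),
                         B3 = list(cn = c(0L, 1L), p = c(0.3, 0.7))),
                       igc_rate = 0.5,
                       igc_tract_mean = 2000,
                       igc_tract_min = 500,
                       igc_within_subfamily = TRUE,
                       inversions = list(
                         list(id = "inv1", locus = "L1",
                              span = c(3L, 5L), af = 0.4)),
                       vntr = NULL,
                       theta = 10,
                       read_length = 100,
                       depth = 20,
                       error_rate = 0.005) {
  cfg <- list(seed = seed, n_samples = n_samples, populations = populations,
              ancestral_locus_length = ancestral_locus_length,
              paralogs = paralogs, markers = markers,
              intra_diversity = intra_diversity,
              locus_templates = locus_templates,
              marker_length = marker_length, spacer_length = spacer_length,
              cn_model = cn_model, igc_rate = igc_rate,
              igc_tract_mean = igc_tract_mean, igc_tract_min = igc_tract_min,
              igc_within_subfamily = igc_within_subfamily,
              inversions = inversions, vntr = vntr, theta = theta,
              read_length = read_length, depth = depth,
              error_rate = error_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (sum(cfg$populations) != cfg$n_samples) {
    stop("population counts must sum to n_samples")
  }
  labels <- names(cfg$paralogs)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("paralogs must be a uniquely named vector")
  }
  for (tpl in cfg$locus_templates) {
    nm <- sub("^[+-]", "", tpl)
    unknown <- setdiff(nm, c(labels, cfg$markers))
    if (length(unknown)) {
      stop("template token(s) not defined as paralog or marker: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(bad <- setdiff(names(cfg$cn_model), labels))) {
    stop("cn_model for unknown paralog(s): ", paste(bad, collapse = ", "))
  }
  for (m in cfg$cn_model) {
    if (any(m$cn < 0)) stop("copy numbers must be >= 0")
    if (length(m$cn) != length(m$p)) stop("cn_model cn/p length mismatch")
  }
  for (inv in cfg$inversions) {
    if (inv$af < 0 || inv$af > 1) stop("inversion allele frequency not in [0,1]")
    if (!inv$locus %in% names(cfg$locus_templates)) {
      stop("inversion on unknown locus: ", inv$locus)
    }
    tpl <- cfg$locus_templates[[inv$locus]]
    if (inv$span[1] < 1 || inv$span[2] > length(tpl) ||
        inv$span[1] > inv$span[2]) {
      stop("inversion span outside template")
    }
  }
  if (!is.null(cfg$vntr)) {
    if (length(bad <- setdiff(cfg$vntr$paralogs, labels))) {
      stop("vntr on unknown paralog(s): ", paste(bad, collapse = ", "))
    }
    units <- vntr_units_dna()
    if (any(nchar(units) %% 3L != 0L)) stop("vntr unit length not divisible by 3")
  }
  invisible(cfg)
}

#' Load a simulation configuration from YAML
#'
#' Scalar fields override the [sim_config()] defaults; structured fields
#' (`paralogs`, `cn_model`, `locus_templates`, `inversions`, `vntr`,
#' `populations`) are taken verbatim when present.
#' @param path YAML file.
#' @return a `sim_config` object.
#' @export
sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$paralogs)) y$paralogs <- unlist(y$paralogs)
  if (!is.null(y$populations)) y$populations <- unlist(y$populations)
  do.call(sim_config, y)
}

## The protein repeat motifs of the coding VNTR and their deterministic
## DNA reverse translations (in-frame, unit lengths divisible by 3).
VNTR_MOTIF_SADD19 <- "SADDNLKTPSERQLTPLPP"
VNTR_MOTIF_SADD23 <- "SADDNIKTPAERLRGPLPPSAPP"
VNTR_MOTIF_MIISR  <- "MIISRHLPSVSSLPFHPQLHPQQMI"

vntr_units_dna <- function() {
  c(sadd19 = reverse_translate(VNTR_MOTIF_SADD19),
    sadd23 = reverse_translate(VNTR_MOTIF_SADD23),
    miisr  = reverse_translate(VNTR_MOTIF_MIISR))
}

## Build one VNTR DNA array with the SADD -> MIISR -> SADD frame-switch
## structure; SADD runs alternate the 19- and 23-residue unit types.
vntr_array_dna <- function(a, b, c) {
  u <- vntr_units_dna()
  sadd_run <- function(n, start_long = FALSE) {
    if (n == 0L) return("")
    types <- rep(c("sadd19", "sadd23"), length.out = n)
    if (start_long) types <- rep(c("sadd23", "sadd19"), length.out = n)
    paste(u[types], collapse = "")
  }
  paste0(sadd_run(a), strrep(u[["miisr"]], b), sadd_run(c))
}

subfamily_of <- function(label) substr(label, 1L, 1L)

#' Simulate phased haplotype assemblies for a multicopy gene family
#'
#' Generates, deterministically from `config$seed`, per-haplotype contigs
#' containing gene-family copies (paralog consensus + copy-private
#' substitutions + optional IGC tract replacements + optional VNTR tails)
#' interleaved with marker genes and unique spacers, together with GFF-style
#' annotations and a machine-readable truth set used as the acceptance
#' oracle for every downstream module.
#'
#' Mutations inside copies are substitutions only, so each copy remains
#' colinear with the ancestral duplicon and PSV bookkeeping stays exact.
#' IGC is applied as whole-tract replacement from the donor paralog
#' consensus; inversions reverse-complement the spanned token interval
#' including embedded copies.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_family` with elements `assemblies` (named
#'   character vector of contigs, one per haplotype), `annotations`
#'   (data.frame: contig/type/name/copy_id/locus/start/end/strand, 0-based
#'   half-open), `truth` (list: samples, copy_table, copy_coordinates,
#'   igc_events, inversion_states, vntr_counts, paralog_consensus,
#'   ancestral, marker_seqs) and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  L <- config$ancestral_locus_length
  labels <- sort(names(config$paralogs))

  ancestral <- local_seed(config$seed, "ancestral", random_dna(L))
  marker_seqs <- local_seed(config$seed, "markers", {
    setNames(
      vapply(seq_along(config$markers),
             function(i) random_dna(config$marker_length), character(1)),
      config$markers)
  })

  anc_chars <- seq_chars(ancestral)
  consensus_chars <- local_seed(config$seed, "paralogs", {
    out <- list()
    for (lab in labels) {
      pos <- draw_sub_positions(L, config$paralogs[[lab]])
      out[[lab]] <- mutate_bases(anc_chars, pos)
    }
    out
  })
  paralog_consensus <- vapply(consensus_chars, chars_seq, character(1))

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  pops <- rep(names(config$populations), config$populations)
  haps <- as.vector(t(outer(samples, c("_h1", "_h2"), paste0)))

  assemblies <- character(0)
  ann_rows <- list()
  copy_rows <- list()
  igc_rows <- list()
  inv_rows <- list()
  vntr_rows <- list()
  cn_mat <- matrix(0L, nrow = length(haps), ncol = length(labels),
                   dimnames = list(haps, labels))

  for (hap in haps) {
    ## per-haplotype copy number per paralog
    cn <- local_seed(config$seed, paste0("cn:", hap), {
      vapply(labels, function(lab) {
        m <- config$cn_model[[lab]]
        if (is.null(m)) return(1L)
        if (length(m$cn) == 1L) m$cn else sample(m$cn, 1L, prob = m$p)
      }, integer(1))
    })
    cn_mat[hap, ] <- cn

    inv_geno <- local_seed(config$seed, paste0("inv:", hap), {
      vapply(config$inversions, function(inv) runif(1) < inv$af, logical(1))
    })

    ## expand locus templates into token lists
    tokens <- list()   # each: name, sign, type, template_idx, locus, copy_id
    copy_seqs <- list()
    for (locus in names(config$locus_templates)) {
      tpl <- config$locus_templates[[locus]]
      copy_counter <- integer(0)
      for (i in seq_along(tpl)) {
        sign <- if (startsWith(tpl[i], "-")) "-" else "+"
        nm <- sub("^[+-]", "", tpl[i])
        if (nm %in% labels) {
          k <- cn[[nm]]
          if (k == 0L) next
          for (j in seq_len(k)) {
            copy_counter[nm] <- if (is.na(copy_counter[nm])) 1L else
              copy_counter[nm] + 1L
            cid <- paste0(hap, "_", nm, "_", copy_counter[nm])
            tokens[[length(tokens) + 1L]] <-
              list(name = nm, sign = sign, type = "copy",
                   template_idx = i, locus = locus, copy_id = cid)
          }
        } else {
          tokens[[length(tokens) + 1L]] <-
            list(name = nm, sign = sign, type = "marker",
                 template_idx = i, locus = locus, copy_id = NA_character_)
        }
      }
    }

    ## copy sequences: consensus + copy-private substitutions
    local_seed(config$seed, paste0("copies:", hap), {
      for (tk in tokens) {
        if (tk$type != "copy") next
        ch <- consensus_chars[[tk$name]]
        pos <- draw_sub_positions(L, config$intra_diversity)
        copy_seqs[[tk$copy_id]] <- mutate_bases(ch, pos)
      }
    })

    ## IGC: whole-tract replacement from the donor consensus
    local_seed(config$seed, paste0("igc:", hap), {
      n_ev <- if (config$igc_rate > 0) rpois(1L, config$igc_rate) else 0L
      copy_tokens <- Filter(function(t) t$type == "copy", tokens)
      if (n_ev > 0L && length(copy_tokens) > 0L) {
        for (e in seq_len(n_ev)) {
          donors_of <- function(lab) {
            cand <- setdiff(labels, lab)
            if (config$igc_within_subfamily) {
              cand <- cand[subfamily_of(cand) == subfamily_of(lab)]
            }
            cand
          }
          eligible <- Filter(function(t) length(donors_of(t$name)) > 0L,
                             copy_tokens)
          if (length(eligible) == 0L) break
          acc <- eligible[[sample.int(length(eligible), 1L)]]
          dn <- donors_of(acc$name)
          donor <- dn[sample.int(length(dn), 1L)]
          len <- min(L, config$igc_tract_min +
                       round(rexp(1, 1 / max(1, config$igc_tract_mean -
                                               config$igc_tract_min))))
          start <- sample.int(L - len + 1L, 1L)
          idx <- start:(start + len - 1L)
          copy_seqs[[acc$copy_id]][idx] <- consensus_chars[[donor]][idx]
          igc_rows[[length(igc_rows) + 1L]] <- data.frame(
            haplotype = hap, copy_id = acc$copy_id, acceptor = acc$name,
            donor = donor, start = start - 1L, end = start - 1L + len,
            stringsAsFactors = FALSE)
        }
      }
    })

    ## VNTR tails appended after the duplicon core
    vntr_len <- setNames(integer(length(tokens)), vapply(tokens, function(t)
      ifelse(is.na(t$copy_id), "", t$copy_id), character(1)))
    if (!is.null(config$vntr)) {
      local_seed(config$seed, paste0("vntr:", hap), {
        rng <- config$vntr$counts
        for (tk in tokens) {
          if (tk$type != "copy" || !(tk$name %in% config$vntr$paralogs)) next
          a <- sample(rng$a[1]:rng$a[2], 1L)
          b <- sample(rng$b[1]:rng$b[2], 1L)
          cc <- sample(rng$c[1]:rng$c[2], 1L)
          arr <- vntr_array_dna(a, b, cc)
          copy_seqs[[tk$copy_id]] <- c(copy_seqs[[tk$copy_id]],
                                        seq_chars(arr))
          vntr_rows[[length(vntr_rows) + 1L]] <- data.frame(
            haplotype = hap, copy_id = tk$copy_id, paralog = tk$name,
            a = a, b = b, c = cc, array_bp = nchar(arr),
            stringsAsFactors = FALSE)
        }
      })
    }

    ## apply inversion polymorphisms at token level
    for (vi in seq_along(config$inversions)) {
      inv <- config$inversions[[vi]]
      state <- if (inv_geno[vi]) "I" else "D"
      inv_rows[[length(inv_rows) + 1L]] <- data.frame(
        haplotype = hap, inversion = inv$id, locus = inv$locus,
        state = state, stringsAsFactors = FALSE)
      if (state == "I") {
        in_span <- which(vapply(tokens, function(t)
          t$locus == inv$locus && t$template_idx >= inv$span[1] &&
            t$template_idx <= inv$span[2], logical(1)))
        if (length(in_span)) {
          blk <- rev(tokens[in_span])
          blk <- lapply(blk, function(t) {
            t$sign <- if (t$sign == "+") "-" else "+"
            t
          })
          tokens[in_span] <- blk
        }
      }
    }

    ## assemble the contig with unique spacers
    contig <- local_seed(config$seed, paste0("spacers:", hap), {
      parts <- character(0)
      pos <- 0L
      parts <- c(parts, random_dna(config$spacer_length))
      pos <- config$spacer_length
      for (tk in tokens) {
        s <- if (tk$type == "marker") marker_seqs[[tk$name]] else
          chars_seq(copy_seqs[[tk$copy_id]])
        emitted <- if (tk$sign == "-") revcomp(s) else s
        start <- pos
        end <- pos + nchar(emitted)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          contig = hap, type = tk$type, name = tk$name,
          copy_id = tk$copy_id, locus = tk$locus,
          start = start, end = end, strand = tk$sign,
          stringsAsFactors = FALSE)
        if (tk$type == "copy") {
          copy_rows[[length(copy_rows) + 1L]] <- data.frame(
            haplotype = hap, contig = hap, copy_id = tk$copy_id,
            paralog = tk$name, locus = tk$locus,
            start = start, end = end, strand = tk$sign,
            stringsAsFactors = FALSE)
        }
        parts <- c(parts, emitted, random_dna(config$spacer_length))
        pos <- end + config$spacer_length
      }
      paste(parts, collapse = "")
    })
    assemblies[hap] <- contig
  }

  bind <- function(rows, proto) {
    if (length(rows)) do.call(rbind, rows) else proto
  }
  truth <- list(
    samples = data.frame(sample = samples, population = pops,
                         hap1 = paste0(samples, "_h1"),
                         hap2 = paste0(samples, "_h2"),
                         stringsAsFactors = FALSE),
    copy_table = cn_mat,
    copy_coordinates = bind(copy_rows, data.frame(
      haplotype = character(0), contig = character(0), copy_id = character(0),
      paralog = character(0), locus = character(0), start = integer(0),
      end = integer(0), strand = character(0))),
    igc_events = bind(igc_rows, data.frame(
      haplotype = character(0), copy_id = character(0),
      acceptor = character(0), donor = character(0), start = integer(0),
      end = integer(0))),
    inversion_states = bind(inv_rows, data.frame(
      haplotype = character(0), inversion = character(0), locus = character(0),
      state = character(0))),
    vntr_counts = bind(vntr_rows, data.frame(
      haplotype = character(0), copy_id = character(0), paralog = character(0),
      a = integer(0), b = integer(0), c = integer(0), array_bp = integer(0))),
    paralog_consensus = paralog_consensus,
    ancestral = ancestral,
    marker_seqs = marker_seqs)

  out <- list(assemblies = assemblies,
              annotations = bind(ann_rows, data.frame(
                contig = character(0), type = character(0), name = character(0),
                copy_id = character(0), locus = character(0),
                start = integer(0), end = integer(0), strand = character(0))),
              truth = truth,
              config = config)
  class(out) <- "sim_family"
  out
}

#' @export
print.sim_family <- function(x, ...) {
  cat("Simulated gene-family assembly set\n")
  cat("  haplotypes:", length(x$assemblies), "\n")
  cat("  paralogs:  ", paste(colnames(x$truth$copy_table), collapse = ", "), "\n")
  cat("  copies:    ", nrow(x$truth$copy_coordinates), "\n")
  cat("  IGC events:", nrow(x$truth$igc_events), "\n")
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits per-haplotype FASTA, a GFF3 of markers and copies, and the truth
#' set as TSV/JSON.
#' @param sim a `sim_family` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_family <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$assemblies, file.path(dir, "assemblies.fa"))
  write_gff3(sim$annotations, file.path(dir, "annotations.gff3"))
  tr <- sim$truth
  write.table(data.frame(haplotype = rownames(tr$copy_table),
                         tr$copy_table, check.names = FALSE),
              file.path(dir, "copy_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("copy_coordinates", "igc_events", "inversion_states",
               "vntr_counts", "samples")) {
    write.table(tr[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = sim$config$seed,
         n_haplotypes = length(sim$assemblies),
         paralogs = colnames(tr$copy_table)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Extract copy sequences from assemblies using truth coordinates
#'
#' Used by the regeneration-consistency check: sequences extracted here must
#' equal the per-copy sequences the simulator emitted (reverse-complemented
#' back to query orientation on the minus strand).
#' @param sim a `sim_family` object.
#' @return named character vector keyed by copy id, in ancestral (query)
#'   orientation.
#' @export
extract_truth_copies <- function(sim) {
  cc <- sim$truth$copy_coordinates
  out <- character(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    s <- substr(sim$assemblies[[cc$contig[i]]], cc$start[i] + 1L, cc$end[i])
    out[i] <- if (cc$strand[i] == "-") revcomp(s) else s
  }
  setNames(out, cc$copy_id)
}

#' Build transcript sequences from paralog consensus loci
#'
#' Concatenates exon intervals (0-based half-open, in ancestral duplicon
#' coordinates) from each paralog consensus into a spliced transcript, the
#' source pool for long-read and short-read RNA simulations.
#' @param sim a `sim_family` object.
#' @param exons list of `c(start, end)` intervals; the default five-exon
#'   chain spans ~3.3 kbp of the duplicon.
#' @param paralogs which paralogs to emit (default: all).
#' @return named character vector `paralog -> transcript`.
#' @export
sim_transcripts <- function(sim,
                            exons = default_exons(),
                            paralogs = names(sim$truth$paralog_consensus)) {
  vapply(paralogs, function(p) {
    splice_sequence(sim$truth$paralog_consensus[[p]], exons)
  }, character(1))
}

#' @rdname sim_transcripts
#' @export
default_exons <- function() {
  list(c(1000L, 1600L), c(3000L, 3900L), c(5000L, 5800L),
       c(8000L, 9200L), c(12000L, 12800L))
}

splice_sequence <- function(s, exons) {
  paste(vapply(exons, function(e) substr(s, e[1] + 1L, e[2]), character(1)),
        collapse = "")
}
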