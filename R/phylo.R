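## Copies emitted by the discovery module are colinear with the ancestral
## duplicon (substitution-only divergence), so equal-length sequences can be
## stacked directly into an alignment matrix.
aln_matrix <- function(seqs, mask = NULL, max_gap_frac = 0.2) {
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be equal length (anchored to the ancestral locus)")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  drop <- rep(FALSE, ncol(m))
  if (!is.null(mask)) drop[mask] <- TRUE
  gapfrac <- colMeans(m == "-" | m == "N")
  drop <- drop | gapfrac > max_gap_frac
  m[, !drop, drop = FALSE]
}

#' Pairwise distances between gene-family copies
#'
#' p-distance (mismatch fraction over compared columns) or its JC69
#' correction `-(3/4) log(1 - 4p/3)`; gap and N columns are excluded
#' pairwise. Columns listed in `mask` (e.g. VNTR-overlapping columns) and
#' columns with more than `max_gap_frac` gaps are removed first.
#'
#' @param seqs named character vector of equal-length anchored sequences.
#' @param model "p" or "JC69".
#' @param mask optional column indices to exclude.
#' @param max_gap_frac maximum per-column gap fraction retained.
#' @return symmetric numeric matrix of distances (substitutions/site).
#' @export
pairwise_distance <- function(seqs, model = c("p", "JC69"), mask = NULL,
                              max_gap_frac = 0.2) {
  model <- match.arg(model)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(seqs, mask, max_gap_frac)
  bin <- ape::as.DNAbin(m)
  d <- ape::dist.dna(bin, model = if (model == "p") "raw" else "JC69",
                     pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) {
    stop("distance undefined (p >= 0.75 under JC69 or no shared columns)")
  }
  dm
}

#' Neighbor-joining tree, midpoint rooted
#'
#' Standard NJ agglomeration on a distance matrix; negative branch lengths
#' are clamped to zero and the tree is midpoint rooted. NJ ties are
#' resolved deterministically by the input label order, so identical
#' matrices always give identical trees.
#'
#' @param D symmetric distance matrix with >= 3 labelled rows.
#' @return an `ape::phylo` tree.
#' @export
build_nj <- function(D) {
  if (nrow(as.matrix(D)) < 3L) stop("need at least 3 labels")
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  phangorn::midpoint(tr)
}

#' Bootstrap branch support for an NJ copy tree
#'
#' Resamples alignment columns, rebuilds the NJ tree per replicate, and
#' scores each internal branch of the reference tree by the percentage of
#' replicates containing the same bipartition. Internal branches of length
#' ~0 are collapsed first, so uninformative (tie-broken) resolutions do not
#' receive support.
#'
#' @param seqs named character vector of equal-length anchored sequences
#'   (>= 50 alignment columns).
#' @param n_reps bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @param model distance model passed to [pairwise_distance()].
#' @param mask,max_gap_frac column filtering as in [pairwise_distance()].
#' @return an `ape::phylo` tree with `node.label` percent supports
#'   (NA for the root).
#' @export
bootstrap_support <- function(seqs, n_reps = 100, seed = 1, model = "p",
                              mask = NULL, max_gap_frac = 0.2) {
  m <- aln_matrix(seqs, mask, max_gap_frac)
  if (ncol(m) < 50L) stop("need >= 50 alignment columns to resample")
  dist_fun <- function(mm) {
    d <- ape::dist.dna(ape::as.DNAbin(mm),
                       model = if (model == "p") "raw" else "JC69",
                       pairwise.deletion = TRUE)
    d[!is.finite(d)] <- 0.75
    d
  }
  f <- function(mm) {
    tr <- ape::nj(dist_fun(mm))
    tr$edge.length[tr$edge.length < 0] <- 0
    phangorn::midpoint(tr)
  }
  ref <- f(m)
  ref <- ape::di2multi(ref, tol = 1e-12)
  if (ref$Nnode <= 1L) {
    ref$node.label <- rep(NA_character_, ref$Nnode)
    return(ref)
  }
  bp <- local_seed(seed, "bootstrap", {
    reps <- lapply(seq_len(n_reps), function(i) {
      f(m[, sample.int(ncol(m), replace = TRUE), drop = FALSE])
    })
    ape::prop.clades(ref, reps, rooted = FALSE)
  })
  bp[is.na(bp)] <- 0L
  lab <- round(100 * bp / n_reps, 1)
  lab[1] <- NA  # root pseudo-bipartition
  ref$node.label <- as.character(lab)
  ref
}

node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

clade_tips <- function(tree, node) {
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Assign copies to paralog clades
#'
#' Maximal clades with support above `support_threshold` containing the
#' anchors of exactly one paralog label inherit that label. Labels whose
#' anchors are never separated by a supported clade, or whose anchors lie
#' closer than `merge_distance`, are merged into a joint "X/Y" label.
#' Supported clades containing no anchor are named after the nearest
#' labelled anchor with an "L" suffix (numbered by descending clade size);
#' copies outside any supported clade fall back to their nearest anchor.
#'
#' @param tree a supported tree from [bootstrap_support()].
#' @param anchors named character vector: tip label -> paralog label for
#'   the reference copies.
#' @param support_threshold percent support defining a clade.
#' @param merge_distance cophenetic separation below which anchor labels
#'   are merged; default is 3x the median intra-anchor-clade distance.
#' @return data.frame of class `clade_assignment`: copy, label, provenance
#'   ("anchor", "merged" or "nearest-neighbor").
#' @export
assign_paralogs <- function(tree, anchors, support_threshold = 75,
                            merge_distance = NULL) {
  if (length(anchors) < 1L) stop("need at least one anchor")
  tips <- tree$tip.label
  anchors <- anchors[names(anchors) %in% tips]
  if (length(anchors) == 0L) stop("no anchor present in the tree")
  ntip <- length(tips)
  sup <- node_support(tree)
  coph <- ape::cophenetic.phylo(tree)

  supported_nodes <- which(!is.na(sup) & sup > support_threshold) + ntip
  clades <- lapply(supported_nodes, function(nd) clade_tips(tree, nd))

  result <- data.frame(copy = tips, label = NA_character_,
                       provenance = NA_character_,
                       stringsAsFactors = FALSE)
  labs <- sort(unique(anchors))

  nearest_anchor_label <- function(tip_set) {
    d <- coph[tip_set, names(anchors), drop = FALSE]
    anchors[[colnames(d)[which.min(apply(d, 2L, min))]]]
  }

  if (length(clades) == 0L) {
    for (i in seq_len(nrow(result))) {
      result$label[i] <- nearest_anchor_label(result$copy[i])
    }
    result$provenance <- "nearest-neighbor"
    class(result) <- c("clade_assignment", "data.frame")
    return(result)
  }

  anchors_of <- function(lab) names(anchors)[anchors == lab]
  clade_has <- function(cl, lab) {
    a <- anchors_of(lab)
    c(all_in = all(a %in% cl), any_in = any(a %in% cl))
  }

  ## minimal supported clade containing all anchors of a label
  min_clade <- function(lab) {
    sizes <- vapply(clades, length, integer(1))
    cand <- which(vapply(clades, function(cl)
      clade_has(cl, lab)[["all_in"]], logical(1)))
    if (length(cand) == 0L) return(NULL)
    clades[[cand[which.min(sizes[cand])]]]
  }

  if (is.null(merge_distance)) {
    intra <- vapply(labs, function(lab) {
      cl <- min_clade(lab)
      if (is.null(cl) || length(cl) < 2L) return(NA_real_)
      median(coph[cl, cl][upper.tri(coph[cl, cl])])
    }, numeric(1))
    merge_distance <- if (all(is.na(intra))) 0 else
      3 * median(intra, na.rm = TRUE)
  }

  ## separation test: a supported clade isolates X's anchors from Y's
  separated <- function(x, y) {
    iso <- function(a, b) {
      any(vapply(clades, function(cl) {
        clade_has(cl, a)[["all_in"]] && !clade_has(cl, b)[["any_in"]]
      }, logical(1)))
    }
    iso(x, y) && iso(y, x)
  }
  anchor_sep <- function(x, y) {
    min(coph[anchors_of(x), anchors_of(y), drop = FALSE])
  }

  parent_grp <- seq_along(labs)
  find_grp <- function(i) {
    while (parent_grp[i] != i) i <- parent_grp[i]
    i
  }
  if (length(labs) > 1L) {
    for (i in seq_len(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        if (!separated(labs[i], labs[j]) ||
            anchor_sep(labs[i], labs[j]) < merge_distance) {
          parent_grp[find_grp(j)] <- find_grp(i)
        }
      }
    }
  }
  grp_id <- vapply(seq_along(labs), find_grp, integer(1))
  groups <- split(labs, grp_id)
  group_label <- vapply(groups, function(g) paste(sort(g), collapse = "/"),
                        character(1))

  assigned_clades <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    ga <- unlist(lapply(g, anchors_of))
    other <- setdiff(names(anchors), ga)
    cand <- which(vapply(clades, function(cl) {
      any(ga %in% cl) && !any(other %in% cl)
    }, logical(1)))
    ## a candidate clade that properly contains a supported anchorless
    ## clade would swallow what the field names as a distinct "L"
    ## paralog; prefer the largest candidate without one
    has_free_subclade <- vapply(cand, function(ci) {
      cl <- clades[[ci]]
      any(vapply(clades, function(s) {
        length(s) >= 2L && length(s) < length(cl) && all(s %in% cl) &&
          !any(names(anchors) %in% s)
      }, logical(1)))
    }, logical(1))
    if (any(!has_free_subclade)) cand <- cand[!has_free_subclade]
    lab <- group_label[gi]
    prov <- if (length(g) > 1L) "merged" else "anchor"
    if (length(cand)) {
      best <- cand[which.max(vapply(clades[cand], length, integer(1)))]
      members <- clades[[best]]
    } else {
      members <- ga
    }
    assigned_clades[[lab]] <- members
    sel <- result$copy %in% members
    result$label[sel] <- lab
    result$provenance[sel] <- prov
  }

  ## anchorless supported clades among still-unlabelled tips
  un <- is.na(result$label)
  if (any(un)) {
    free_clades <- Filter(function(cl) {
      !any(names(anchors) %in% cl) && all(cl %in% result$copy[un])
    }, clades)
    if (length(free_clades)) {
      ## maximal first
      free_clades <- free_clades[order(-vapply(free_clades, length,
                                               integer(1)))]
      suffix_count <- integer(0)
      taken <- character(0)
      for (cl in free_clades) {
        if (any(cl %in% taken)) next
        base <- nearest_anchor_label(cl)
        base_grp <- group_label[vapply(groups, function(g) base %in% g,
                                       logical(1))]
        nth <- (if (is.na(suffix_count[base_grp])) 0L else
          suffix_count[base_grp]) + 1L
        suffix_count[base_grp] <- nth
        sel <- result$copy %in% cl
        result$label[sel] <- paste0(base_grp, "L", nth)
        result$provenance[sel] <- "nearest-neighbor"
        taken <- c(taken, cl)
      }
    }
  }

  ## leftovers: nearest anchor
  un <- which(is.na(result$label))
  for (i in un) {
    base <- nearest_anchor_label(result$copy[i])
    result$label[i] <- group_label[vapply(groups, function(g) base %in% g,
                                          logical(1))]
    result$provenance[i] <- "nearest-neighbor"
  }
  class(result) <- c("clade_assignment", "data.frame")
  result
}

#' Strict-clock proportional node dating
#'
#' Roots the tree on the outgroup, then assigns each node an age
#' proportional to its mean root-to-tip path fraction:
#' `age(v) = root_age * mean over tips t under v of dist(v,t)/dist(root,t)`.
#' Leaves get age 0 and ages are clamped to decrease from root to tips.
#' The estimate is scale invariant: multiplying all branch lengths by a
#' constant leaves ages unchanged.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param outgroup outgroup tip label used to root the tree.
#' @param root_age calibration age of the root, Myr.
#' @return list with `tree` (rooted) and `ages` (named numeric, tips then
#'   internal nodes "node<k>"), in Myr.
#' @export
date_nodes <- function(tree, outgroup, root_age) {
  if (root_age <= 0) stop("root_age must be positive")
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  tip_depth <- depth[seq_len(ntip)]
  if (all(tip_depth == 0)) stop("zero root height")
  ages <- numeric(ntip + tr$Nnode)
  for (nd in (ntip + 1L):(ntip + tr$Nnode)) {
    tt <- phangorn::Descendants(tr, nd, type = "tips")[[1]]
    frac <- (depth[tt] - depth[nd]) / depth[tt]
    frac <- frac[is.finite(frac)]
    if (length(frac) == 0L) stop("zero root height through node ", nd)
    ages[nd] <- root_age * mean(frac)
  }
  ## clamp to monotone root -> tip
  ord <- order(depth[(ntip + 1L):(ntip + tr$Nnode)])
  for (nd in (ntip + ord)) {
    par <- tr$edge[tr$edge[, 2] == nd, 1]
    if (length(par)) ages[nd] <- min(ages[nd], ages[par])
  }
  names(ages) <- c(tr$tip.label, paste0("node", (ntip + 1L):(ntip + tr$Nnode)))
  list(tree = tr, ages = ages)
}
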