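## ---- token helpers for configuration strings ----

tok_name <- function(tokens) sub("^[+-]", "", tokens)
tok_sign <- function(tokens) ifelse(startsWith(tokens, "-"), -1L, 1L)

## Positional matching of duplicate token names: the k-th occurrence of a
## name in `a` is matched to the k-th occurrence in `b`; leftover
## occurrences become private markers (indel material). Returns signed
## integer marker sequences with ids unique within each genome and shared
## ids for matched occurrences.
match_tokens <- function(a, b) {
  na <- tok_name(a); nb <- tok_name(b)
  sa <- tok_sign(a); sb <- tok_sign(b)
  ids_a <- integer(length(a)); ids_b <- integer(length(b))
  next_id <- 1L
  for (nm in unique(c(na, nb))) {
    ia <- which(na == nm); ib <- which(nb == nm)
    k <- min(length(ia), length(ib))
    if (k > 0L) {
      for (j in seq_len(k)) {
        ids_a[ia[j]] <- next_id
        ids_b[ib[j]] <- next_id
        next_id <- next_id + 1L
      }
    }
    extra <- c(ia[seq_len(length(ia) - k) + k])
    for (j in extra) {
      ids_a[j] <- next_id; next_id <- next_id + 1L
    }
    extrb <- c(ib[seq_len(length(ib) - k) + k])
    for (j in extrb) {
      ids_b[j] <- next_id; next_id <- next_id + 1L
    }
  }
  list(a = ids_a * sa, b = ids_b * sb)
}

## maximal runs of private (non-common) markers in a sequence
count_runs <- function(x, common) {
  if (length(x) == 0L) return(0L)
  priv <- !(abs(x) %in% common)
  if (!any(priv)) return(0L)
  r <- rle(priv)
  sum(r$values)
}

## extremity encoding: marker m has tail 2m-1, head 2m
ext_left <- function(x) ifelse(x > 0, 2L * x - 1L, -2L * x)
ext_right <- function(x) ifelse(x > 0, 2L * x, -2L * x - 1L)

## Elements (adjacencies + telomeres) of one linear genome restricted to
## the common markers; each element may carry one indel run label.
genome_elements_r <- function(x, common, genome_tag) {
  keep <- abs(x) %in% common
  els <- list()
  if (!any(keep)) return(els)
  idx <- which(keep)
  m <- x[idx]
  k <- length(m)
  run_before <- logical(k + 1L)
  run_before[1] <- idx[1] > 1L
  if (k > 1L) {
    for (i in 2:k) run_before[i] <- (idx[i] - idx[i - 1L]) > 1L
  }
  run_before[k + 1L] <- idx[k] < length(x)
  els[[1]] <- list(genome = genome_tag, exts = ext_left(m[1]),
                   run = run_before[1])
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      els[[length(els) + 1L]] <- list(
        genome = genome_tag,
        exts = c(ext_right(m[i]), ext_left(m[i + 1L])),
        run = run_before[i + 1L])
    }
  }
  els[[length(els) + 1L]] <- list(genome = genome_tag,
                                  exts = ext_right(m[k]),
                                  run = run_before[k + 1L])
  els
}

## Adjacency-graph decomposition for two linear marker sequences with
## unique markers per genome: N common markers, cycles, odd paths, and
## per-component indel-run counts (number of elements carrying a run of
## markers private to one genome).
dcj_graph <- function(a, b) {
  common <- intersect(abs(a), abs(b))
  N <- length(common)
  if (N == 0L) return(list(N = 0L))
  els <- c(genome_elements_r(a, common, "A"),
           genome_elements_r(b, common, "B"))
  ## extremity -> element index per genome
  lookup <- list(A = new.env(parent = emptyenv()),
                 B = new.env(parent = emptyenv()))
  for (i in seq_along(els)) {
    for (e in els[[i]]$exts) {
      assign(as.character(e), i, envir = lookup[[els[[i]]$genome]])
    }
  }
  other <- c(A = "B", B = "A")
  visited <- logical(length(els))
  components <- list()

  walk_from <- function(start) {
    ## returns ordered element indices; follows shared extremities
    path <- integer(0)
    cur <- start
    ent <- NA_integer_  # extremity we entered through
    repeat {
      visited[cur] <<- TRUE
      path <- c(path, cur)
      exts <- els[[cur]]$exts
      out_ext <- if (length(exts) == 1L) {
        if (is.na(ent)) exts else NA_integer_
      } else {
        if (is.na(ent)) exts[1] else setdiff(exts, ent)
      }
      if (length(out_ext) == 0L || is.na(out_ext)) return(path)
      nxt <- get(as.character(out_ext),
                 envir = lookup[[other[[els[[cur]]$genome]]]])
      if (visited[nxt]) return(path)   # closed a cycle
      ent <- out_ext
      cur <- nxt
    }
  }

  ## paths first (start at telomere elements)
  telo <- which(vapply(els, function(e) length(e$exts) == 1L, logical(1)))
  for (s in telo) {
    if (visited[s]) next
    p <- walk_from(s)
    components[[length(components) + 1L]] <- list(idx = p, type = "path")
  }
  for (s in seq_along(els)) {
    if (visited[s]) next
    p <- walk_from(s)
    components[[length(components) + 1L]] <- list(idx = p, type = "cycle")
  }

  C <- sum(vapply(components, function(cp) cp$type == "cycle", logical(1)))
  odd_paths <- sum(vapply(components, function(cp) {
    cp$type == "path" && (length(cp$idx) - 1L) %% 2L == 1L
  }, logical(1)))
  runs <- vapply(components, function(cp) {
    sum(vapply(cp$idx, function(i) els[[i]]$run, logical(1)))
  }, integer(1))
  list(N = N, C = C, I = odd_paths, runs = runs,
       d_dcj = N - C - odd_paths / 2)
}

## Closed-form DCJ-indel bounds. Upper: d_dcj plus one indel per private
## run (the scenario that sorts the common markers optimally and handles
## every run with its own operation). Lower: d_dcj plus one op per
## pending indel direction. Whenever the bounds disagree the run-merge
## credit is resolved exactly by the IDA* refinement.
dcj_formula_bounds <- function(a, b) {
  g <- dcj_graph(a, b)
  if (g$N == 0L) {
    d <- (length(a) > 0L) + (length(b) > 0L)
    return(list(lower = d, upper = d))
  }
  common <- intersect(abs(a), abs(b))
  runs_a <- count_runs(a, common)
  runs_b <- count_runs(b, common)
  ## a deletion can simultaneously remove a run and heal a breakpoint,
  ## so the sound lower bound takes the max, not the sum
  list(lower = max(g$d_dcj, (runs_a > 0L) + (runs_b > 0L)),
       upper = g$d_dcj + runs_a + runs_b)
}

#' DCJ-indel rearrangement distance between locus configurations
#'
#' Minimum number of double-cut-and-join rearrangements plus insertions or
#' deletions of contiguous runs of private tokens transforming one
#' configuration into the other (linear chromosomes, capping-free).
#' Duplicate token names are disambiguated by positional matching: the
#' k-th occurrence in `a` pairs with the k-th occurrence in `b`, leftover
#' occurrences become indel material. Computed by the adjacency-graph
#' formula `d = N - C - I/2` plus indel-run terms; validated against the
#' exhaustive search oracle [dcj_distance_oracle()] on small instances.
#'
#' @param a,b token character vectors (elements like "+A1", "-G2"; a bare
#'   name means "+"), or `configuration` objects.
#' @return non-negative integer distance.
#' @seealso [dcj_distance_oracle()]
#' @export
dcj_indel_distance <- function(a, b) {
  a <- config_tokens(a); b <- config_tokens(b)
  m <- match_tokens(a, b)
  bounds <- dcj_formula_bounds(m$a, m$b)
  if (bounds$lower >= bounds$upper) return(as.integer(bounds$upper))
  ## resolve the run-merge credit exactly; the heuristic search is driven
  ## by the same adjacency-graph bound and never exceeds `upper`
  dcj_ida_distance_cpp(m$a, m$b, max_bound = as.integer(bounds$upper))
}

#' Exhaustive-search DCJ-indel distance (oracle)
#'
#' Plain breadth-first search over the move graph. Every sorting scenario
#' can be ordered with deletions before insertions, so two deletion-only
#' DCJ waves (one from each configuration, each deleting its own private
#' tokens) are expanded until they meet at a common middle genome; the
#' distance is the shortest met total. Exponential: intended for
#' validating [dcj_indel_distance()] on instances of at most ~8 tokens.
#'
#' @param a,b token character vectors or `configuration` objects.
#' @param max_depth search depth cap.
#' @return non-negative integer distance.
#' @export
dcj_distance_oracle <- function(a, b, max_depth = 12L) {
  a <- config_tokens(a); b <- config_tokens(b)
  m <- match_tokens(a, b)
  dcj_bfs_distance_cpp(m$a, m$b, max_depth)
}

## accept configuration objects or plain token vectors
config_tokens <- function(x) {
  if (inherits(x, "configuration")) x <- x$tokens
  if (length(x) == 0L) return(character(0))
  ifelse(grepl("^[+-]", x), x, paste0("+", x))
}
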