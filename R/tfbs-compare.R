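#' @title Shared motif content and motif-order shuffling
#' @description Quantifies shared transcription-factor motif content between
#'   ortholog CRE pairs and measures motif-order shuffling with the
#'   normalized Kendall tau rank distance, taking the minimum over both
#'   orientations of the second list and over all unique ranking rows when a
#'   motif recurs noncontiguously. Cohen's d summarizes between-class effect
#'   sizes.
#' @name tfbs-compare
NULL

#' Drop overlapping hits of the same motif, keeping the higher score
#'
#' Greedy by descending score (ties: lower start): a hit is retained unless
#' it overlaps an already-retained hit of the same motif id.
#'
#' @param hits Data.frame of motif hits within one CRE window: `chrom`,
#'   `start`, `end`, `motif_id`, `score`, `strand`.
#' @return The retained hits, in ascending `start` order.
#' @export
dedupe_same_motif_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$start)
  keep <- logical(nrow(hits))
  for (i in ord) {
    prior <- which(keep & hits$motif_id == hits$motif_id[[i]])
    clash <- any(hits$start[prior] < hits$end[[i]] &
                   hits$end[prior] > hits$start[[i]])
    if (!clash) keep[[i]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

#' Shared motif content of two hit lists
#'
#' Per motif id the shared count is `min(count_a, count_b)`; `n_shared` sums
#' these over motifs. Both lists are expected to be deduplicated with
#' [dedupe_same_motif_hits()] first.
#'
#' @param hits_a,hits_b Deduplicated hit data.frames.
#' @return List with `shared` (named integer vector of per-motif shared
#'   counts, motifs with 0 dropped) and `n_shared`.
#' @export
count_shared_motifs <- function(hits_a, hits_b) {
  ta <- table(hits_a$motif_id)
  tb <- table(hits_b$motif_id)
  common <- sort(intersect(names(ta), names(tb)))
  shared <- vapply(common, function(m) min(ta[[m]], tb[[m]]), integer(1))
  list(shared = shared, n_shared = sum(shared))
}

#' Build the ranking set of a hit list
#'
#' Prepares the 5'-3' motif order of a CRE for rank comparison:
#' largely-overlapping hits from *different* motifs (overlap of at least
#' `min_cross_overlap` bp) are resolved keeping the highest score; contiguous
#' runs of the same motif collapse to a single match; and when a motif still
#' recurs noncontiguously (e.g. A,B,C,A,D) the order expands into a matrix of
#' unique ranking rows, one per choice of which occurrence to keep
#' (A,B,C,D and B,C,A,D), each row a permutation of the motif set.
#'
#' @param hits Deduplicated hits restricted to the shared motif set of the
#'   pair.
#' @param min_cross_overlap Minimum bp overlap between hits of different
#'   motifs that triggers filtering (default 8; the boundary is inclusive).
#' @param max_rows Cap on expanded ranking rows for pathological repeat
#'   structures (default 64).
#' @return List of class `ranking_set`: `motifs` (sorted motif set), `rows`
#'   (list of character vectors, each a permutation of `motifs`), `order`
#'   (the collapsed 5'-3' motif sequence), `hits` (the retained hit rows), or
#'   `NULL` when fewer than two distinct motifs survive filtering.
#' @export
prepare_ranking <- function(hits, min_cross_overlap = 8L, max_rows = 64L) {
  if (nrow(hits) == 0L) return(NULL)
  # cross-motif overlap filter: greedy by descending score, ties lower start
  ord <- order(-hits$score, hits$start)
  keep <- logical(nrow(hits))
  for (i in ord) {
    prior <- which(keep & hits$motif_id != hits$motif_id[[i]])
    ov <- pmin(hits$end[prior], hits$end[[i]]) -
      pmax(hits$start[prior], hits$start[[i]])
    if (!any(ov >= min_cross_overlap)) keep[[i]] <- TRUE
  }
  h <- hits[keep, , drop = FALSE]
  h <- h[order(h$start, h$end), , drop = FALSE]
  # collapse contiguous same-motif runs to a singular match
  seq5to3 <- h$motif_id
  runs <- rle(seq5to3)$values
  if (length(unique(runs)) < 2L) return(NULL)
  rows <- .expand_ranking_rows(runs, max_rows)
  structure(list(motifs = sort(unique(runs)), rows = rows, order = runs,
                 hits = h),
            class = "ranking_set")
}

# expand a collapsed motif sequence with noncontiguous recurrences into all
# unique rows keeping exactly one occurrence per motif
.expand_ranking_rows <- function(runs, max_rows) {
  occ <- split(seq_along(runs), runs)
  combos <- expand.grid(occ, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    idx <- sort(unlist(combos[i, ]))
    row <- runs[idx]
    key <- paste(row, collapse = "\r")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- row
    }
    if (length(rows) >= max_rows) break
  }
  rows
}

# normalized Kendall tau distance between two permutations of one set:
# discordant pairs / (n(n-1)/2), counted over b's ranks in a's order
.kendall_distance <- function(a, b) {
  n <- length(a)
  r <- match(b, a)
  disc <- 0L
  for (i in seq_len(n - 1L)) {
    disc <- disc + sum(r[(i + 1L):n] < r[[i]])
  }
  disc / (n * (n - 1L) / 2)
}

#' Minimum normalized Kendall tau distance between two ranking sets
#'
#' Computes the normalized Kendall tau distance between every unique ranking
#' row of `ranking_a` and every row of `ranking_b` in both orientations of
#' `ranking_b` (the 5'-3' order of the reference list compared against the
#' second list as written and fully reversed), returning the smallest value.
#'
#' @param ranking_a,ranking_b `ranking_set` objects over the same motif set.
#' @return List of class `kendall_result`: `k_d` in \[0, 1\], `orientation`
#'   (`"forward"`/`"reverse"` of the second list at the minimum; forward wins
#'   ties) and `n` (motif set size).
#' @export
normalized_kendall_min <- function(ranking_a, ranking_b) {
  stopifnot(inherits(ranking_a, "ranking_set"), inherits(ranking_b, "ranking_set"))
  if (!identical(ranking_a$motifs, ranking_b$motifs)) {
    stop("ranking sets cover different motif sets")
  }
  if (length(ranking_a$motifs) < 2L) stop("need at least 2 distinct motifs")
  best <- Inf
  best_orient <- "forward"
  for (ra in ranking_a$rows) {
    for (rb in ranking_b$rows) {
      kf <- .kendall_distance(ra, rb)
      kr <- .kendall_distance(ra, rev(rb))
      if (kf < best) { best <- kf; best_orient <- "forward" }
      if (kr < best) { best <- kr; best_orient <- "reverse" }
    }
  }
  structure(list(k_d = best, orientation = best_orient,
                 n = length(ranking_a$motifs)),
            class = "kendall_result")
}

#' Cohen's d effect size with magnitude label
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n_x-1)s_x^2 + (n_y-1)s_y^2) / (n_x+n_y-2))`. Magnitude
#' labels on `|d|`: below 0.2 `"small"`, 0.2 to 0.5 `"medium"`, above 0.5
#' `"large"`.
#'
#' @param x,y Numeric samples of size at least 2 each.
#' @return List with `d` and `magnitude`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) {
      return(list(d = 0, magnitude = "small"))
    }
    stop("pooled standard deviation is zero; Cohen's d undefined")
  }
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  mag <- if (abs(d) < 0.2) "small" else if (abs(d) <= 0.5) "medium" else "large"
  list(d = d, magnitude = mag)
}

#' Motif-shuffling pipeline over ortholog CRE pairs
#'
#' For each pair: deduplicate same-motif overlaps, restrict both hit lists to
#' the pair's shared motif set, drop pairs with fewer than `min_shared`
#' shared motif hits, build ranking sets (re-intersecting the motif sets if
#' the cross-motif overlap filter removed a motif from one side only) and
#' take the minimum normalized Kendall tau distance. Per-class medians and
#' pairwise Cohen's d are reported alongside.
#'
#' @param pairs List of pair records, each
#'   `list(pair_id, class, hits_a, hits_b)`.
#' @param min_shared Minimum shared motif hits for a pair to enter the rank
#'   comparison (default 6).
#' @param min_cross_overlap Passed to [prepare_ranking()].
#' @return List with `results` (data.frame: `pair_id`, `class`, `n_shared`,
#'   `k_d`, `orientation`), `dropped` (data.frame: `pair_id`, `reason`),
#'   `medians` (named per-class medians) and `effect_sizes` (data.frame of
#'   pairwise class contrasts with Cohen's d and magnitude, `NA` when a class
#'   has fewer than 2 pairs).
#' @export
kendall_pipeline <- function(pairs, min_shared = 6L, min_cross_overlap = 8L) {
  res <- list(); dropped <- list()
  for (p in pairs) {
    ha <- dedupe_same_motif_hits(p$hits_a)
    hb <- dedupe_same_motif_hits(p$hits_b)
    sh <- count_shared_motifs(ha, hb)
    if (sh$n_shared < min_shared) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(pair_id = p$pair_id,
                   reason = sprintf("n_shared=%d < %d", sh$n_shared, min_shared))
      next
    }
    motifs <- names(sh$shared)
    ra <- rb <- NULL
    # the cross-motif filter can remove a motif from one list only; shrink the
    # shared set and retry until both rankings cover the same motifs
    repeat {
      ra <- prepare_ranking(ha[ha$motif_id %in% motifs, , drop = FALSE],
                            min_cross_overlap)
      rb <- prepare_ranking(hb[hb$motif_id %in% motifs, , drop = FALSE],
                            min_cross_overlap)
      if (is.null(ra) || is.null(rb)) break
      if (identical(ra$motifs, rb$motifs)) break
      motifs <- intersect(ra$motifs, rb$motifs)
      if (length(motifs) < 2L) { ra <- NULL; break }
    }
    if (is.null(ra) || is.null(rb)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(pair_id = p$pair_id,
                   reason = "fewer than 2 distinct motifs after filtering")
      next
    }
    k <- normalized_kendall_min(ra, rb)
    res[[length(res) + 1L]] <-
      data.frame(pair_id = p$pair_id, class = p$class, n_shared = sh$n_shared,
                 k_d = k$k_d, orientation = k$orientation)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(pair_id = character(0), class = character(0),
               n_shared = integer(0), k_d = numeric(0), orientation = character(0))
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(pair_id = character(0), reason = character(0))
  classes <- unique(results$class)
  medians <- vapply(classes, function(cl)
    stats::median(results$k_d[results$class == cl]), numeric(1))
  eff <- list()
  if (length(classes) >= 2L) {
    cmb <- utils::combn(sort(classes), 2L)
    for (j in seq_len(ncol(cmb))) {
      x <- results$k_d[results$class == cmb[1, j]]
      y <- results$k_d[results$class == cmb[2, j]]
      if (length(x) >= 2L && length(y) >= 2L) {
        cd <- tryCatch(cohens_d(x, y),
                       error = function(e) list(d = NA_real_, magnitude = NA_character_))
      } else {
        cd <- list(d = NA_real_, magnitude = NA_character_)
      }
      eff[[j]] <- data.frame(class_a = cmb[1, j], class_b = cmb[2, j],
                             d = cd$d, magnitude = cd$magnitude)
    }
  }
  effect_sizes <- if (length(eff)) do.call(rbind, eff) else
    data.frame(class_a = character(0), class_b = character(0),
               d = numeric(0), magnitude = character(0))
  list(results = results, dropped = dropped, medians = medians,
       effect_sizes = effect_sizes)
}
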