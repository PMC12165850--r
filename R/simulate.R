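#' @title Synthetic multispecies genome simulator
#' @description Simulates colinear anchor blocks shared across a species
#'   tree, with per-branch divergence that can destroy direct alignability
#'   while preserving bridged alignability, and emits per-pair chain files
#'   plus ground-truth ortholog positions. Also generates paired motif-hit
#'   lists with a controlled number of adjacent transpositions. These
#'   fixtures make the whole projection pipeline testable offline.
#' @name simulate
NULL

#' Build a species tree from an edge list
#'
#' All nodes are species; branch lengths are in arbitrary divergence units.
#'
#' @param edges Data.frame with columns `from`, `to`, `length` describing an
#'   acyclic connected graph over species ids.
#' @return A `species_tree` object.
#' @export
species_tree <- function(edges) {
  stopifnot(all(c("from", "to", "length") %in% names(edges)),
            all(edges$length >= 0))
  species <- sort(unique(c(edges$from, edges$to)))
  if (nrow(edges) != length(species) - 1L) {
    stop("edge count must be species count - 1 (tree)")
  }
  structure(list(species = species, edges = edges), class = "species_tree")
}

#' A linear (caterpillar) species tree
#'
#' @param species Character vector of species ids, in chain order.
#' @param lengths Branch lengths between consecutive species (recycled).
#' @return A `species_tree`.
#' @export
linear_tree <- function(species, lengths = 1) {
  n <- length(species)
  stopifnot(n >= 2L)
  species_tree(data.frame(from = species[-n], to = species[-1],
                          length = rep_len(lengths, n - 1L)))
}

# indices of tree edges on the unique path between two species (BFS)
.tree_path_edges <- function(tree, a, b) {
  if (a == b) return(integer(0))
  adj <- list()
  for (k in seq_len(nrow(tree$edges))) {
    e <- tree$edges[k, ]
    adj[[e$from]] <- rbind(adj[[e$from]], data.frame(to = e$to, edge = k))
    adj[[e$to]] <- rbind(adj[[e$to]], data.frame(to = e$from, edge = k))
  }
  prev <- list()
  queue <- a
  seen <- a
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur == b) break
    nb <- adj[[cur]]
    for (j in seq_len(NROW(nb))) {
      if (!nb$to[[j]] %in% seen) {
        seen <- c(seen, nb$to[[j]])
        prev[[nb$to[[j]]]] <- list(node = cur, edge = nb$edge[[j]])
        queue <- c(queue, nb$to[[j]])
      }
    }
  }
  if (!b %in% seen) stop(sprintf("species %s and %s are disconnected", a, b))
  path <- integer(0)
  cur <- b
  while (cur != a) {
    path <- c(path, prev[[cur]]$edge)
    cur <- prev[[cur]]$node
  }
  path
}

#' Simulate anchor blocks across a species tree
#'
#' An ancestral chromosome of `n_anchors` anchor slots (length `anchor_len`)
#' separated by lognormal spacers evolves along the tree: each anchor accrues
#' an independent exponential divergence increment on every branch (mean =
#' branch length), and an anchor is alignable between two species iff its
#' summed divergence along the tree path between them is below `theta`. A
#' bridging species at intermediate distance can therefore stay alignable to
#' both endpoints while the endpoints are not directly alignable — the regime
#' that makes bridged projection gain orthologs. Spacer lengths are resampled
#' per species (insertions/deletions); anchor lengths are conserved. An
#' optional inversion flips a contiguous anchor run in one species to
#' exercise minus-strand chains. Fully deterministic given `seed`.
#'
#' @param tree A [species_tree()].
#' @param n_anchors Number of ancestral anchor slots. Default 200.
#' @param anchor_len Anchor length in bp. Default 60.
#' @param spacer_meanlog,spacer_sdlog Lognormal parameters of spacer lengths
#'   in bp. Defaults `log(800)` and 0.5.
#' @param theta Divergence threshold above which a pair loses the anchor.
#' @param seed Integer seed; all randomness flows from it.
#' @param inversion Optional `list(species=, from=, to=)` flipping anchors
#'   `from..to` (1-based slot indices) in one species.
#' @param divergence Function `(n, branch_length) -> n increments` drawing
#'   per-anchor divergence on one branch. Default exponential with mean equal
#'   to the branch length; a degenerate function (constant increments) makes
#'   alignability fully deterministic.
#' @return An `ipp_sim` object: species coordinates of every anchor, per-pair
#'   alignability, per-species chromosome sizes, and the generating
#'   parameters. Use [chains_from_sim()], [sim_truth_map()],
#'   [oracle_project_point()] and [write_sim()] to consume it.
#' @export
simulate_multispecies_anchors <- function(tree, n_anchors = 200L,
                                          anchor_len = 60L,
                                          spacer_meanlog = log(800),
                                          spacer_sdlog = 0.5,
                                          theta = 2.2, seed = 1L,
                                          inversion = NULL,
                                          divergence = function(n, len)
                                            stats::rexp(n) * len) {
  stopifnot(inherits(tree, "species_tree"), theta > 0, n_anchors >= 1L)
  sp <- tree$species
  ns <- length(sp)
  ne <- nrow(tree$edges)
  sim <- .with_seed(seed, {
    div <- vapply(seq_len(ne),
                  function(e) divergence(n_anchors, tree$edges$length[[e]]),
                  numeric(n_anchors))
    div <- matrix(div, n_anchors, ne)
    spacers <- matrix(pmax(1L, round(stats::rlnorm((n_anchors + 1L) * ns,
                                                   spacer_meanlog, spacer_sdlog))),
                     n_anchors + 1L, ns, dimnames = list(NULL, sp))
    list(div = div, spacers = spacers)
  })
  # anchor coordinates per species: spacer0 anchor1 spacer1 ... anchorN spacerN
  starts <- matrix(0L, n_anchors, ns, dimnames = list(NULL, sp))
  for (s in seq_len(ns)) {
    starts[, s] <- cumsum(sim$spacers[-(n_anchors + 1L), s]) +
      (seq_len(n_anchors) - 1L) * anchor_len
  }
  sizes <- stats::setNames(
    colSums(sim$spacers) + n_anchors * anchor_len, sp)
  inverted <- matrix(FALSE, n_anchors, ns, dimnames = list(NULL, sp))
  if (!is.null(inversion)) {
    s <- inversion$species
    f <- inversion$from; t <- inversion$to
    stopifnot(s %in% sp, f >= 1L, t <= n_anchors, f <= t)
    seg_start <- starts[f, s]
    seg_end <- starts[t, s] + anchor_len
    idx <- f:t
    new_start <- seg_start + (seg_end - (starts[idx, s] + anchor_len))
    starts[idx, s] <- new_start
    inverted[idx, s] <- TRUE
  }
  align <- list()
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      pe <- .tree_path_edges(tree, sp[[i]], sp[[j]])
      pd <- if (length(pe) == 1L) sim$div[, pe] else rowSums(sim$div[, pe, drop = FALSE])
      align[[.pair_key(sp[[i]], sp[[j]])]] <- pd < theta
    }
  }
  if (!any(unlist(align))) {
    warning("theta too small: no anchor is alignable in any species pair")
  }
  structure(list(
    tree = tree, species = sp, n_anchors = n_anchors, anchor_len = anchor_len,
    spacers = sim$spacers, starts = starts, inverted = inverted,
    sizes = sizes, chrom = "chr1", alignable = align,
    params = list(theta = theta, seed = seed,
                  spacer_meanlog = spacer_meanlog, spacer_sdlog = spacer_sdlog)
  ), class = "ipp_sim")
}

#' @export
print.ipp_sim <- function(x, ...) {
  cat(sprintf("<ipp_sim: %d species, %d anchors of %d bp, theta=%g, seed=%d>\n",
              length(x$species), x$n_anchors, x$anchor_len,
              x$params$theta, x$params$seed))
  invisible(x)
}

# anchor data.frame of one pair from a simulation, in anchors_from_chains()
# column layout; orientation "inverted" when exactly one species carries the
# inversion
sim_pair_anchors <- function(sim, a, b) {
  al <- sim$alignable[[.pair_key(a, b)]]
  idx <- which(al)
  if (!length(idx)) {
    return(data.frame(species_a = character(0), chrom_a = character(0),
                      start_a = integer(0), end_a = integer(0),
                      species_b = character(0), chrom_b = character(0),
                      start_b = integer(0), end_b = integer(0),
                      orientation = character(0), chain_id = integer(0)))
  }
  ori <- ifelse(sim$inverted[idx, a] != sim$inverted[idx, b], "inverted", "same")
  data.frame(
    species_a = a, chrom_a = sim$chrom,
    start_a = sim$starts[idx, a], end_a = sim$starts[idx, a] + sim$anchor_len,
    species_b = b, chrom_b = sim$chrom,
    start_b = sim$starts[idx, b], end_b = sim$starts[idx, b] + sim$anchor_len,
    orientation = ori, chain_id = seq_along(idx)
  )
}

#' Emit chain alignments for every alignable species pair of a simulation
#'
#' Same-orientation anchors are grouped into plus-strand chains of maximal
#' colinear runs; anchors inverted between the two species are emitted as
#' single-block minus-strand chains with q coordinates on the reverse strand,
#' per the chain convention.
#'
#' @param sim An `ipp_sim`.
#' @return Named list keyed `"A|B"`; each element a list of
#'   `chain_alignment` objects. Pairs with no alignable anchor are omitted.
#' @export
chains_from_sim <- function(sim) {
  out <- list()
  sp <- sim$species
  for (i in seq_along(sp)[-length(sp)]) {
    for (j in (i + 1L):length(sp)) {
      a <- sp[[i]]; b <- sp[[j]]
      an <- sim_pair_anchors(sim, a, b)
      if (!nrow(an)) next
      out[[.pair_key(a, b)]] <- .pair_chains(an, sim$sizes[[a]], sim$sizes[[b]], a, b)
    }
  }
  out
}

.pair_chains <- function(an, size_a, size_b, spa, spb) {
  an <- an[order(an$start_a), , drop = FALSE]
  chains <- list()
  cid <- 0L
  make_plus <- function(rows) {
    cid <<- cid + 1L
    nb <- nrow(rows)
    sizes <- rows$end_a - rows$start_a
    dts <- c(rows$start_a[-1] - rows$end_a[-nb], NA_integer_)
    dqs <- c(rows$start_b[-1] - rows$end_b[-nb], NA_integer_)
    ch <- list(score = 1000,
               ref = list(chrom = rows$chrom_a[[1]], size = size_a, strand = "+",
                          start = rows$start_a[[1]], end = rows$end_a[[nb]]),
               qry = list(chrom = rows$chrom_b[[1]], size = size_b, strand = "+",
                          start = rows$start_b[[1]], end = rows$end_b[[nb]]),
               blocks = data.frame(size = sizes, dt = dts, dq = dqs),
               id = cid, species_a = spa, species_b = spb)
    class(ch) <- "chain_alignment"
    ch
  }
  make_minus <- function(row) {
    cid <<- cid + 1L
    ch <- list(score = 1000,
               ref = list(chrom = row$chrom_a, size = size_a, strand = "+",
                          start = row$start_a, end = row$end_a),
               qry = list(chrom = row$chrom_b, size = size_b, strand = "-",
                          start = size_b - row$end_b, end = size_b - row$start_b),
               blocks = data.frame(size = row$end_a - row$start_a,
                                   dt = NA_integer_, dq = NA_integer_),
               id = cid, species_a = spa, species_b = spb)
    class(ch) <- "chain_alignment"
    ch
  }
  run <- NULL
  flush <- function() {
    if (!is.null(run)) chains[[length(chains) + 1L]] <<- make_plus(run)
    run <<- NULL
  }
  for (k in seq_len(nrow(an))) {
    row <- an[k, , drop = FALSE]
    if (row$orientation == "inverted") {
      flush()
      chains[[length(chains) + 1L]] <- make_minus(row)
      next
    }
    if (is.null(run)) {
      run <- row
    } else {
      nb <- nrow(run)
      if (row$start_a >= run$end_a[[nb]] && row$start_b >= run$end_b[[nb]]) {
        run <- rbind(run, row)
      } else {
        flush()
        run <- row
      }
    }
  }
  flush()
  chains
}

#' Map a simulated position to its true ortholog position
#'
#' Uses the generating piecewise-linear coordinate maps: exact offset inside
#' an anchor (mirrored through inversions), proportional position inside a
#' spacer (the spacer was resampled per species, so the true position is the
#' same fractional offset in the target spacer, rounded half up).
#'
#' @param sim An `ipp_sim`.
#' @param species_from Species `pos` is expressed in.
#' @param pos 0-based position within the simulated chromosome.
#' @param species_to Target species.
#' @return Integer position, or `NA` when the target spacer has length zero
#'   (no ortholog).
#' @export
sim_truth_map <- function(sim, species_from, pos, species_to) {
  st_f <- sim$starts[, species_from]
  en_f <- st_f + sim$anchor_len
  # inversion reorders anchor coordinates; search by coordinate, not slot
  ordf <- order(st_f)
  k <- findInterval(pos, st_f[ordf])
  if (k >= 1L) {
    slot <- ordf[[k]]
    if (pos < en_f[[slot]]) {
      o <- if (sim$inverted[slot, species_from]) {
        en_f[[slot]] - 1L - pos
      } else {
        pos - st_f[[slot]]
      }
      st_t <- sim$starts[slot, species_to]
      return(as.integer(if (sim$inverted[slot, species_to]) {
        st_t + sim$anchor_len - 1L - o
      } else {
        st_t + o
      }))
    }
  }
  # spacer: between ordered anchors k and k+1 (0 = before the first)
  .spacer_pos <- function(species, k_ord) {
    st <- sim$starts[, species]
    ord <- order(st)
    lo <- if (k_ord >= 1L) st[ord[[k_ord]]] + sim$anchor_len else 0L
    hi <- if (k_ord < sim$n_anchors) st[ord[[k_ord + 1L]]] else sim$sizes[[species]]
    c(lo, hi)
  }
  sp_f <- .spacer_pos(species_from, k)
  len_f <- sp_f[[2]] - sp_f[[1]]
  if (len_f <= 0L) return(NA_integer_)
  frac <- (pos - sp_f[[1]]) / len_f
  sp_t <- .spacer_pos(species_to, k)
  len_t <- sp_t[[2]] - sp_t[[1]]
  if (len_t <= 0L) return(NA_integer_)
  as.integer(sp_t[[1]] + min(len_t - 1L, .round_half_up(frac * len_t)))
}

#' Brute-force oracle projection and classification
#'
#' Independent of the indexed projector: nearest anchors are found by linear
#' scan over the simulation's true alignable anchors, and the best bridged
#' path by exhaustive enumeration of all simple species paths up to
#' `max_hops` hops, applying the same documented projection arithmetic
#' (in-block offset, facing-edge interpolation, one-sided extrapolation) and
#' tie rules (fewer hops, then lexicographic species order). Classification
#' applies the DC/IC/NC thresholds.
#'
#' @param sim An `ipp_sim`.
#' @param query_species,pos Query coordinate.
#' @param target_species Target species.
#' @param params An [ipp_params()] object; `min_block_size` also filters the
#'   oracle's anchors.
#' @return List with `class`, `direct_d`, `bridged_distance`, `bridged_pos`,
#'   `path` (`NA`s when absent).
#' @export
oracle_project_point <- function(sim, query_species, pos, target_species,
                                 params = ipp_params()) {
  usable <- sim$anchor_len >= params$min_block_size
  pair_anchors <- function(a, b) {
    if (!usable) return(NULL)
    an <- sim_pair_anchors(sim, a, b)
    if (!nrow(an)) return(NULL)
    an
  }
  # linear-scan single-hop projection, mirroring the documented rules
  hop <- function(a, b, p) {
    an <- pair_anchors(a, b)
    if (is.null(an)) return(NULL)
    swap <- an$species_a[[1]] != a
    s <- if (swap) an$start_b else an$start_a
    e <- if (swap) an$end_b else an$end_a
    os <- if (swap) an$start_a else an$start_b
    oe <- if (swap) an$end_a else an$end_b
    mapv <- function(i, x) {
      if (an$orientation[[i]] == "same") os[[i]] + (x - s[[i]]) else oe[[i]] - 1 - (x - s[[i]])
    }
    inb <- which(s <= p & p < e)
    if (length(inb)) {
      lens <- e[inb] - s[inb]
      i <- inb[order(-lens, s[inb])][[1]]
      return(list(pos = mapv(i, p), d = 0))
    }
    ups <- which(e <= p)
    dns <- which(s > p)
    up <- if (length(ups)) {
      cand <- ups[e[ups] == max(e[ups])]
      cand[order(-(e[cand] - s[cand]), s[cand])][[1]]
    } else NA
    dn <- if (length(dns)) dns[which.min(s[dns])] else NA
    if (is.na(up) && is.na(dn)) return(NULL)
    d <- min(if (!is.na(up)) p - e[[up]] else Inf,
             if (!is.na(dn)) s[[dn]] - p else Inf)
    if (!is.na(up) && !is.na(dn) && an$orientation[[up]] == an$orientation[[dn]]) {
      f <- (p - e[[up]]) / (s[[dn]] - e[[up]])
      tgt <- if (an$orientation[[up]] == "same") {
        .round_half_up(oe[[up]] + f * (os[[dn]] - oe[[up]]))
      } else {
        .round_half_up(os[[up]] - 1 - f * (os[[up]] - oe[[dn]]))
      }
      return(list(pos = tgt, d = d))
    }
    du <- if (!is.na(up)) p - e[[up]] else Inf
    dd <- if (!is.na(dn)) s[[dn]] - p else Inf
    i <- if (du <= dd) up else dn
    list(pos = mapv(i, p), d = d)
  }
  direct <- hop(query_species, target_species, pos)
  # exhaustive simple paths query -> target
  others <- setdiff(sim$species, c(query_species, target_species))
  best <- NULL
  consider <- function(seqs) {
    p <- pos
    dist <- 0
    for (h in seq_len(length(seqs) - 1L)) {
      pr <- hop(seqs[[h]], seqs[[h + 1L]], p)
      if (is.null(pr)) return(NULL)
      dist <- dist + pr$d
      if (dist >= params$ic_threshold) return(NULL)
      p <- pr$pos
    }
    list(dist = dist, pos = p, path = seqs)
  }
  all_seqs <- list(c(query_species, target_species))
  if (length(others)) {
    for (k in seq_len(min(length(others), params$max_hops - 1L))) {
      subsets <- utils::combn(others, k, simplify = FALSE)
      for (sub in subsets) {
        perms <- .permutations(sub)
        for (pm in perms) {
          all_seqs[[length(all_seqs) + 1L]] <- c(query_species, pm, target_species)
        }
      }
    }
  }
  for (seqs in all_seqs) {
    r <- consider(seqs)
    if (is.null(r)) next
    if (is.null(best) ||
        r$dist < best$dist ||
        (r$dist == best$dist && length(r$path) < length(best$path)) ||
        (r$dist == best$dist && length(r$path) == length(best$path) &&
         paste(r$path, collapse = ",") < paste(best$path, collapse = ","))) {
      best <- r
    }
  }
  cls <- if (!is.null(direct) && direct$d <= params$dc_threshold) {
    "DC"
  } else if (!is.null(best)) {
    "IC"
  } else if (!is.null(direct)) {
    "NC"
  } else {
    "UNPROJECTABLE"
  }
  list(class = cls,
       direct_d = if (is.null(direct)) NA_real_ else direct$d,
       bridged_distance = if (is.null(best)) NA_real_ else best$dist,
       bridged_pos = if (is.null(best)) NA_integer_ else as.integer(best$pos),
       path = if (is.null(best)) NA_character_ else paste(best$path, collapse = ">"))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[[i]], rest)
    }
  }
  out
}

#' Ground-truth lookup for a simulated query
#'
#' @param sim An `ipp_sim`.
#' @param query_species,pos Query coordinate.
#' @param target_species Target species.
#' @param params An [ipp_params()] object.
#' @return List with `true_pos` (`NA` when the position falls in a segment
#'   with no ortholog) and `expected_class` from [oracle_project_point()].
#' @export
truth_lookup <- function(sim, query_species, pos, target_species,
                         params = ipp_params()) {
  list(true_pos = sim_truth_map(sim, query_species, pos, target_species),
       expected_class = oracle_project_point(sim, query_species, pos,
                                             target_species, params)$class)
}

#' Sample query positions from a simulated genome
#'
#' @param sim An `ipp_sim`.
#' @param species Species to sample in.
#' @param n Number of queries.
#' @param seed Integer seed.
#' @param width Width of the emitted BED intervals (centered on the sampled
#'   point). Default 500, a typical CRE window.
#' @return BED-like data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`) whose midpoints are the sampled points.
#' @export
simulate_queries <- function(sim, species, n = 500L, seed = 1L, width = 500L) {
  size <- sim$sizes[[species]]
  pts <- .with_seed(seed, sample.int(size - width, n) + width %/% 2L)
  data.frame(chrom = sim$chrom,
             start = pts - width %/% 2L,
             end = pts + (width - width %/% 2L),
             name = sprintf("q%04d", seq_len(n)),
             score = 0, strand = "+")
}

#' The standard simulated fixture
#'
#' Four species on a linear tree (query, two bridges, target; unit branch
#' lengths), 200 anchors of 60 bp, lognormal spacers around 800 bp with wide
#' spread (`sdlog = 1`, so occasional multi-kb anchor deserts), and a
#' divergence threshold `theta = 1.5` under which adjacent pairs usually stay
#' alignable while most query-target anchors lose direct alignment — so DC,
#' IC and NC queries all occur.
#'
#' @param seed Integer seed (default 42).
#' @param n_queries Number of query regions (default 500).
#' @return List with `sim`, `queries` (BED-like data.frame over the query
#'   species), `query_species` (`"mmu"`), `target_species` (`"gga"`).
#' @export
standard_fixture <- function(seed = 42L, n_queries = 500L) {
  tree <- linear_tree(c("mmu", "bri1", "bri2", "gga"), lengths = 1)
  sim <- simulate_multispecies_anchors(tree, n_anchors = 200L, anchor_len = 60L,
                                       spacer_meanlog = log(800),
                                       spacer_sdlog = 1,
                                       theta = 1.5, seed = seed)
  queries <- simulate_queries(sim, "mmu", n = n_queries, seed = seed + 1L)
  list(sim = sim, queries = queries,
       query_species = "mmu", target_species = "gga")
}

#' Simulate paired motif-hit lists with controlled shuffling
#'
#' Each pair carries `n_motifs` distinct motifs placed without overlap in a
#' 500 bp window; list B is list A's motif order after `t` disjoint adjacent
#' transpositions (each contributing exactly one discordant pair), optionally
#' followed by a whole-window orientation flip (order reversal with strand
#' swap). Deterministic given `seed`.
#'
#' @param n_pairs Number of pairs.
#' @param n_motifs Motifs per window (default 6); must fit the window.
#' @param t_transpositions Integer vector of transposition counts, recycled
#'   over pairs; each must satisfy `t <= floor(n_motifs / 2)` so disjoint
#'   adjacent transpositions exist.
#' @param orientation_flip_prob Probability of flipping list B (default 0).
#' @param seed Integer seed.
#' @param window Window width in bp (default 500).
#' @return List of pair records:
#'   `list(pair_id, t, flipped, hits_a, hits_b)` with hit data.frames in
#'   motif-hit layout (`chrom`, `start`, `end`, `motif_id`, `score`,
#'   `strand`).
#' @export
simulate_motif_pairs <- function(n_pairs, n_motifs = 6L, t_transpositions = 0L,
                                 orientation_flip_prob = 0, seed = 1L,
                                 window = 500L) {
  hit_w <- 10L
  slot <- window %/% n_motifs
  if (slot < hit_w + 1L) stop("requested motifs exceed window capacity")
  tt <- rep_len(as.integer(t_transpositions), n_pairs)
  if (any(tt > n_motifs %/% 2L)) {
    stop("t exceeds the maximum number of disjoint adjacent transpositions")
  }
  .with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      motifs <- sprintf("M%02d", sample.int(99L, n_motifs))
      order_a <- motifs
      t <- tt[[i]]
      order_b <- order_a
      if (t > 0L) {
        # rejection-sample t pairwise-disjoint adjacent positions
        repeat {
          pos <- sort(sample.int(n_motifs - 1L, t))
          if (t == 1L || all(diff(pos) >= 2L)) break
        }
        for (p in pos) order_b[c(p, p + 1L)] <- order_b[c(p + 1L, p)]
      }
      flipped <- stats::runif(1) < orientation_flip_prob
      if (flipped) order_b <- rev(order_b)
      place <- function(ord, strand) {
        data.frame(chrom = "window", start = (seq_len(n_motifs) - 1L) * slot,
                   end = (seq_len(n_motifs) - 1L) * slot + hit_w,
                   motif_id = ord,
                   score = round(stats::runif(n_motifs, 5, 10), 3),
                   strand = strand)
      }
      list(pair_id = sprintf("pair%04d", i), t = t, flipped = flipped,
           hits_a = place(order_a, "+"),
           hits_b = place(order_b, if (flipped) "-" else "+"))
    })
  })
}
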