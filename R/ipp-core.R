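#' @title Interspecies point projection
#' @description Projects query coordinates into a target genome either
#'   directly (interpolating against anchor points of the direct species
#'   pair) or through multi-hop paths over bridging species, and classifies
#'   each projection as directly conserved (DC), indirectly conserved (IC) or
#'   nonconserved (NC) by its distance to anchor points.
#' @name ipp-core
NULL

#' Projection parameters
#'
#' @param dc_threshold Maximum query-side distance (bp) to a direct-alignment
#'   anchor for a projection to count as directly conserved; the boundary is
#'   inclusive ("within 300 bp"). Default 300.
#' @param ic_threshold Upper bound (bp) on the summed per-hop anchor distance
#'   of a bridged path for indirect conservation; the boundary is exclusive
#'   ("less than 2.5 kb"). Default 2500.
#' @param max_hops Maximum number of pairwise projections in a bridged path.
#'   Default 4.
#' @param min_block_size Minimum ungapped chain block length (bp) used as an
#'   anchor. Default 10.
#' @return A validated list of class `ipp_params`.
#' @export
ipp_params <- function(dc_threshold = 300, ic_threshold = 2500,
                       max_hops = 4L, min_block_size = 10L) {
  stopifnot(dc_threshold > 0, ic_threshold >= dc_threshold, max_hops >= 1L,
            min_block_size >= 1L)
  structure(list(dc_threshold = dc_threshold, ic_threshold = ic_threshold,
                 max_hops = as.integer(max_hops),
                 min_block_size = as.integer(min_block_size)),
            class = "ipp_params")
}

# round half away from zero, so projections are reproducible across platforms
# (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

# affine map of an anchor row (locate() one-row data.frame), extended beyond
# the block for one-sided extrapolation
.anchor_map <- function(anchor, pos) {
  if (anchor$orientation == "same") {
    anchor$o_start + (pos - anchor$start)
  } else {
    anchor$o_end - 1 - (pos - anchor$start)
  }
}

#' Project a single position through one species pair
#'
#' Maps `pos` to the other species of the pair using the anchors around it:
#' exact offset arithmetic inside an anchor block (`mode = "in_block"`,
#' `d = 0`); linear interpolation between the facing edges of the flanking
#' anchors when both exist with equal orientation (`mode = "interpolated"`);
#' otherwise constant-offset extrapolation from the nearest anchor
#' (`mode = "one_sided"`, equidistant ties resolved toward the upstream
#' anchor). Flanking anchors of opposite orientation fall back to the
#' one-sided rule, since an inversion breakpoint between them makes
#' interpolation meaningless.
#'
#' @param index `anchor_index` for the species pair.
#' @param species Species `pos` is expressed in (either of the pair).
#' @param chrom,pos Query coordinate.
#' @return `NULL` when the chromosome carries no anchors; otherwise a list
#'   with `source` (`species`, `chrom`, `pos`), `target` (`species`, `chrom`,
#'   `pos`), `d` (bp to the nearest source-side anchor) and `mode`.
#' @export
project_pairwise <- function(index, species, chrom, pos) {
  nb <- locate(index, species, chrom, pos)
  if (is.null(nb$containing) && is.null(nb$upstream) && is.null(nb$downstream)) {
    return(NULL)
  }
  other <- setdiff(index$species, species)
  if (!is.null(nb$containing)) {
    a <- nb$containing
    tgt <- .anchor_map(a, pos)
    mode <- "in_block"
  } else if (!is.null(nb$upstream) && !is.null(nb$downstream) &&
             nb$upstream$orientation == nb$downstream$orientation) {
    up <- nb$upstream; dn <- nb$downstream
    f <- (pos - up$end) / (dn$start - up$end)
    if (up$orientation == "same") {
      tgt <- .round_half_up(up$o_end + f * (dn$o_start - up$o_end))
    } else {
      tgt <- .round_half_up(up$o_start - 1 - f * (up$o_start - dn$o_end))
    }
    a <- up
    mode <- "interpolated"
  } else {
    du <- if (!is.null(nb$upstream)) pos - nb$upstream$end else Inf
    dd <- if (!is.null(nb$downstream)) nb$downstream$start - pos else Inf
    a <- if (du <= dd) nb$upstream else nb$downstream
    tgt <- .anchor_map(a, pos)
    mode <- "one_sided"
  }
  list(source = list(species = species, chrom = chrom, pos = pos),
       target = list(species = other, chrom = a$o_chrom, pos = as.integer(tgt)),
       d = nb$d, mode = mode)
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

# species adjacency from the names of the index list
.species_graph <- function(indexes) {
  if (!length(indexes)) return(list())
  pairs <- strsplit(names(indexes), "|", fixed = TRUE)
  species <- unique(unlist(pairs))
  adj <- stats::setNames(vector("list", length(species)), species)
  for (p in pairs) {
    adj[[p[[1]]]] <- sort(unique(c(adj[[p[[1]]]], p[[2]])))
    adj[[p[[2]]]] <- sort(unique(c(adj[[p[[2]]]], p[[1]])))
  }
  adj
}

#' Best bridged projection path between two species
#'
#' Uniform-cost search over (species, chromosome, position) states: from the
#' query position, every species pair with an index is a candidate hop, each
#' hop costing its source-side anchor distance `d`. Partial paths are pruned
#' once their cumulative distance reaches `ic_threshold` or their hop count
#' exceeds `max_hops`; no species is visited twice. Among equal-cost complete
#' paths, fewer hops win, then lexicographic species order. The single-hop
#' direct route competes like any other path.
#'
#' @param query_species,chrom,pos Query coordinate.
#' @param target_species Destination species.
#' @param indexes Named list of `anchor_index` objects keyed
#'   `"<speciesA>|<speciesB>"` with the two names sorted.
#' @param params An [ipp_params()] object.
#' @return `NULL` if the target is unreachable under pruning; otherwise a
#'   list with `species_sequence`, `per_hop` (list of [project_pairwise()]
#'   results), `total_distance` and `final` (`chrom`, `pos`).
#' @export
best_bridged_path <- function(query_species, chrom, pos, target_species,
                              indexes, params = ipp_params()) {
  stopifnot(inherits(params, "ipp_params"))
  adj <- .species_graph(indexes)
  if (!query_species %in% names(adj) || !target_species %in% names(adj)) {
    return(NULL)
  }
  frontier <- list(list(species = query_species, chrom = chrom, pos = pos,
                        dist = 0, path = query_species, per_hop = list()))
  keys <- data.frame(dist = 0, hops = 0L, lex = query_species)
  while (length(frontier)) {
    ord <- order(keys$dist, keys$hops, keys$lex)[[1]]
    st <- frontier[[ord]]
    frontier <- frontier[-ord]
    keys <- keys[-ord, , drop = FALSE]
    if (st$species == target_species && length(st$per_hop) > 0L) {
      return(list(species_sequence = st$path,
                  per_hop = st$per_hop,
                  total_distance = st$dist,
                  final = list(chrom = st$chrom, pos = st$pos)))
    }
    if (length(st$per_hop) >= params$max_hops) next
    for (nxt in adj[[st$species]]) {
      if (nxt %in% st$path) next
      idx <- indexes[[.pair_key(st$species, nxt)]]
      if (is.null(idx)) next
      proj <- project_pairwise(idx, st$species, st$chrom, st$pos)
      if (is.null(proj)) next
      ndist <- st$dist + proj$d
      if (ndist >= params$ic_threshold) next
      frontier[[length(frontier) + 1L]] <-
        list(species = nxt, chrom = proj$target$chrom, pos = proj$target$pos,
             dist = ndist, path = c(st$path, nxt),
             per_hop = c(st$per_hop, list(proj)))
      keys <- rbind(keys, data.frame(dist = ndist,
                                     hops = length(st$per_hop) + 1L,
                                     lex = paste(c(st$path, nxt), collapse = ",")))
    }
  }
  NULL
}

#' Classify a projection as DC, IC, NC or UNPROJECTABLE
#'
#' DC: a direct projection exists within `dc_threshold` bp of a direct
#' alignment (boundary inclusive). IC: not DC, and a bridged path exists with
#' summed anchor distance strictly below `ic_threshold`. NC: some projection
#' exists but neither rule fires. UNPROJECTABLE: no projection at all.
#'
#' @param direct A [project_pairwise()] result for the direct pair, or `NULL`.
#' @param bridged A [best_bridged_path()] result, or `NULL`.
#' @param params An [ipp_params()] object.
#' @return One of `"DC"`, `"IC"`, `"NC"`, `"UNPROJECTABLE"`.
#' @export
classify <- function(direct, bridged, params = ipp_params()) {
  if (!is.null(direct) && direct$d <= params$dc_threshold) return("DC")
  if (!is.null(bridged) && bridged$total_distance < params$ic_threshold) return("IC")
  if (!is.null(direct) || !is.null(bridged)) return("NC")
  "UNPROJECTABLE"
}

#' Project one query point and classify it
#'
#' @inheritParams best_bridged_path
#' @return List with `direct`, `bridged`, `class`.
#' @export
project_point <- function(query_species, chrom, pos, target_species,
                          indexes, params = ipp_params()) {
  dk <- .pair_key(query_species, target_species)
  direct <- if (!is.null(indexes[[dk]])) {
    project_pairwise(indexes[[dk]], query_species, chrom, pos)
  } else NULL
  bridged <- best_bridged_path(query_species, chrom, pos, target_species,
                               indexes, params)
  list(direct = direct, bridged = bridged,
       class = classify(direct, bridged, params))
}

#' Project a table of query regions to a target genome
#'
#' Each region is projected as a point: its summit when the BED-like input
#' carries a `summit` column (offset from `start`), otherwise its midpoint.
#' Regions on chromosomes without anchors come back `UNPROJECTABLE`, never as
#' an error.
#'
#' @param bed Data.frame of query regions (`chrom`, `start`, `end`, optional
#'   `name`, optional `summit`).
#' @param query_species,target_species Species identifiers.
#' @inheritParams best_bridged_path
#' @param quiet Suppress the per-class summary message.
#' @return Data.frame with one row per region: `qchrom`, `qstart`, `qend`,
#'   `qname`, `point`, `tchrom_direct`, `tpos_direct`, `d_direct`,
#'   `tchrom_bridged`, `tpos_bridged`, `d_bridged_sum`, `path`, `class`.
#' @export
project_regions <- function(bed, query_species, target_species, indexes,
                            params = ipp_params(), quiet = FALSE) {
  n <- nrow(bed)
  out <- data.frame(
    qchrom = character(n), qstart = integer(n), qend = integer(n),
    qname = character(n), point = integer(n),
    tchrom_direct = rep(NA_character_, n), tpos_direct = rep(NA_integer_, n),
    d_direct = rep(NA_real_, n),
    tchrom_bridged = rep(NA_character_, n), tpos_bridged = rep(NA_integer_, n),
    d_bridged_sum = rep(NA_real_, n), path = rep(NA_character_, n),
    class = character(n)
  )
  if (n == 0L) {
    if (!quiet) message("projected 0 regions")
    return(out)
  }
  for (i in seq_len(n)) {
    point <- if (!is.null(bed$summit) && !is.na(bed$summit[[i]])) {
      bed$start[[i]] + bed$summit[[i]]
    } else {
      (bed$start[[i]] + bed$end[[i]]) %/% 2L
    }
    res <- project_point(query_species, bed$chrom[[i]], point,
                         target_species, indexes, params)
    out$qchrom[[i]] <- bed$chrom[[i]]
    out$qstart[[i]] <- bed$start[[i]]
    out$qend[[i]] <- bed$end[[i]]
    out$qname[[i]] <- if (!is.null(bed$name) && !is.na(bed$name[[i]]))
      bed$name[[i]] else sprintf("region_%d", i)
    out$point[[i]] <- point
    if (!is.null(res$direct)) {
      out$tchrom_direct[[i]] <- res$direct$target$chrom
      out$tpos_direct[[i]] <- res$direct$target$pos
      out$d_direct[[i]] <- res$direct$d
    }
    if (!is.null(res$bridged)) {
      out$tchrom_bridged[[i]] <- res$bridged$final$chrom
      out$tpos_bridged[[i]] <- res$bridged$final$pos
      out$d_bridged_sum[[i]] <- res$bridged$total_distance
      out$path[[i]] <- paste(res$bridged$species_sequence, collapse = ">")
    }
    out$class[[i]] <- res$class
  }
  if (!quiet) {
    counts <- table(factor(out$class, levels = c("DC", "IC", "NC", "UNPROJECTABLE")))
    message(sprintf("projected %d regions: DC=%d IC=%d NC=%d UNPROJECTABLE=%d",
                    n, counts[["DC"]], counts[["IC"]], counts[["NC"]],
                    counts[["UNPROJECTABLE"]]))
  }
  out
}

#' Build anchor indexes from per-pair chain lists
#'
#' @param chains_by_pair Named list keyed `"A|B"` (sorted species names), each
#'   element a list of `chain_alignment` objects read with species attached.
#' @param min_block_size Minimum anchor block length in bp.
#' @return Named list of `anchor_index` objects with the same keys.
#' @export
build_pair_indexes <- function(chains_by_pair, min_block_size = 10L) {
  stats::setNames(
    lapply(chains_by_pair, function(chs) {
      build_index(anchors_from_chains(chs, min_block_size = min_block_size))
    }),
    names(chains_by_pair)
  )
}
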