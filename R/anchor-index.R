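#' @title Anchor index: fast containing/flanking-anchor queries
#' @description Sorted per-chromosome lookup structures over anchor blocks for
#'   one species pair, supporting queries from either species of the pair.
#' @name anchor-index
NULL

#' Build an anchor index for one species pair
#'
#' Indexes anchor blocks (as produced by [anchors_from_chains()]) by
#' chromosome and start coordinate on both sides of the pair, so that
#' [locate()] can answer containing/flanking queries from either species in
#' O(log n).
#'
#' @param anchors Anchor data.frame with columns `species_a`, `chrom_a`,
#'   `start_a`, `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`,
#'   `orientation`, `chain_id`. All rows must share one species pair.
#' @return An `anchor_index` object; `length()` gives the anchor count.
#' @export
build_index <- function(anchors) {
  req <- c("species_a", "chrom_a", "start_a", "end_a",
           "species_b", "chrom_b", "start_b", "end_b", "orientation")
  stopifnot(all(req %in% names(anchors)))
  if (nrow(anchors)) {
    if (length(unique(anchors$species_a)) > 1L ||
        length(unique(anchors$species_b)) > 1L) {
      stop("anchors mix species pairs; build one index per pair")
    }
    bad <- anchors$start_a >= anchors$end_a | anchors$start_b >= anchors$end_b
    if (any(bad)) stop("invalid anchor interval(s) at row ", which(bad)[1])
    sp <- c(anchors$species_a[[1]], anchors$species_b[[1]])
  } else {
    sp <- c(NA_character_, NA_character_)
  }
  idx <- list(
    species = sp,
    n = nrow(anchors),
    forward = .index_side(anchors, side = "a"),
    reverse = .index_side(anchors, side = "b")
  )
  class(idx) <- "anchor_index"
  idx
}

# One direction: anchors keyed by `side` coordinates, per chromosome, sorted
# by start. Each chromosome entry keeps parallel vectors plus a running max
# of ends (for containing lookups over overlapping blocks) and an
# end-sorted permutation (for upstream lookups).
.index_side <- function(anchors, side) {
  if (!nrow(anchors)) return(list())
  this <- if (side == "a") "a" else "b"
  other <- if (side == "a") "b" else "a"
  df <- data.frame(
    chrom = anchors[[paste0("chrom_", this)]],
    start = anchors[[paste0("start_", this)]],
    end = anchors[[paste0("end_", this)]],
    o_chrom = anchors[[paste0("chrom_", other)]],
    o_start = anchors[[paste0("start_", other)]],
    o_end = anchors[[paste0("end_", other)]],
    orientation = anchors$orientation
  )
  split_df <- split(df, df$chrom)
  lapply(split_df, function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    rownames(d) <- NULL
    list(df = d,
         cummax_end = cummax(d$end),
         # ties on end sort the preferred anchor (larger block, lower start)
         # last, so findInterval's last-index-<=-pos picks it
         by_end = order(d$end, d$end - d$start, -d$start))
  })
}

#' @export
length.anchor_index <- function(x) x$n

#' @export
print.anchor_index <- function(x, ...) {
  cat(sprintf("<anchor_index %s <-> %s: %d anchor(s) on %d/%d chromosome(s)>\n",
              x$species[1], x$species[2], x$n,
              length(x$forward), length(x$reverse)))
  invisible(x)
}

#' Locate the anchors around a position
#'
#' Finds the containing anchor (if any), the nearest upstream anchor (ending
#' at or before `pos`) and the nearest downstream anchor (starting after
#' `pos`), plus the distance `d` to the nearest anchor point. Distances are
#' measured to the half-open block edges on the query side:
#' `d = min(pos - upstream$end, downstream$start - pos)`, and `d = 0` inside a
#' block. When several anchors contain `pos`, the largest block wins, then the
#' lower start. Equidistant up/downstream ties break toward the upstream
#' anchor when a single nearest anchor is required.
#'
#' @param index An `anchor_index`.
#' @param species Which species of the pair `pos` is expressed in.
#' @param chrom Chromosome name.
#' @param pos 0-based position.
#' @return A list with `containing`, `upstream`, `downstream` (each a one-row
#'   data.frame with `start`, `end`, `o_chrom`, `o_start`, `o_end`,
#'   `orientation`, or `NULL`) and `d` (bp, `NA` when no anchor exists on the
#'   chromosome).
#' @export
locate <- function(index, species, chrom, pos) {
  side <- .which_side(index, species)
  chroms <- if (side == "forward") index$forward else index$reverse
  entry <- chroms[[chrom]]
  empty <- list(containing = NULL, upstream = NULL, downstream = NULL, d = NA_real_)
  if (is.null(entry)) return(empty)
  d <- entry$df
  n <- nrow(d)

  # containing: among starts <= pos, any end > pos; prefer larger block
  k <- findInterval(pos, d$start)
  containing <- NULL
  if (k >= 1L && entry$cummax_end[[k]] > pos) {
    best <- -1L
    best_len <- -1L
    i <- k
    while (i >= 1L && entry$cummax_end[[i]] > pos) {
      if (d$end[[i]] > pos) {
        len <- d$end[[i]] - d$start[[i]]
        if (len > best_len || (len == best_len && d$start[[i]] < d$start[[best]])) {
          best <- i; best_len <- len
        }
      }
      i <- i - 1L
    }
    if (best >= 1L) containing <- d[best, , drop = FALSE]
  }

  # upstream: maximal end among ends <= pos
  ends_sorted <- d$end[entry$by_end]
  ku <- findInterval(pos, ends_sorted)
  upstream <- if (ku >= 1L) d[entry$by_end[[ku]], , drop = FALSE] else NULL

  # downstream: minimal start among starts > pos
  kd <- findInterval(pos, d$start, left.open = TRUE) + 1L
  downstream <- if (kd <= n) d[kd, , drop = FALSE] else NULL

  dist <- if (!is.null(containing)) {
    0
  } else {
    du <- if (!is.null(upstream)) pos - upstream$end else Inf
    dd <- if (!is.null(downstream)) downstream$start - pos else Inf
    min(du, dd)
  }
  list(containing = containing, upstream = upstream, downstream = downstream,
       d = as.numeric(dist))
}

.which_side <- function(index, species) {
  if (index$n == 0L) return("forward")
  if (identical(species, index$species[[1]])) return("forward")
  if (identical(species, index$species[[2]])) return("reverse")
  stop(sprintf("species '%s' is not part of the indexed pair (%s, %s)",
               species, index$species[[1]], index$species[[2]]))
}

#' Serialize an anchor index to TSV
#'
#' Writes the indexed anchors as a tab-separated table with columns
#' `species_a, chrom_a, start_a, end_a, species_b, chrom_b, start_b, end_b,
#' orientation`.
#'
#' @param index An `anchor_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(index, path) {
  rows <- list()
  for (chrom in names(index$forward)) {
    d <- index$forward[[chrom]]$df
    rows[[chrom]] <- data.frame(
      species_a = index$species[[1]], chrom_a = chrom,
      start_a = d$start, end_a = d$end,
      species_b = index$species[[2]], chrom_b = d$o_chrom,
      start_b = d$o_start, end_b = d$o_end,
      orientation = d$orientation
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_a = character(0), chrom_a = character(0),
               start_a = integer(0), end_a = integer(0),
               species_b = character(0), chrom_b = character(0),
               start_b = integer(0), end_b = integer(0),
               orientation = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
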