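#' @title Functional-activity labelling of projections
#' @description Labels projected positions as functionally conserved (+) or
#'   not (-) by overlap with target-genome activity peaks (ATAC/ChIP), and
#'   summarizes +/- fractions per conservation class. Also draws same-TAD
#'   background (nonortholog) peaks for control comparisons.
#' @name activity-overlap
NULL

#' Label projections by overlap with activity peaks
#'
#' A projection is `plus` when the projected point, widened by `window` bp on
#' each side, intersects at least one peak; the peak with the largest overlap
#' is recorded. The bridged target coordinate is used when available,
#' otherwise the direct one. `UNPROJECTABLE` rows are labelled `minus` with
#' `unprojectable = TRUE` so they can be counted separately.
#'
#' @param projections Output of [project_regions()].
#' @param peaks Data.frame of peaks (`chrom`, `start`, `end`, 0-based
#'   half-open) in the target genome.
#' @param window Non-negative bp added on each side of the projected point
#'   before intersection (default 0: the point itself must fall in a peak).
#' @return Data.frame with one row per projection: `qname`, `class`, `label`
#'   (`"plus"`/`"minus"`), `peak_chrom`, `peak_start`, `peak_end`,
#'   `unprojectable`.
#' @export
label_projection_activity <- function(projections, peaks, window = 0L) {
  stopifnot(window >= 0L)
  n <- nrow(projections)
  out <- data.frame(
    qname = projections$qname, class = projections$class,
    label = rep("minus", n),
    peak_chrom = NA_character_, peak_start = NA_integer_, peak_end = NA_integer_,
    unprojectable = projections$class == "UNPROJECTABLE"
  )
  if (n == 0L || nrow(peaks) == 0L) return(out)
  for (i in seq_len(n)) {
    if (out$unprojectable[[i]]) next
    use_bridged <- !is.na(projections$tpos_bridged[[i]])
    tchrom <- if (use_bridged) projections$tchrom_bridged[[i]] else projections$tchrom_direct[[i]]
    tpos <- if (use_bridged) projections$tpos_bridged[[i]] else projections$tpos_direct[[i]]
    if (is.na(tpos)) next
    qs <- tpos - window
    qe <- tpos + window + 1L  # half-open query interval around the point
    on_chrom <- peaks$chrom == tchrom
    ov <- pmin(peaks$end[on_chrom], qe) - pmax(peaks$start[on_chrom], qs)
    hit <- which(ov > 0)
    if (length(hit)) {
      best <- hit[[which.max(ov[hit])]]
      p <- which(on_chrom)[[best]]
      out$label[[i]] <- "plus"
      out$peak_chrom[[i]] <- peaks$chrom[[p]]
      out$peak_start[[i]] <- peaks$start[[p]]
      out$peak_end[[i]] <- peaks$end[[p]]
    }
  }
  out
}

#' Summarize +/- fractions per conservation class
#'
#' @param labels Output of [label_projection_activity()] (columns `class`,
#'   `label`).
#' @return Data.frame with one row per class (`DC`, `IC`, `NC`,
#'   `UNPROJECTABLE`): `class`, `n`, `n_plus`, `fraction_plus` (0 for an
#'   empty class). Counts over all rows sum to the input size.
#' @export
summarize_class_fractions <- function(labels) {
  classes <- c("DC", "IC", "NC", "UNPROJECTABLE")
  cls <- factor(labels$class, levels = classes)
  n <- as.integer(table(cls))
  n_plus <- as.integer(table(cls[labels$label == "plus"]))
  data.frame(
    class = classes,
    n = n,
    n_plus = n_plus,
    fraction_plus = ifelse(n > 0, n_plus / n, 0)
  )
}

#' Sample a background (nonortholog) peak, preferring the same TAD
#'
#' Draws one peak uniformly at random from the candidate peaks in the same
#' TAD as the query's ortholog peak, excluding the ortholog peak itself; when
#' the TAD holds no other peak (or no TADs are given), the draw falls back to
#' the whole genome with `same_tad = FALSE`. Deterministic for a given seed.
#'
#' @param ortholog_peak One-row data.frame (`chrom`, `start`, `end`): the true
#'   ortholog peak to exclude.
#' @param peaks Data.frame of candidate peaks.
#' @param tads Optional data.frame of TAD intervals (`chrom`, `start`, `end`).
#' @param rng_seed Integer seed; the caller's RNG state is left untouched.
#' @return List with `peak` (one-row data.frame) and `same_tad` (logical).
#' @export
sample_background_peak <- function(ortholog_peak, peaks, tads = NULL,
                                   rng_seed = 1L) {
  is_orth <- peaks$chrom == ortholog_peak$chrom &
    peaks$start == ortholog_peak$start & peaks$end == ortholog_peak$end
  candidates <- peaks[!is_orth, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    stop("no background peak available: the ortholog peak is the only peak")
  }
  same_tad <- FALSE
  pool <- candidates
  if (!is.null(tads) && nrow(tads)) {
    mid <- (ortholog_peak$start + ortholog_peak$end) %/% 2L
    in_tad <- tads$chrom == ortholog_peak$chrom &
      tads$start <= mid & tads$end > mid
    if (any(in_tad)) {
      tad <- tads[which(in_tad)[1], , drop = FALSE]
      pmid <- (candidates$start + candidates$end) %/% 2L
      hit <- candidates$chrom == tad$chrom &
        pmid >= tad$start & pmid < tad$end
      if (any(hit)) {
        pool <- candidates[hit, , drop = FALSE]
        same_tad <- TRUE
      }
    }
  }
  pick <- .with_seed(rng_seed, sample.int(nrow(pool), 1L))
  list(peak = pool[pick, , drop = FALSE], same_tad = same_tad)
}

# run expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
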