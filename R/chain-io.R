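#' @title UCSC chain and BED input/output
#' @description Faithful readers and writers for the UCSC pairwise alignment
#'   chain format and BED3/BED6 interval files, plus decomposition of chains
#'   into ungapped anchor blocks. All coordinates are 0-based half-open
#'   internally; chain minus-strand q coordinates are kept as written at parse
#'   time and converted to forward-strand coordinates only when anchor blocks
#'   are extracted.
#' @name chain-io
NULL

#' Read a UCSC chain file
#'
#' Parses a pairwise whole-genome alignment chain file into a list of chain
#' alignments. Each chain is a header
#' \code{chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id}
#' followed by ungapped block lines \code{size [dt dq]}; the last block line
#' carries only \code{size}. Minus-strand q coordinates are retained exactly as
#' written (on the reverse strand); conversion to forward coordinates happens
#' in [extract_anchor_blocks()].
#'
#' @param path Path to a chain file.
#' @param species_a,species_b Species identifiers for the reference (t) and
#'   query (q) genomes of the file; attached to each alignment.
#' @return A list of `chain_alignment` objects, each a list with elements
#'   `score`, `ref` and `qry` (each `list(chrom, size, strand, start, end)`),
#'   `blocks` (data.frame with columns `size`, `dt`, `dq`; `dt`/`dq` are `NA`
#'   on the final block), `id`, `species_a`, `species_b`.
#' @seealso [write_chain()], [extract_anchor_blocks()]
#' @export
read_chain <- function(path, species_a = "ref", species_b = "qry") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) {
      i <- i + 1L
      next
    }
    f <- strsplit(line, "[ \t]+")[[1]]
    if (f[[1]] != "chain" || length(f) != 13L) {
      stop(sprintf("malformed chain header at line %d: '%s'", i, lines[[i]]))
    }
    num <- suppressWarnings(as.numeric(f[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(num)) {
      stop(sprintf("non-numeric field in chain header at line %d", i))
    }
    hdr <- list(
      score = as.numeric(f[[2]]),
      ref = list(chrom = f[[3]], size = as.integer(f[[4]]), strand = f[[5]],
                 start = as.integer(f[[6]]), end = as.integer(f[[7]])),
      qry = list(chrom = f[[8]], size = as.integer(f[[9]]), strand = f[[10]],
                 start = as.integer(f[[11]]), end = as.integer(f[[12]])),
      id = as.integer(f[[13]])
    )
    if (!hdr$ref$strand %in% c("+", "-") || !hdr$qry$strand %in% c("+", "-")) {
      stop(sprintf("invalid strand in chain header at line %d", i))
    }
    i <- i + 1L
    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    repeat {
      if (i > n) stop(sprintf("chain %d truncated: no terminal block line", hdr$id))
      bl <- trimws(lines[[i]])
      i <- i + 1L
      if (!nzchar(bl)) next
      bf <- suppressWarnings(as.integer(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(bf) || !length(bf) %in% c(1L, 3L)) {
        stop(sprintf("malformed block line at line %d", i - 1L))
      }
      if (length(bf) == 3L) {
        sizes <- c(sizes, bf[[1]]); dts <- c(dts, bf[[2]]); dqs <- c(dqs, bf[[3]])
      } else {
        sizes <- c(sizes, bf[[1]]); dts <- c(dts, NA_integer_); dqs <- c(dqs, NA_integer_)
        break
      }
    }
    if (any(sizes <= 0L)) stop(sprintf("chain %d has a non-positive block size", hdr$id))
    ref_span <- sum(sizes) + sum(dts, na.rm = TRUE)
    qry_span <- sum(sizes) + sum(dqs, na.rm = TRUE)
    if (ref_span != hdr$ref$end - hdr$ref$start) {
      stop(sprintf("chain %d: block sums (%d) inconsistent with ref span (%d)",
                   hdr$id, ref_span, hdr$ref$end - hdr$ref$start))
    }
    if (qry_span != hdr$qry$end - hdr$qry$start) {
      stop(sprintf("chain %d: block sums (%d) inconsistent with qry span (%d)",
                   hdr$id, qry_span, hdr$qry$end - hdr$qry$start))
    }
    ch <- c(hdr["score"], hdr["ref"], hdr["qry"],
            list(blocks = data.frame(size = sizes, dt = dts, dq = dqs)),
            hdr["id"],
            list(species_a = species_a, species_b = species_b))
    class(ch) <- "chain_alignment"
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Write chain alignments to a UCSC chain file
#'
#' Inverse of [read_chain()]: `read_chain(write_chain(x, p))` reproduces `x`
#' field-for-field. Alignments are validated against the chain invariants
#' (block sums must reconstruct both spans) before anything is written.
#'
#' @param alignments A list of `chain_alignment` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(alignments, path) {
  out <- character(0)
  for (ch in alignments) {
    b <- ch$blocks
    if (any(b$size <= 0L)) stop(sprintf("chain %d: non-positive block size", ch$id))
    if (!is.na(b$dt[nrow(b)]) || !is.na(b$dq[nrow(b)])) {
      stop(sprintf("chain %d: final block must have no dt/dq", ch$id))
    }
    if (sum(b$size) + sum(b$dt, na.rm = TRUE) != ch$ref$end - ch$ref$start ||
        sum(b$size) + sum(b$dq, na.rm = TRUE) != ch$qry$end - ch$qry$start) {
      stop(sprintf("chain %d: blocks inconsistent with header spans; refusing to write", ch$id))
    }
    hdr <- sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %d",
                   format(ch$score, scientific = FALSE, trim = TRUE),
                   ch$ref$chrom, ch$ref$size, ch$ref$strand, ch$ref$start, ch$ref$end,
                   ch$qry$chrom, ch$qry$size, ch$qry$strand, ch$qry$start, ch$qry$end,
                   ch$id)
    body <- ifelse(is.na(b$dt),
                   as.character(b$size),
                   sprintf("%d %d %d", b$size, b$dt, b$dq))
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' Reads tab-separated BED intervals (0-based half-open). Track, browser and
#' `#` comment lines are skipped. Columns beyond the third populate `name`,
#' `score` and `strand` when present.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (the last three `NA`/`"+"`-defaulted when absent).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), strand = character(0)))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (any(ncols < 3L)) {
    stop(sprintf("BED row with fewer than 3 columns at data line %d", which(ncols < 3L)[1]))
  }
  grab <- function(k, default = NA_character_) {
    vapply(rows, function(r) if (length(r) >= k) r[[k]] else default, character(1))
  }
  start <- suppressWarnings(as.integer(grab(2)))
  end <- suppressWarnings(as.integer(grab(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("non-integer BED coordinates at data line %d", bad))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("BED row with start >= end at data line %d", bad))
  }
  strand <- grab(6, "+")
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(
    chrom = grab(1),
    start = start,
    end = end,
    name = grab(4),
    score = suppressWarnings(as.numeric(grab(5))),
    strand = strand
  )
}

#' Write intervals to a BED file
#'
#' @param bed Data.frame with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` written when present.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path, header = NULL) {
  cols <- list(bed$chrom, bed$start, bed$end)
  if (!is.null(bed$name)) {
    cols <- c(cols, list(ifelse(is.na(bed$name), ".", bed$name),
                         ifelse(is.na(bed$score), 0, bed$score),
                         bed$strand))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Decompose a chain into ungapped anchor blocks
#'
#' Walks the chain's (size, dt, dq) triples and emits one anchor block per
#' ungapped block of at least `min_block_size` bp. Minus-strand q blocks are
#' converted to forward genome coordinates (`pos_fwd = qSize - pos_rev`) and
#' flagged `orientation = "inverted"`. Blocks are sorted by their a-side start.
#'
#' @param chain A `chain_alignment` from [read_chain()].
#' @param min_block_size Minimum ungapped block length in bp to keep
#'   (default 10); smaller blocks are treated as alignment noise.
#' @return A data.frame of anchors with columns `species_a`, `chrom_a`,
#'   `start_a`, `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`,
#'   `orientation` (`"same"`/`"inverted"`), `chain_id`. Both interval pairs
#'   are equal length and in forward coordinates.
#' @export
extract_anchor_blocks <- function(chain, min_block_size = 10L) {
  b <- chain$blocks
  tpos <- chain$ref$start
  qpos <- chain$qry$start
  qsize <- chain$qry$size
  minus <- chain$qry$strand == "-"
  n <- nrow(b)
  start_a <- end_a <- start_b <- end_b <- integer(n)
  for (k in seq_len(n)) {
    sz <- b$size[[k]]
    start_a[[k]] <- tpos
    end_a[[k]] <- tpos + sz
    if (minus) {
      # chain q coords run along the reverse strand; mirror to forward
      start_b[[k]] <- qsize - (qpos + sz)
      end_b[[k]] <- qsize - qpos
    } else {
      start_b[[k]] <- qpos
      end_b[[k]] <- qpos + sz
    }
    if (k < n) {
      tpos <- tpos + sz + b$dt[[k]]
      qpos <- qpos + sz + b$dq[[k]]
    }
  }
  keep <- (end_a - start_a) >= min_block_size
  out <- data.frame(
    species_a = chain$species_a,
    chrom_a = chain$ref$chrom,
    start_a = start_a[keep],
    end_a = end_a[keep],
    species_b = chain$species_b,
    chrom_b = chain$qry$chrom,
    start_b = start_b[keep],
    end_b = end_b[keep],
    orientation = if (minus) "inverted" else "same",
    chain_id = chain$id
  )
  out[order(out$start_a), , drop = FALSE]
}

#' Extract anchor blocks from every chain in a list
#'
#' @param chains List of `chain_alignment` objects (one species pair).
#' @inheritParams extract_anchor_blocks
#' @return Row-bound anchor data.frame, sorted by `chrom_a`, `start_a`.
#' @export
anchors_from_chains <- function(chains, min_block_size = 10L) {
  if (!length(chains)) {
    return(extract_anchor_blocks(.empty_chain(), min_block_size)[0, ])
  }
  out <- do.call(rbind, lapply(chains, extract_anchor_blocks,
                               min_block_size = min_block_size))
  out[order(out$chrom_a, out$start_a), , drop = FALSE]
}

.empty_chain <- function() {
  ch <- list(score = 0, ref = list(chrom = "chr", size = 1L, strand = "+",
                                   start = 0L, end = 1L),
             qry = list(chrom = "chr", size = 1L, strand = "+",
                        start = 0L, end = 1L),
             blocks = data.frame(size = 1L, dt = NA_integer_, dq = NA_integer_),
             id = 0L, species_a = "a", species_b = "b")
  class(ch) <- "chain_alignment"
  ch
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf("<chain %d> score %s  %s:%d-%d (%s) <-> %s:%d-%d (%s), %d block(s)\n",
              x$id, format(x$score), x$ref$chrom, x$ref$start, x$ref$end,
              x$species_a, x$qry$chrom, x$qry$start, x$qry$end, x$species_b,
              nrow(x$blocks)))
  invisible(x)
}
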