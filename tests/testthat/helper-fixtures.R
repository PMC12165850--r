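# shared in-code fixtures for the test suite

# anchor data.frame in the package's column layout
make_anchors <- function(start_a, end_a, start_b, end_b,
                         orientation = "same", chrom_a = "chrA",
                         chrom_b = "chrB", species_a = "A", species_b = "B") {
  n <- length(start_a)
  data.frame(
    species_a = rep_len(species_a, n), chrom_a = rep_len(chrom_a, n),
    start_a = as.integer(start_a), end_a = as.integer(end_a),
    species_b = rep_len(species_b, n), chrom_b = rep_len(chrom_b, n),
    start_b = as.integer(start_b), end_b = as.integer(end_b),
    orientation = rep_len(orientation, n),
    chain_id = seq_len(n)
  )
}

# write chain text to a temp file and return the path
write_chain_text <- function(lines) {
  path <- tempfile(fileext = ".chain")
  writeLines(lines, path)
  path
}

# single-anchor index helper: A:1000-1100 <-> B:2000-2100
toy_index <- function(orientation = "same") {
  build_index(make_anchors(1000, 1100, 2000, 2100, orientation))
}

# motif hit data.frame helper
make_hits <- function(start, end, motif_id, score, strand = "+") {
  data.frame(chrom = "window", start = as.integer(start),
             end = as.integer(end), motif_id = motif_id,
             score = score, strand = rep_len(strand, length(start)))
}

# evenly spaced non-overlapping hits realizing a given 5'-3' motif order
hits_in_order <- function(motifs, score = 7) {
  n <- length(motifs)
  make_hits((seq_len(n) - 1L) * 50L, (seq_len(n) - 1L) * 50L + 10L,
            motifs, rep_len(score, n))
}

# brute-force normalized Kendall distance between two permutations
brute_kendall <- function(a, b) {
  n <- length(a)
  disc <- 0L
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      # order of pair (a[i], a[j]) in b
      pi <- which(b == a[[i]]); pj <- which(b == a[[j]])
      if (pi > pj) disc <- disc + 1L
    }
  }
  disc / (n * (n - 1L) / 2)
}

# linear-scan locate oracle over an anchor data.frame (a-side)
scan_locate <- function(anchors, chrom, pos) {
  d <- anchors[anchors$chrom_a == chrom, , drop = FALSE]
  if (!nrow(d)) return(list(containing = FALSE, d = NA_real_))
  inside <- d$start_a <= pos & pos < d$end_a
  if (any(inside)) return(list(containing = TRUE, d = 0))
  du <- suppressWarnings(min(pos - d$end_a[d$end_a <= pos]))
  dd <- suppressWarnings(min(d$start_a[d$start_a > pos] - pos))
  list(containing = FALSE, d = min(du, dd))
}
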