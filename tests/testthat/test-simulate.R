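test_that("an infinite divergence threshold keeps every anchor alignable everywhere", {
  tree <- linear_tree(c("A", "B", "C"), 1)
  sim <- simulate_multispecies_anchors(tree, n_anchors = 30L, anchor_len = 60L,
                                       spacer_meanlog = log(100),
                                       spacer_sdlog = 0.2,
                                       theta = Inf, seed = 5)
  expect_true(all(unlist(sim$alignable)))
  # dense anchors + tiny spacers: every query lands within the DC distance
  idx <- build_pair_indexes(chains_from_sim(sim))
  q <- simulate_queries(sim, "A", n = 40, seed = 6, width = 10)
  tab <- project_regions(q, "A", "C", idx, quiet = TRUE)
  expect_true(all(tab$class == "DC"))
  expect_true(all(tab$d_direct <= 300))
})

test_that("a vanishing threshold leaves no anchors and unprojectable queries", {
  tree <- linear_tree(c("A", "B"), 1)
  expect_warning(
    sim <- simulate_multispecies_anchors(tree, n_anchors = 10L,
                                         theta = 1e-12, seed = 5),
    "no anchor"
  )
  expect_length(chains_from_sim(sim), 0)
  q <- simulate_queries(sim, "A", n = 5, seed = 6, width = 10)
  tab <- project_regions(q, "A", "B", list(), quiet = TRUE)
  expect_true(all(tab$class == "UNPROJECTABLE"))
})

test_that("degenerate divergence makes adjacent pairs bridged-only by construction", {
  tree <- linear_tree(c("A", "B", "C"), 1)
  theta <- 1
  sim <- simulate_multispecies_anchors(
    tree, n_anchors = 20L, anchor_len = 60L,
    spacer_meanlog = log(400), spacer_sdlog = 0.3,
    theta = theta, seed = 9,
    divergence = function(n, len) rep(0.6 * theta * len, n)
  )
  # per-branch 0.6*theta: A-B and B-C alignable, A-C (1.2*theta) never
  expect_true(all(sim$alignable[["A|B"]]))
  expect_true(all(sim$alignable[["B|C"]]))
  expect_false(any(sim$alignable[["A|C"]]))
  idx <- build_pair_indexes(chains_from_sim(sim))
  q <- simulate_queries(sim, "A", n = 30, seed = 10, width = 10)
  tab <- project_regions(q, "A", "C", idx, quiet = TRUE)
  expect_true(all(is.na(tab$d_direct)))
  expect_true(all(tab$class == "IC"))
  expect_true(all(tab$path == "A>B>C"))
})

test_that("simulated chains satisfy every chain invariant", {
  fx <- standard_fixture(seed = 13, n_queries = 1)
  chains <- chains_from_sim(fx$sim)
  expect_gt(length(chains), 0)
  for (key in names(chains)) {
    for (ch in chains[[key]]) {
      b <- ch$blocks
      expect_true(all(b$size > 0))
      expect_true(is.na(b$dt[nrow(b)]) && is.na(b$dq[nrow(b)]))
      expect_equal(sum(b$size) + sum(b$dt, na.rm = TRUE), ch$ref$end - ch$ref$start)
      expect_equal(sum(b$size) + sum(b$dq, na.rm = TRUE), ch$qry$end - ch$qry$start)
    }
  }
})

test_that("truth positions sit at matching anchor offsets and spacer fractions", {
  tree <- linear_tree(c("A", "B"), 1)
  sim <- simulate_multispecies_anchors(tree, n_anchors = 5L, anchor_len = 60L,
                                       spacer_meanlog = log(300),
                                       spacer_sdlog = 0.4,
                                       theta = Inf, seed = 17)
  # anchor midpoint maps to the corresponding anchor midpoint
  for (i in 1:5) {
    mid_a <- unname(sim$starts[i, "A"]) + 30L
    expect_equal(sim_truth_map(sim, "A", mid_a, "B"),
                 unname(sim$starts[i, "B"]) + 30L)
    expect_equal(truth_lookup(sim, "A", mid_a, "B")$expected_class, "DC")
  }
  # spacer midpoint maps to the fractional position of the target spacer
  lo_a <- unname(sim$starts[1, "A"]) + 60L
  hi_a <- unname(sim$starts[2, "A"])
  mid_spacer <- (lo_a + hi_a) %/% 2L
  frac <- (mid_spacer - lo_a) / (hi_a - lo_a)
  lo_b <- unname(sim$starts[1, "B"]) + 60L
  hi_b <- unname(sim$starts[2, "B"])
  expect_equal(sim_truth_map(sim, "A", mid_spacer, "B"),
               as.integer(lo_b + floor(frac * (hi_b - lo_b) + 0.5)))
})

test_that("the oracle classifies bridged-only and anchor-desert queries as stated", {
  tree <- linear_tree(c("A", "B", "C"), 1)
  theta <- 1
  sim <- simulate_multispecies_anchors(
    tree, n_anchors = 4L, anchor_len = 60L,
    spacer_meanlog = log(6000), spacer_sdlog = 0.01,
    theta = theta, seed = 3,
    divergence = function(n, len) rep(0.6 * theta * len, n)
  )
  # just beside an anchor: bridged-only, summed distance < 2.5 kb -> IC
  pos_near <- unname(sim$starts[2, "A"]) - 100L
  near <- oracle_project_point(sim, "A", pos_near, "C")
  expect_equal(near$class, "IC")
  expect_lt(near$bridged_distance, 2500)

  # all pairs alignable, but the query sits midway in a ~6 kb anchor desert:
  # direct projection exists at ~3 kb and every bridged path is pruned -> NC
  sim2 <- simulate_multispecies_anchors(
    tree, n_anchors = 4L, anchor_len = 60L,
    spacer_meanlog = log(6000), spacer_sdlog = 0.01,
    theta = theta, seed = 3,
    divergence = function(n, len) rep(0.3 * theta * len, n)
  )
  pos_far <- unname(sim2$starts[1, "A"]) + 60L + 3000L
  far <- oracle_project_point(sim2, "A", pos_far, "C")
  expect_equal(far$class, "NC")
  expect_gt(far$direct_d, 2500)
  expect_true(is.na(far$bridged_distance))
})

test_that("an inversion run yields minus-strand chains that project correctly", {
  tree <- linear_tree(c("A", "B"), 1)
  sim <- simulate_multispecies_anchors(tree, n_anchors = 10L, anchor_len = 60L,
                                       spacer_meanlog = log(300),
                                       spacer_sdlog = 0.3, theta = Inf,
                                       seed = 23,
                                       inversion = list(species = "B",
                                                        from = 4L, to = 6L))
  chains <- chains_from_sim(sim)[["A|B"]]
  strands <- vapply(chains, function(ch) ch$qry$strand, character(1))
  expect_true(any(strands == "-"))
  idx <- build_pair_indexes(list("A|B" = chains))[["A|B"]]
  # in-block positions still map to their true ortholog positions
  for (i in c(3L, 4L, 5L, 6L, 7L)) {
    pos <- sim$starts[i, "A"] + 17L
    got <- project_pairwise(idx, "A", "chr1", pos)
    expect_equal(got$target$pos,
                 as.integer(sim_truth_map(sim, "A", pos, "B")))
  }
})

test_that("identical seeds reproduce simulations byte for byte", {
  dir1 <- file.path(tempdir(), "simrep1")
  dir2 <- file.path(tempdir(), "simrep2")
  for (d in c(dir1, dir2)) {
    unlink(d, recursive = TRUE)
    fx <- standard_fixture(seed = 19, n_queries = 20)
    mp <- simulate_motif_pairs(3, t_transpositions = 1, seed = 20)
    write_sim(fx$sim, fx$queries, "mmu", "gga", motif_pairs = mp, out_dir = d)
  }
  files <- list.files(dir1, recursive = TRUE)
  expect_gt(length(files), 4)
  for (f in files) {
    expect_equal(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                 label = f)
  }
})

test_that("motif pair simulation realizes the requested transposition counts", {
  pairs <- simulate_motif_pairs(8, n_motifs = 6, t_transpositions = c(0L, 3L),
                                seed = 29)
  expect_equal(vapply(pairs, `[[`, integer(1), "t"), rep(c(0L, 3L), 4))
  for (p in pairs) {
    ra <- prepare_ranking(p$hits_a)
    rb <- prepare_ranking(p$hits_b)
    k <- normalized_kendall_min(ra, rb)
    expect_equal(k$k_d, p$t / 15)
  }
  flipped <- simulate_motif_pairs(4, n_motifs = 6, t_transpositions = 0,
                                  orientation_flip_prob = 1, seed = 30)
  for (p in flipped) {
    expect_true(p$flipped)
    k <- normalized_kendall_min(prepare_ranking(p$hits_a),
                                prepare_ranking(p$hits_b))
    expect_equal(k$k_d, 0)
    expect_equal(k$orientation, "reverse")
  }
  expect_error(simulate_motif_pairs(1, n_motifs = 60), "window capacity")
  expect_error(simulate_motif_pairs(1, n_motifs = 6, t_transpositions = 4),
               "disjoint")
})

test_that("forward Kendall distance is bounded by the transposition count", {
  # t disjoint adjacent transpositions create exactly t discordant pairs;
  # overlapping ones can cancel, so t/C(n,2) is an upper bound in general
  set.seed(33)
  n <- 6
  for (rep in 1:25) {
    perm <- LETTERS[1:n]
    t <- sample(0:7, 1)
    for (k in seq_len(t)) {
      p <- sample.int(n - 1, 1)
      perm[c(p, p + 1)] <- perm[c(p + 1, p)]
    }
    kf <- brute_kendall(LETTERS[1:n], perm)
    expect_lte(kf, t / (n * (n - 1) / 2))
  }
})
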