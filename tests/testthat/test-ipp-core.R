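test_that("pairwise projection maps in-block, interpolated and inverted points", {
  # inside the anchor: exact offset
  p <- project_pairwise(toy_index(), "A", "chrA", 1050)
  expect_equal(p$target$pos, 2050)
  expect_equal(p$d, 0)
  expect_equal(p$mode, "in_block")

  # between anchors: linear interpolation of the facing edges
  idx <- build_index(make_anchors(c(1000, 1500), c(1100, 1600),
                                  c(2000, 3000), c(2100, 3100)))
  p2 <- project_pairwise(idx, "A", "chrA", 1300)
  expect_equal(p2$target$pos, 2550)  # 2100 + 0.5 * (3000 - 2100)
  expect_equal(p2$d, 200)
  expect_equal(p2$mode, "interpolated")

  # inverted containing anchor: reverse-offset arithmetic
  inv <- build_index(make_anchors(1000, 1100, 5000, 5100, "inverted"))
  p3 <- project_pairwise(inv, "A", "chrA", 1010)
  expect_equal(p3$target$pos, 5089)  # 5100 - 1 - (1010 - 1000)
  expect_equal(p3$d, 0)
})

test_that("pairwise projection extrapolates one-sided beyond the outermost anchor", {
  p <- project_pairwise(toy_index(), "A", "chrA", 950)
  expect_equal(p$mode, "one_sided")
  expect_equal(p$d, 50)
  expect_equal(p$target$pos, 1950)  # constant offset from the block map
  expect_null(project_pairwise(toy_index(), "A", "chrZ", 100))
})

test_that("opposite-orientation flanks fall back to the nearest anchor's map", {
  idx <- build_index(make_anchors(c(1000, 1500), c(1100, 1600),
                                  c(2000, 3000), c(2100, 3100),
                                  orientation = c("same", "inverted")))
  p <- project_pairwise(idx, "A", "chrA", 1150)
  expect_equal(p$mode, "one_sided")
  expect_equal(p$target$pos, 2150)  # upstream same-orientation map extended
})

# three-species toy: direct A->C anchor far away, A->B and B->C close.
# A anchors: direct (A|C) at a distance of 5000 from pos; A|B at 400; after
# projecting into B, the B|C anchor sits 600 away.
three_species_indexes <- function() {
  pos <- 10000
  list(
    "A|C" = build_index(make_anchors(pos + 5000, pos + 5100, 20000, 20100,
                                     species_a = "A", species_b = "C")),
    "A|B" = build_index(make_anchors(pos + 400, pos + 500, 10400, 10500,
                                     species_a = "A", species_b = "B",
                                     chrom_b = "chrB")),
    "B|C" = build_index(make_anchors(10000 - 700, 10000 - 600, 21000, 21100,
                                     species_a = "B", species_b = "C",
                                     chrom_a = "chrB"))
  )
}

test_that("the bridged search prefers the two-hop path with smaller summed distance", {
  idx <- three_species_indexes()
  path <- best_bridged_path("A", "chrA", 10000, "C", idx)
  expect_equal(path$species_sequence, c("A", "B", "C"))
  expect_equal(path$total_distance, 1000)  # 400 via B + 600 from B to C
  expect_equal(sum(vapply(path$per_hop, `[[`, numeric(1), "d")),
               path$total_distance)
})

test_that("a query inside a direct anchor takes the zero-cost single hop", {
  idx <- three_species_indexes()
  path <- best_bridged_path("A", "chrA", 15050, "C", idx)
  expect_equal(path$species_sequence, c("A", "C"))
  expect_equal(path$total_distance, 0)
})

test_that("paths at or beyond the summed-distance bound are pruned to none", {
  idx <- three_species_indexes()
  params <- ipp_params(dc_threshold = 300, ic_threshold = 1000)
  expect_null(best_bridged_path("A", "chrA", 10000, "C", idx, params))
  params2 <- ipp_params(dc_threshold = 300, ic_threshold = 1001)
  expect_equal(best_bridged_path("A", "chrA", 10000, "C", idx, params2)$total_distance,
               1000)
})

test_that("classification applies the documented DC/IC/NC boundaries", {
  params <- ipp_params()
  direct <- function(d) list(d = d)
  bridged <- function(s) list(total_distance = s)
  expect_equal(classify(direct(150), NULL, params), "DC")
  expect_equal(classify(direct(300), NULL, params), "DC")    # inclusive
  expect_equal(classify(direct(301), bridged(100), params), "IC")
  expect_equal(classify(direct(5000), bridged(1800), params), "IC")
  expect_equal(classify(direct(5000), bridged(2499), params), "IC")
  expect_equal(classify(direct(5000), bridged(2500), params), "NC")  # exclusive
  expect_equal(classify(direct(5000), NULL, params), "NC")
  expect_equal(classify(NULL, NULL, params), "UNPROJECTABLE")
})

test_that("project_regions composes per-region classes and survives edge cases", {
  idx <- three_species_indexes()
  params <- ipp_params(ic_threshold = 1001)
  bed <- data.frame(chrom = c("chrA", "chrA", "chrA", "chrZ"),
                    start = c(15000, 9950, 2000, 0),
                    end = c(15100, 10050, 2100, 100),
                    name = c("dc", "ic", "nc", "unproj"))
  tab <- project_regions(bed, "A", "C", idx, params, quiet = TRUE)
  expect_equal(tab$class, c("DC", "IC", "NC", "UNPROJECTABLE"))
  expect_equal(tab$point, c(15050, 10000, 2050, 50))
  expect_equal(tab$path[[2]], "A>B>C")

  empty <- project_regions(bed[0, ], "A", "C", idx, params, quiet = TRUE)
  expect_equal(nrow(empty), 0)
})

test_that("a summit column overrides the midpoint as point of projection", {
  idx <- list("A|B" = toy_index())
  bed <- data.frame(chrom = "chrA", start = 1000, end = 1100, summit = 10)
  tab <- project_regions(bed, "A", "B", idx, quiet = TRUE)
  expect_equal(tab$point, 1010)
  expect_equal(tab$tpos_direct, 2010)
})

test_that("projection round-trips exactly for positions inside anchor blocks", {
  fx <- standard_fixture(seed = 3, n_queries = 1)
  anchors <- sim_pair_anchors(fx$sim, "mmu", "gga")
  idx <- build_index(anchors)
  set.seed(31)
  rows <- sample(nrow(anchors), 50, replace = TRUE)
  for (r in rows) {
    pos <- anchors$start_a[[r]] +
      sample.int(anchors$end_a[[r]] - anchors$start_a[[r]], 1) - 1L
    fwd <- project_pairwise(idx, "mmu", "chr1", pos)
    back <- project_pairwise(idx, "gga", fwd$target$chrom, fwd$target$pos)
    expect_equal(back$target$pos, pos)
  }
})

test_that("the bridged search equals exhaustive enumeration on simulated graphs", {
  for (seed in c(5, 6)) {
    tree <- linear_tree(c("A", "B", "C", "D"), 1)
    sim <- simulate_multispecies_anchors(tree, n_anchors = 20L, anchor_len = 60L,
                                         spacer_meanlog = log(500),
                                         spacer_sdlog = 1, theta = 1.5,
                                         seed = seed)
    idx <- build_pair_indexes(chains_from_sim(sim))
    set.seed(seed)
    for (pos in sample.int(sim$sizes[["A"]], 40)) {
      got <- best_bridged_path("A", "chr1", pos, "D", idx)
      ref <- oracle_project_point(sim, "A", pos, "D")
      if (is.null(got)) {
        expect_true(is.na(ref$bridged_distance))
      } else {
        expect_equal(got$total_distance, ref$bridged_distance)
        expect_equal(paste(got$species_sequence, collapse = ">"), ref$path)
        expect_equal(got$final$pos, ref$bridged_pos)
      }
    }
  }
})

test_that("DC classification depends only on the direct index", {
  fx <- standard_fixture(seed = 8, n_queries = 60)
  idx_all <- build_pair_indexes(chains_from_sim(fx$sim))
  idx_direct <- idx_all["gga|mmu"]
  p_all <- project_regions(fx$queries, "mmu", "gga", idx_all, quiet = TRUE)
  p_dir <- project_regions(fx$queries, "mmu", "gga", idx_direct, quiet = TRUE)
  expect_equal(p_all$class == "DC", p_dir$class == "DC")
  expect_equal(p_all$d_direct, p_dir$d_direct)
})
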