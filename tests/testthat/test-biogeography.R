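test_that("unit presence is the OR over the unit's samples", {
  meta <- data.frame(sample_id = paste0("s", 1:5), lake = "L1",
                     region = "LIM", library_size = 1L)
  p <- matrix(0L, 5, 2, dimnames = list(meta$sample_id, c("G1", "G2")))
  p["s3", "G1"] <- 1L
  out <- collapse_presence(p, meta, "lake")
  expect_true(out["L1", "G1"])
  expect_false(out["L1", "G2"])

  meta2 <- rbind(meta, data.frame(sample_id = "s6", lake = "L2",
                                  region = "LIM", library_size = 1L))
  expect_warning(collapse_presence(p, meta2, "lake"), "no samples")
})

test_that("collapsing samples to lakes to regions is associative", {
  sim <- tiny_sim()
  ab <- build_abundance_table(sim$depth, sim$catalog, sim$metadata, 0.70)
  p <- presence_table(ab)
  by_region_direct <- collapse_presence(p, sim$metadata, "region")
  by_lake <- collapse_presence(p, sim$metadata, "lake")
  lake_meta <- unique(sim$metadata[c("lake", "region")])
  lake_as_sample <- data.frame(sample_id = lake_meta$lake,
                               lake = lake_meta$lake,
                               region = lake_meta$region,
                               library_size = 1L)
  by_region_via_lakes <- collapse_presence(by_lake + 0L, lake_as_sample,
                                           "region")
  expect_equal(by_region_direct[rownames(by_region_via_lakes), ],
               by_region_via_lakes)
})

test_that("upset counts use exact-subset semantics", {
  p <- matrix(0L, 3, 4,
              dimnames = list(c("u1", "u2", "u3"), paste0("G", 1:4)))
  p["u1", c("G1", "G2")] <- 1L
  p["u2", "G2"] <- 1L
  p["u3", "G3"] <- 1L
  u <- upset_counts(p)
  ints <- setNames(u$intersections$count, u$intersections$subset)
  expect_equal(ints[["u1&u2"]], 1)   # G2 counted once, in its exact subset
  expect_equal(ints[["u1"]], 1)
  expect_equal(ints[["u3"]], 1)
  expect_false("u2" %in% names(ints))
  # a unit whose GVMAGs are all exclusive has uniqueness 1
  expect_equal(
    u$per_unit$uniqueness_fraction[u$per_unit$unit == "u3"], 1)
  # directional sharing: |u1 n u2|/|u1| vs /|u2|
  pw <- u$pairwise
  expect_equal(pw$shared_pct[pw$unit == "u1" & pw$other == "u2"], 50)
  expect_equal(pw$shared_pct[pw$unit == "u2" & pw$other == "u1"], 100)
})

test_that("upset counts equal brute-force enumeration on random matrices", {
  set.seed(202)
  for (rep in 1:25) {
    p <- matrix(rbinom(4 * 50, 1, 0.3), 4,
                dimnames = list(paste0("u", 1:4), paste0("G", 1:50)))
    got <- upset_counts(p)
    want <- upset_brute(p)
    got_map <- setNames(got$intersections$count, got$intersections$subset)
    expect_setequal(names(got_map), names(want))
    expect_equal(got_map[names(want)], unlist(want), ignore_attr = TRUE)
    # counts tile the detected GVMAGs
    expect_equal(sum(got$intersections$count), sum(colSums(p) > 0))
  }
})

test_that("uniqueness fractions are invariant to duplicating a sample", {
  sim <- tiny_sim()
  ab <- build_abundance_table(sim$depth, sim$catalog, sim$metadata, 0.70)
  p <- presence_table(ab)
  meta <- sim$metadata
  p2 <- rbind(p, dup = p[1, ])
  rownames(p2)[nrow(p2)] <- "dup"
  meta2 <- rbind(meta, within(meta[1, ], sample_id <- "dup"))
  u1 <- upset_counts(collapse_presence(p, meta, "lake"))
  u2 <- upset_counts(collapse_presence(p2, meta2, "lake"))
  expect_equal(u1$per_unit, u2$per_unit)
})

test_that("protein cluster region sets and specificity fractions", {
  regions <- c(G1 = "Antarctic", G2 = "Antarctic", G3 = "Arctic_subarctic",
               G4 = "Temperate")
  cl <- data.frame(
    cluster_id = c("P1", "P1", "P2", "P2", "P3"),
    gvmag_id = c("G1", "G2", "G3", "G4", "G1"),
    protein_id = paste0("p", 1:5))
  out <- protein_cluster_distribution(cl, regions)
  cr <- out$cluster_regions
  expect_equal(cr$regions[cr$cluster_id == "P1"], "Antarctic")
  expect_true(cr$polar_specific[cr$cluster_id == "P1"])
  # Arctic+Temperate cluster is not polar-specific
  expect_false(cr$polar_specific[cr$cluster_id == "P2"])
  expect_equal(out$polar_specific_fraction, 2 / 3)
  spec <- out$region_specificity
  expect_equal(spec$specificity_fraction[spec$region == "Antarctic"], 1)

  expect_error(protein_cluster_distribution(cl, regions[-1]), "region")
})

test_that("planted polar-specific cluster fraction is recovered", {
  sim <- medium_sim()
  out <- protein_cluster_distribution(sim$protein_clusters,
                                      sim$truth$origin_region)
  expect_lt(abs(out$polar_specific_fraction -
                  sim$config$polar_specific_cluster_fraction), 0.05)
  expect_setequal(
    out$cluster_regions$cluster_id[out$cluster_regions$polar_specific],
    sim$truth$polar_specific_clusters)
})
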