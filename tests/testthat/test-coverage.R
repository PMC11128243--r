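make_depth <- function(ids, lens, depths, covered, sample = "s1") {
  d <- data.frame(contig_id = ids, contig_len = as.integer(lens),
                  total_avg_depth = depths,
                  covered_bases = as.integer(covered),
                  stringsAsFactors = FALSE)
  attr(d, "sample_id") <- sample
  class(d) <- c("gvlake_depth", "data.frame")
  d
}

two_contig_catalog <- gvlake:::new_catalog(data.frame(
  gvmag_id = c("G1", "G1"), contig_id = c("c1", "c2"),
  contig_len = c(40000L, 40000L), stringsAsFactors = FALSE))

test_that("gvmag depth is the length-weighted mean of contig depths", {
  cat2 <- gvlake:::new_catalog(data.frame(
    gvmag_id = "G1", contig_id = c("c1", "c2"),
    contig_len = c(100e3L, 300e3L)))
  d <- make_depth(c("c1", "c2"), c(100e3, 300e3), c(10, 2),
                  c(50e3, 150e3))
  expect_equal(gvmag_depth(d, cat2, "G1"),
               (100e3 * 10 + 300e3 * 2) / 400e3)
  expect_equal(gvmag_depth(d, cat2, "G1"), 4)

  d0 <- make_depth(c("c1", "c2"), c(100e3, 300e3), c(0, 0), c(0, 0))
  expect_equal(gvmag_depth(d0, cat2, "G1"), 0)

  cat1 <- gvlake:::new_catalog(data.frame(
    gvmag_id = "G1", contig_id = "c1", contig_len = 100000L))
  d1 <- make_depth("c1", 100000, 7.5, 90000)
  expect_equal(gvmag_depth(d1, cat1, "G1"), 7.5)

  expect_error(gvmag_depth(d, cat2, "nope"), "not in catalog")
})

test_that("breadth is summed covered bases over total length", {
  cat2 <- gvlake:::new_catalog(data.frame(
    gvmag_id = "G1", contig_id = c("c1", "c2"),
    contig_len = c(100000L, 100000L)))
  d <- make_depth(c("c1", "c2"), c(1e5, 1e5), c(1, 1), c(80000, 10000))
  expect_equal(gvmag_breadth(d, cat2, "G1"), 0.45)
  d0 <- make_depth(c("c1", "c2"), c(1e5, 1e5), c(0, 0), c(0, 0))
  expect_equal(gvmag_breadth(d0, cat2, "G1"), 0)
  d1 <- make_depth(c("c1", "c2"), c(1e5, 1e5), c(2, 2), c(1e5, 1e5))
  expect_equal(gvmag_breadth(d1, cat2, "G1"), 1)
})

test_that("missing contigs contribute zero depth and breadth", {
  d <- make_depth("c1", 40000, 6, 20000)
  expect_equal(gvmag_depth(d, two_contig_catalog, "G1"),
               40000 * 6 / 80000)
  expect_equal(gvmag_breadth(d, two_contig_catalog, "G1"), 0.25)
})

test_that("normalization scales by library size times 1e9", {
  expect_equal(normalize_coverage(4, 1e6), 4000)
  expect_equal(normalize_coverage(0, 123), 0)
  expect_equal(normalize_coverage(3.7, 1e9), 3.7)
  expect_error(normalize_coverage(1, 0), "positive")
})

test_that("presence cutoffs are inclusive and flip exactly at the boundary", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), lake = "L",
                     region = "LIM", library_size = 1e6L,
                     stringsAsFactors = FALSE)
  # breadths: 0.699 (below 0.70), 0.70 exactly, 0.25 exactly
  depths <- list(
    s1 = make_depth(c("c1", "c2"), c(4e4, 4e4), c(1, 1),
                    c(40000, 15920), "s1"),   # 55920/80000 = 0.699
    s2 = make_depth(c("c1", "c2"), c(4e4, 4e4), c(1, 1),
                    c(40000, 16000), "s2"),   # 0.70 exactly
    s3 = make_depth(c("c1", "c2"), c(4e4, 4e4), c(1, 1),
                    c(20000, 0), "s3"))       # 0.25 exactly
  ab70 <- build_abundance_table(depths, two_contig_catalog, meta, 0.70)
  expect_equal(unname(ab70["s1", "G1"]), 0)
  expect_gt(ab70["s2", "G1"], 0)
  ab25 <- build_abundance_table(depths, two_contig_catalog, meta, 0.25)
  expect_gt(ab25["s3", "G1"], 0)
})

test_that("normalized coverage is scale-equivariant and presence is not", {
  sim <- tiny_sim()
  ab <- build_abundance_table(sim$depth, sim$catalog, sim$metadata, 0.25)
  scaled <- sim$depth
  s <- names(scaled)[1]
  scaled[[s]]$total_avg_depth <- scaled[[s]]$total_avg_depth * 3
  ab2 <- build_abundance_table(scaled, sim$catalog, sim$metadata, 0.25)
  expect_equal(ab2[s, ], 3 * ab[s, ])
  expect_equal(ab2[-1, ], ab[-1, ])
  expect_equal(ab2 > 0, ab > 0)
})

test_that("presence at 0.70 implies presence at 0.25", {
  sim <- tiny_sim()
  ab25 <- build_abundance_table(sim$depth, sim$catalog, sim$metadata, 0.25)
  ab70 <- build_abundance_table(sim$depth, sim$catalog, sim$metadata, 0.70)
  expect_true(all(ab25[ab70 > 0] > 0))
})

test_that("marker filter needs >= 4 of 7 markers and <= 4 copies each", {
  mk <- data.frame(gvmag_id = c("A", "B", "C"),
                   m1 = c(1L, 1L, 1L), m2 = c(1L, 1L, 1L),
                   m3 = c(1L, 1L, 1L), m4 = c(1L, 1L, 0L),
                   m5 = c(0L, 5L, 0L), m6 = c(0L, 0L, 0L),
                   m7 = c(0L, 0L, 0L))
  expect_equal(marker_filter(mk), "A")
  expect_error(marker_filter(mk[, 1:6]), "7 marker")
  # copy counts 2-4 are fine; marker presence means >= 1 copy
  mk2 <- data.frame(gvmag_id = "D", m1 = 4L, m2 = 4L, m3 = 2L, m4 = 3L,
                    m5 = 0L, m6 = 0L, m7 = 0L)
  expect_equal(marker_filter(mk2), "D")
})

test_that("viral restriction recomputes lengths and drops short GVMAGs", {
  flags_all <- c(c1 = TRUE, c2 = TRUE)
  expect_equal(as.data.frame(restrict_to_viral(two_contig_catalog,
                                               flags_all)),
               as.data.frame(two_contig_catalog))
  # dropping one 40 kb contig sinks the GVMAG below the 75 kb floor
  flags_half <- c(c1 = TRUE, c2 = FALSE)
  expect_warning(out <- restrict_to_viral(two_contig_catalog, flags_half),
                 "no GVMAG survives")
  expect_equal(nrow(out), 0)
  flags_none <- c(c1 = FALSE, c2 = FALSE)
  expect_warning(out2 <- restrict_to_viral(two_contig_catalog,
                                           flags_none), "survives")
  expect_equal(nrow(out2), 0)
  expect_error(restrict_to_viral(two_contig_catalog, c(c1 = TRUE)),
               "missing")
  expect_warning(
    restrict_to_viral(two_contig_catalog,
                      c(c1 = TRUE, c2 = TRUE, cx = TRUE)),
    "not in catalog")
})
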