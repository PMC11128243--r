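test_that("clade binarization thresholds at the clade mean, ties rare", {
  ec <- data.frame(sample_id = c("s1", "s2"), clade = "X",
                   read_count = c(0, 10))
  lab <- binarize_clades(ec)
  expect_equal(as.character(lab$label), c("rare", "abundant"))
  expect_equal(unname(attr(lab, "thresholds")[["X"]]), 5)

  ec2 <- data.frame(sample_id = paste0("s", 1:3), clade = "Y",
                    read_count = c(5, 5, 5))
  expect_equal(as.character(binarize_clades(ec2)$label), rep("rare", 3))

  ec3 <- data.frame(sample_id = paste0("s", 1:3), clade = "Z",
                    read_count = c(1, 2, 9))
  expect_equal(as.character(binarize_clades(ec3)$label),
               c("rare", "rare", "abundant"))

  ec4 <- data.frame(sample_id = paste0("s", 1:3), clade = "W",
                    read_count = c(0, 0, 0))
  expect_warning(lab4 <- binarize_clades(ec4), "all-rare")
  expect_equal(as.character(lab4$label), rep("rare", 3))

  # invariant to positive rescaling of a clade's counts
  ec5 <- data.frame(sample_id = paste0("s", 1:4), clade = "V",
                    read_count = c(1, 4, 2, 9))
  expect_equal(binarize_clades(ec5)$label,
               binarize_clades(transform(ec5,
                                         read_count = read_count * 7))$label)
})

test_that("clade filter applies the 1% abundance and <25% error rules", {
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     lake = rep(c("L1", "L2"), each = 2),
                     region = "LIM", library_size = 1L)
  # clade A is 0.9% everywhere; B is 5% in L1
  ec <- rbind(
    data.frame(sample_id = paste0("s", 1:4), clade = "A",
               read_count = c(9, 9, 9, 9)),
    data.frame(sample_id = paste0("s", 1:4), clade = "B",
               read_count = c(91, 9, 5, 5)),
    data.frame(sample_id = paste0("s", 1:4), clade = "C",
               read_count = c(900, 982, 986, 986)))
  mk_report <- function(oob) structure(
    list(oob_error = oob, degenerate = FALSE), class = "gvlake_rf_report")
  reports <- list(A = mk_report(0.1), B = mk_report(0.24),
                  C = mk_report(0.25))
  out <- filter_clades(ec, meta, reports)
  expect_false("A" %in% out)   # under 1% in every lake
  expect_true("B" %in% out)    # 5% in one lake, error 0.24
  expect_false("C" %in% out)   # error exactly 0.25 is excluded
})

test_that("edge selection keeps top plus up to three within the 80% window", {
  mk <- function(imp) structure(list(importance = imp, degenerate = FALSE),
                                class = "gvlake_rf_report")
  e1 <- select_edges(mk(c(F1 = 10, F2 = 8.5, F3 = 7.9)), "cl")
  expect_equal(e1$family, c("F1", "F2"))
  expect_equal(e1$is_top, c(TRUE, FALSE))

  # five ties at 9: cap at three extras, lexicographic order
  e2 <- select_edges(mk(c(F1 = 10, F6 = 9, F5 = 9, F4 = 9, F3 = 9,
                          F2 = 9)), "cl")
  expect_equal(e2$family, c("F1", "F2", "F3", "F4"))
  expect_equal(sum(e2$is_top), 1)

  e3 <- select_edges(mk(c(solo = 4)), "cl")
  expect_equal(nrow(e3), 1)

  expect_warning(e4 <- select_edges(mk(c(F1 = 0, F2 = 0)), "cl"),
                 "all-zero")
  expect_equal(nrow(e4), 0)

  # ratio-based window is invariant to rescaling all importances
  e5 <- select_edges(mk(c(F1 = 10, F2 = 8.5, F3 = 7.9) * 1e3), "cl")
  expect_equal(e5$family, e1$family)
})

test_that("random forests recover separable targets and stay honest on noise", {
  set.seed(9)
  n <- 50
  x <- matrix(rlnorm(n * 5), n,
              dimnames = list(paste0("s", 1:n), paste0("F", 1:5)))
  target <- factor(ifelse(x[, "F3"] > median(x[, "F3"]),
                          "abundant", "rare"),
                   levels = c("rare", "abundant"))
  rep1 <- tune_and_fit(x, target, n_tree = 300, n_tree_try = 300,
                       seed = 1)
  expect_lt(rep1$oob_error, 0.05)
  expect_equal(names(which.max(rep1$importance)), "F3")

  rep2 <- tune_and_fit(x, target, n_tree = 300, n_tree_try = 300,
                       seed = 1)
  expect_identical(rep1$importance, rep2$importance)
  expect_identical(rep1$oob_error, rep2$oob_error)

  # pure-noise targets hover near 50% OOB error
  errs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    y <- factor(sample(c("rare", "abundant"), n, replace = TRUE),
                levels = c("rare", "abundant"))
    tune_and_fit(x, y, n_tree = 300, n_tree_try = 300,
                 seed = s)$oob_error
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)

  # single-class target is reported degenerate
  repd <- tune_and_fit(x, factor(rep("rare", n),
                                 levels = c("rare", "abundant")))
  expect_true(repd$degenerate)
})

test_that("the network recovers planted edges and filters null clades", {
  sim <- medium_sim()
  ab25 <- build_abundance_table(sim$depth, sim$catalog, sim$metadata,
                                0.25)
  net <- build_network(sim$euk_counts, ab25, sim$taxonomy, sim$metadata,
                       seed = 1)
  top <- net$edges[net$edges$is_top, ]
  planted <- sim$truth$planted
  hits <- mapply(function(cl, fam)
    any(top$clade == cl & top$family == fam),
    planted$clade, planted$family)
  expect_true(all(hits))
  # every clade has exactly one top edge and at most 4 edges
  for (cl in unique(net$edges$clade)) {
    sub <- net$edges[net$edges$clade == cl, ]
    expect_equal(sum(sub$is_top), 1)
    expect_lte(nrow(sub), 4)
    expect_true(all(sub$gini[!sub$is_top] >= 0.8 * max(sub$gini)))
  }
  # null clades rarely sneak through the error filter
  n_null <- length(setdiff(unique(sim$euk_counts$clade), planted$clade))
  spurious <- length(setdiff(net$eligible, planted$clade))
  expect_lte(spurious, ceiling(n_null / 10))
})

test_that("network export writes edge list, SIF and model reports", {
  sim <- tiny_sim()
  ab <- build_abundance_table(sim$depth, sim$catalog, sim$metadata, 0.25)
  net <- build_network(sim$euk_counts, ab, sim$taxonomy, sim$metadata,
                       n_tree = 100, n_tree_try = 100, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  reread <- read.delim(file.path(dir, "edges.tsv"))
  expect_equal(nrow(reread), nrow(net$edges))
})
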