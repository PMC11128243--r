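#' Binarize eukaryote clade counts into rare/abundant
#'
#' Per clade, the threshold is the mean of its counts over all samples: a
#' sample is `"abundant"` when its count is strictly above the mean and
#' `"rare"` otherwise (ties at the mean are rare). Clades with zero total
#' counts become all-rare with a warning.
#'
#' @param euk_counts data frame from [read_euk_counts()].
#' @return data frame `sample_id`, `clade`, `read_count`, `label`
#'   (factor rare/abundant), with attribute `thresholds` (per-clade
#'   means).
#' @export
binarize_clades <- function(euk_counts) {
  if (length(unique(euk_counts$sample_id)) < 2) {
    stop("binarize_clades: need at least 2 samples", call. = FALSE)
  }
  means <- tapply(euk_counts$read_count, euk_counts$clade, mean)
  zero <- names(means)[means == 0]
  if (length(zero)) {
    warning("clade(s) with zero counts everywhere labeled all-rare: ",
            paste(zero, collapse = ", "))
  }
  out <- euk_counts
  out$label <- factor(
    ifelse(euk_counts$read_count > means[euk_counts$clade],
           "abundant", "rare"),
    levels = c("rare", "abundant"))
  attr(out, "thresholds") <- means
  out
}

#' Virus-family feature matrix for the association models
#'
#' Sums normalized coverage over the GVMAGs of each virus family, per
#' sample, from the 25%-cutoff abundance table.
#'
#' @param ab abundance matrix (samples x GVMAGs).
#' @param taxonomy data frame from [read_taxonomy()].
#' @return matrix samples x families.
#' @export
family_features <- function(ab, taxonomy) {
  fam <- taxonomy$family[match(colnames(ab), taxonomy$gvmag_id)]
  fam[is.na(fam)] <- "undetermined"
  t(rowsum(t(ab), fam))
}

#' Tune and fit one clade's random-forest model
#'
#' Binary classification (rare/abundant) from virus-family abundances.
#' `mtry` is tuned starting from `floor(sqrt(p))`, stepping by
#' `step_factor` and accepting a move only when the out-of-bag (OOB)
#' error improves by more than `improve` (relative), with `n_tree_try`
#' trees per candidate; the final forest is refit at the selected `mtry`
#' with `n_tree` trees. Importances are mean decrease in Gini impurity.
#'
#' @param features samples x families numeric matrix.
#' @param target factor of length `nrow(features)` with levels
#'   rare/abundant.
#' @param n_tree trees in the final forest.
#' @param n_tree_try trees per tuning candidate.
#' @param step_factor multiplicative step for the `mtry` search.
#' @param improve minimum relative OOB improvement to accept a step.
#' @param seed optional integer seed.
#' @return list of class `gvlake_rf_report`: `oob_error`,
#'   `mtry_selected`, `n_trees`, `importance` (named, mean decrease
#'   Gini), `degenerate`, `seed`. Single-class targets return a
#'   degenerate report (no model).
#' @export
tune_and_fit <- function(features, target, n_tree = 1000,
                         n_tree_try = 1000, step_factor = 1.5,
                         improve = 0.01, seed = NULL) {
  x <- as.matrix(features)
  y <- droplevels(as.factor(target))
  if (nlevels(y) < 2) {
    return(structure(list(oob_error = NA_real_, mtry_selected = NA_integer_,
                          n_trees = 0L,
                          importance = stats::setNames(
                            rep(NA_real_, ncol(x)), colnames(x)),
                          degenerate = TRUE, seed = seed),
                     class = "gvlake_rf_report"))
  }
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(x)
  mtry_start <- max(1L, floor(sqrt(p)))
  mtry <- mtry_start
  if (p >= 2) {
    # tuneRF prints improvement diagnostics even with trace = FALSE
    quiet <- utils::capture.output(
      tuned <- try(suppressMessages(randomForest::tuneRF(
        x, y, mtryStart = mtry_start, ntreeTry = n_tree_try,
        stepFactor = step_factor, improve = improve,
        trace = FALSE, plot = FALSE, doBest = FALSE)), silent = TRUE))
    if (!inherits(tuned, "try-error")) {
      mtry <- tuned[which.min(tuned[, "OOBError"]), "mtry"]
    }
  }
  rf <- randomForest::randomForest(x, y, mtry = mtry, ntree = n_tree)
  imp <- randomForest::importance(rf, type = 2)[, 1]
  structure(list(oob_error = unname(rf$err.rate[n_tree, "OOB"]),
                 mtry_selected = as.integer(mtry),
                 n_trees = as.integer(n_tree),
                 importance = imp, degenerate = FALSE, seed = seed),
            class = "gvlake_rf_report")
}

#' Filter clades on per-lake relative abundance and model error
#'
#' A clade is eligible when (a) its relative abundance (its share of the
#' summed eukaryote counts over a lake's samples) is at least
#' `min_rel_abund` in at least one lake, and (b) its model's OOB error is
#' strictly below `max_error`.
#'
#' @param euk_counts data frame from [read_euk_counts()].
#' @param metadata sample metadata.
#' @param reports named list of `gvlake_rf_report`, keyed by clade.
#' @param min_rel_abund minimum per-lake relative abundance.
#' @param max_error exclusive OOB error ceiling.
#' @return character vector of eligible clade names.
#' @export
filter_clades <- function(euk_counts, metadata, reports,
                          min_rel_abund = 0.01, max_error = 0.25) {
  lake <- metadata$lake[match(euk_counts$sample_id, metadata$sample_id)]
  by_lake <- rowsum(euk_counts$read_count,
                    paste(lake, euk_counts$clade, sep = "\r"))
  key <- strsplit(rownames(by_lake), "\r", fixed = TRUE)
  lakes <- vapply(key, `[`, "", 1)
  clades <- vapply(key, `[`, "", 2)
  lake_tot <- tapply(by_lake[, 1], lakes, sum)
  rel <- by_lake[, 1] / lake_tot[lakes]
  max_rel <- tapply(rel, clades, max)
  Filter(function(cl) {
    rep <- reports[[cl]]
    !is.null(rep) && !rep$degenerate &&
      isTRUE(max_rel[[cl]] >= min_rel_abund) &&
      rep$oob_error < max_error
  }, names(reports))
}

#' Select association edges from one model's importances
#'
#' Keeps the top-importance family, plus up to `max_extra` further
#' families whose mean-decrease-Gini importance is at least `window`
#' times the top importance, in decreasing order (ties broken by family
#' name). All-zero importances yield no edges with a warning.
#'
#' @param report a `gvlake_rf_report`.
#' @param clade clade name attached to the edges.
#' @param window retention window relative to the top importance.
#' @param max_extra maximum number of non-top edges.
#' @return data frame `clade`, `family`, `gini`, `is_top`.
#' @export
select_edges <- function(report, clade = NA_character_, window = 0.8,
                         max_extra = 3) {
  empty <- data.frame(clade = character(), family = character(),
                      gini = numeric(), is_top = logical(),
                      stringsAsFactors = FALSE)
  if (report$degenerate) return(empty)
  imp <- report$importance
  if (all(imp <= 0)) {
    warning("all-zero importances for clade ", clade, "; no edges")
    return(empty)
  }
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  top <- imp[1]
  extra <- imp[-1]
  extra <- extra[extra >= window * top]
  extra <- utils::head(extra, max_extra)
  kept <- c(imp[1], extra)
  data.frame(clade = clade, family = names(kept),
             gini = unname(kept),
             is_top = seq_along(kept) == 1,
             stringsAsFactors = FALSE)
}

#' Build the clade-family co-occurrence network
#'
#' Runs the full association procedure: binarize clade counts, fit one
#' tuned random forest per clade on virus-family abundances, filter
#' clades on per-lake relative abundance and OOB error, and select edges
#' with the top-explainer-plus-80%-window rule. Edge weights are mean
#' decrease Gini; the network is bipartite (clades vs virus families).
#'
#' @param euk_counts data frame from [read_euk_counts()].
#' @param ab 25%-cutoff abundance matrix (samples x GVMAGs).
#' @param taxonomy data frame from [read_taxonomy()].
#' @param metadata sample metadata.
#' @param min_rel_abund,max_error see [filter_clades()].
#' @param window,max_extra see [select_edges()].
#' @param n_tree,n_tree_try,step_factor,improve see [tune_and_fit()].
#' @param seed optional integer seed (governs all model fits).
#' @return list of class `gvlake_network`: `edges` (data frame),
#'   `reports` (per-clade model summaries), `eligible` (clades passing
#'   the filters), `seed`.
#' @export
build_network <- function(euk_counts, ab, taxonomy, metadata,
                          min_rel_abund = 0.01, max_error = 0.25,
                          window = 0.8, max_extra = 3, n_tree = 1000,
                          n_tree_try = 1000, step_factor = 1.5,
                          improve = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labeled <- binarize_clades(euk_counts)
  feats <- family_features(ab, taxonomy)
  clades <- sort(unique(labeled$clade))
  samples <- rownames(feats)
  reports <- lapply(clades, function(cl) {
    sub <- labeled[labeled$clade == cl, ]
    target <- sub$label[match(samples, sub$sample_id)]
    tune_and_fit(feats, target, n_tree = n_tree,
                 n_tree_try = n_tree_try, step_factor = step_factor,
                 improve = improve, seed = NULL)
  })
  names(reports) <- clades
  eligible <- filter_clades(euk_counts, metadata, reports,
                            min_rel_abund = min_rel_abund,
                            max_error = max_error)
  edges <- do.call(rbind, c(
    lapply(eligible, function(cl)
      select_edges(reports[[cl]], clade = cl, window = window,
                   max_extra = max_extra)),
    list(select_edges(
      structure(list(degenerate = TRUE), class = "gvlake_rf_report")))))
  rownames(edges) <- NULL
  structure(list(edges = edges, reports = reports, eligible = eligible,
                 seed = seed),
            class = "gvlake_network")
}

#' @export
print.gvlake_network <- function(x, ...) {
  cat(sprintf(
    "Clade-family association network: %d edge(s), %d eligible clade(s)\n",
    nrow(x$edges), length(x$eligible)))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Export a network as TSV edge list and SIF
#' @param network a `gvlake_network`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge_path <- file.path(dir, "edges.tsv")
  sif_path <- file.path(dir, "network.sif")
  report_path <- file.path(dir, "model_reports.tsv")
  write_tsv_file(network$edges, edge_path)
  writeLines(
    if (nrow(network$edges)) {
      paste(network$edges$clade, "associates", network$edges$family)
    } else character(0),
    sif_path)
  reports <- do.call(rbind, lapply(names(network$reports), function(cl) {
    r <- network$reports[[cl]]
    data.frame(clade = cl, oob_error = r$oob_error,
               mtry_selected = r$mtry_selected, n_trees = r$n_trees,
               degenerate = r$degenerate,
               eligible = cl %in% network$eligible,
               stringsAsFactors = FALSE)
  }))
  write_tsv_file(reports, report_path)
  invisible(c(edge_path, sif_path, report_path))
}
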