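#' Hellinger transformation of an abundance table
#'
#' Per sample (row): `y_ij = sqrt(x_ij / sum_j x_ij)`. Square-rooting
#' relative abundances keeps downstream distances from being dominated by
#' the most abundant genomes. All-zero rows are returned as all-zero with
#' a warning.
#'
#' @param x non-negative samples x taxa matrix.
#' @return transformed matrix of the same shape.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("hellinger: negative entries", call. = FALSE)
  zero <- rowSums(x) == 0
  if (any(zero)) {
    warning("hellinger: all-zero row(s) kept as all-zero: ",
            paste(rownames(x)[zero], collapse = ", "))
  }
  out <- x
  if (any(!zero)) {
    out[!zero, ] <- suppressWarnings(
      vegan::decostand(x[!zero, , drop = FALSE], method = "hellinger"))
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over taxa `i`.
#' A pair of all-zero samples gets distance 0 with a warning.
#'
#' @param x non-negative samples x taxa matrix (usually Hellinger
#'   transformed), at least two samples.
#' @return a `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("bray_curtis: need at least 2 samples",
                        call. = FALSE)
  if (any(x < 0)) stop("bray_curtis: negative entries", call. = FALSE)
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d)) {
    warning("bray_curtis: pair(s) of all-zero samples set to distance 0")
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- "bray_curtis"
  d
}

#' NMDS ordination of a distance matrix
#'
#' Non-metric multidimensional scaling (Kruskal stress-1, monotone
#' regression) with multiple random starts, via [vegan::metaMDS()].
#' Deterministic for a fixed seed.
#'
#' @param d a `dist` object.
#' @param k number of ordination dimensions (must be < number of
#'   samples).
#' @param n_starts number of random starts.
#' @param seed optional integer seed.
#' @return list with `points` (samples x k), `stress`, `converged`,
#'   `n_starts`, `seed`; class `gvlake_nmds`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = NULL) {
  n <- attr(d, "Size")
  if (k >= n) stop("nmds: k must be smaller than the number of samples",
                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- suppressMessages(suppressWarnings(
    vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                   trace = 0, autotransform = FALSE, wascores = FALSE)))
  structure(list(points = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged) ||
                   (is.numeric(fit$converged) && fit$converged > 0),
                 n_starts = n_starts, seed = seed),
            class = "gvlake_nmds")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor, computed from distance-based sums of squares:
#' `SS_total = sum_{j<k} d_jk^2 / N`,
#' `SS_within = sum_g sum_{j<k in g} d_jk^2 / n_g`,
#' `SS_among = SS_total - SS_within`, and
#' `F = (SS_among / (a - 1)) / (SS_within / (N - a))`.
#' The p-value is `(1 + #\{permuted F >= observed F\}) / (1 + n_perm)`
#' under free permutation of the labels; ties count as exceedances. When
#' groups are perfectly separated (`SS_within = 0`) the observed F is
#' `+Inf` and the p-value reaches its floor `1 / (n_perm + 1)`.
#'
#' @param d a `dist` object over samples.
#' @param groups group label per sample, in the order of `labels(d)` (or
#'   a named vector keyed by sample id).
#' @param n_perm number of label permutations.
#' @param seed optional integer seed.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_permutations` and
#'   the sums of squares; class `gvlake_permanova`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  dm2 <- as.matrix(d)^2
  n <- nrow(dm2)
  if (!is.null(names(groups)) && !is.null(labels(d))) {
    groups <- groups[labels(d)]
  }
  groups <- as.character(groups)
  if (length(groups) != n) stop("permanova: one label per sample required",
                                call. = FALSE)
  a <- length(unique(groups))
  if (a < 2) stop("permanova: need at least 2 groups", call. = FALSE)
  if (n_perm < 1) stop("permanova: n_perm must be >= 1", call. = FALSE)
  ss_total <- sum(dm2) / (2 * n)
  ss_within_for <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      s <- s + sum(dm2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ssa <- ss_total - ssw
    if (ssw <= 0) return(Inf)
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_for(groups)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_for(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  ssw <- ss_within_for(groups)
  structure(list(pseudo_F = f_obs,
                 R2 = (ss_total - ssw) / ss_total,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm,
                 ss_total = ss_total, ss_within = ssw,
                 ss_among = ss_total - ssw,
                 df_among = a - 1, df_within = n - a),
            class = "gvlake_permanova")
}

#' @export
print.gvlake_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (one-way, %d permutations)\n", x$n_permutations))
  cat(sprintf("  pseudo-F = %.4g  R2 = %.4f  p = %.4g\n",
              x$pseudo_F, x$R2, x$p_value))
  invisible(x)
}

#' Average taxonomic composition per lake or region
#'
#' Aggregates the abundance table to a taxonomic rank, converts each
#' sample to relative abundances, and averages those proportions across
#' the samples of each lake or region (mean of per-sample proportions,
#' robust to library-size differences). Samples with zero total abundance
#' are excluded with a warning.
#'
#' @param ab abundance matrix (samples x GVMAGs).
#' @param taxonomy data frame from [read_taxonomy()].
#' @param metadata sample metadata.
#' @param group_by `"lake"` or `"region"`.
#' @param rank `"order"` or `"family"`.
#' @return matrix groups x taxa; each row sums to 1.
#' @export
taxon_composition <- function(ab, taxonomy, metadata,
                              group_by = c("lake", "region"),
                              rank = c("order", "family")) {
  group_by <- match.arg(group_by)
  rank <- match.arg(rank)
  lab <- taxonomy[[rank]][match(colnames(ab), taxonomy$gvmag_id)]
  lab[is.na(lab)] <- "undetermined"
  by_rank <- t(rowsum(t(ab), lab))
  tot <- rowSums(by_rank)
  if (any(tot == 0)) {
    warning("taxon_composition: excluding all-zero sample(s): ",
            paste(rownames(ab)[tot == 0], collapse = ", "))
    by_rank <- by_rank[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  prop <- by_rank / tot
  grp <- metadata[[group_by]][match(rownames(prop), metadata$sample_id)]
  out <- rowsum(prop, grp) / as.vector(table(grp)[sort(unique(grp))])
  out
}
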