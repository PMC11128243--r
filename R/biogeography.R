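#' Collapse per-sample presence to lakes or regions
#'
#' A GVMAG is present in a unit (lake or region) when it is present in at
#' least one of the unit's samples (logical OR). Units with no samples in
#' the presence table are dropped with a warning.
#'
#' @param presence samples x GVMAGs binary matrix (e.g. from
#'   [presence_table()] of the 70%-cutoff abundance table).
#' @param metadata sample metadata mapping samples to lakes/regions.
#' @param unit `"lake"` or `"region"`.
#' @return logical matrix units x GVMAGs.
#' @export
collapse_presence <- function(presence, metadata,
                              unit = c("lake", "region")) {
  unit <- match.arg(unit)
  p <- as.matrix(presence) != 0
  u <- metadata[[unit]][match(rownames(p), metadata$sample_id)]
  if (anyNA(u)) {
    stop("sample(s) missing from metadata: ",
         paste(rownames(p)[is.na(u)], collapse = ", "), call. = FALSE)
  }
  all_units <- unique(metadata[[unit]])
  absent <- setdiff(all_units, u)
  if (length(absent)) {
    warning("unit(s) with no samples dropped: ",
            paste(absent, collapse = ", "))
  }
  out <- rowsum((p) + 0L, u) > 0
  out[unique(u), , drop = FALSE]
}

#' Exact-subset intersection counts (UpSet-style)
#'
#' Assigns every GVMAG detected in at least one unit to the exact subset
#' of units it occurs in, and summarizes per-unit totals, uniqueness
#' fractions (share of a unit's GVMAGs found nowhere else) and
#' directional pairwise sharing percentages (`|u and v| / |u|`, so the
#' two directions of a pair generally differ).
#'
#' @param p logical/binary matrix units x GVMAGs.
#' @param display_threshold pairwise percentages at or below this value
#'   (percent) are flagged `above_display = FALSE` but retained.
#' @return list of class `gvlake_upset` with elements `intersections`
#'   (subset signature, degree, count), `per_unit` (total, unique count,
#'   uniqueness fraction) and `pairwise` (directional shared counts and
#'   percentages).
#' @export
upset_counts <- function(p, display_threshold = 0.1) {
  p <- as.matrix(p) != 0
  if (nrow(p) < 1) stop("upset_counts: need at least one unit",
                        call. = FALSE)
  units <- rownames(p)
  detected <- p[, colSums(p) > 0, drop = FALSE]
  sig <- if (ncol(detected)) {
    apply(detected, 2, function(col) paste(units[col], collapse = "&"))
  } else {
    character(0)
  }
  tab <- table(sig)
  intersections <- data.frame(
    subset = names(tab),
    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    count = as.integer(tab),
    stringsAsFactors = FALSE)
  intersections <- intersections[order(-intersections$count,
                                       intersections$subset), ]
  rownames(intersections) <- NULL

  totals <- rowSums(detected)
  uniq <- vapply(seq_along(units), function(i) {
    sum(detected[i, ] & colSums(detected) == 1)
  }, integer(1))
  per_unit <- data.frame(
    unit = units, total = as.integer(totals), n_unique = uniq,
    uniqueness_fraction = ifelse(totals > 0, uniq / totals, NA_real_),
    stringsAsFactors = FALSE)

  pairs <- expand.grid(unit = units, other = units,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$unit != pairs$other, , drop = FALSE]
  pairs$shared <- mapply(function(u, v) sum(detected[u, ] & detected[v, ]),
                         pairs$unit, pairs$other)
  pairs$shared_pct <- ifelse(totals[pairs$unit] > 0,
                             100 * pairs$shared / totals[pairs$unit],
                             NA_real_)
  pairs$above_display <- !is.na(pairs$shared_pct) &
    pairs$shared_pct > display_threshold
  rownames(pairs) <- NULL

  structure(list(intersections = intersections, per_unit = per_unit,
                 pairwise = pairs),
            class = "gvlake_upset")
}

#' @export
print.gvlake_upset <- function(x, ...) {
  cat("UpSet-style intersection counts over", nrow(x$per_unit),
      "unit(s)\n")
  print(utils::head(x$intersections, 10))
  invisible(x)
}

#' Region distribution of protein clusters
#'
#' Maps every protein cluster to the set of regions of the GVMAGs that
#' contribute members (by default the region of the lake each GVMAG was
#' originally assembled from), then counts region-specific clusters and
#' the polar/temperate split.
#'
#' @param clusters data frame from [read_protein_clusters()].
#' @param gvmag_regions named character vector GVMAG id -> region.
#' @param polar_regions regions counted as polar.
#' @return list of class `gvlake_cluster_dist`: `cluster_regions`
#'   (per-cluster region set, polar specificity), `region_specificity`
#'   (per region: clusters found in it, clusters found only in it, the
#'   specificity fraction), `polar_specific_fraction` (share of all
#'   clusters whose region set is purely polar) and `upset`
#'   ([upset_counts()] over the cluster x region presence matrix).
#' @export
protein_cluster_distribution <- function(clusters, gvmag_regions,
                                         polar_regions = c(
                                           "LIM", "Arctic_subarctic",
                                           "Antarctic")) {
  missing <- setdiff(unique(clusters$gvmag_id), names(gvmag_regions))
  if (length(missing)) {
    stop("cluster member(s) from GVMAG(s) without a region: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  reg <- unname(gvmag_regions[clusters$gvmag_id])
  sets <- lapply(split(reg, clusters$cluster_id), function(r)
    sort(unique(r)))
  cluster_regions <- data.frame(
    cluster_id = names(sets),
    regions = vapply(sets, paste, "", collapse = ","),
    n_regions = lengths(sets),
    polar_specific = vapply(sets, function(r)
      all(r %in% polar_regions), logical(1)),
    stringsAsFactors = FALSE)
  rownames(cluster_regions) <- NULL

  all_regions <- sort(unique(unlist(sets)))
  in_region <- vapply(all_regions, function(r)
    sum(vapply(sets, function(s) r %in% s, logical(1))), integer(1))
  only_region <- vapply(all_regions, function(r)
    sum(vapply(sets, function(s) identical(s, r), logical(1))),
    integer(1))
  region_specificity <- data.frame(
    region = all_regions, n_clusters = in_region,
    n_specific = only_region,
    specificity_fraction = ifelse(in_region > 0,
                                  only_region / in_region, NA_real_),
    stringsAsFactors = FALSE)
  rownames(region_specificity) <- NULL

  pres <- matrix(FALSE, length(all_regions), length(sets),
                 dimnames = list(all_regions, names(sets)))
  for (k in seq_along(sets)) pres[sets[[k]], k] <- TRUE

  structure(list(
    cluster_regions = cluster_regions,
    region_specificity = region_specificity,
    polar_specific_fraction = mean(cluster_regions$polar_specific),
    upset = upset_counts(pres)),
    class = "gvlake_cluster_dist")
}
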