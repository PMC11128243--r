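#' GVMAG read-depth coverage in one sample
#'
#' Length-weighted mean contig depth:
#' `sum(contig_len * contig_avg_depth) / total_length`. Contigs of the
#' GVMAG absent from the sample's depth table contribute zero depth.
#'
#' @param depth a `gvlake_depth` table for one sample.
#' @param catalog a `gvlake_catalog`.
#' @param gvmag_id GVMAG identifier.
#' @return non-negative numeric (reads per base).
#' @export
gvmag_depth <- function(depth, catalog, gvmag_id) {
  coverage_stats(depth, catalog, gvmag_id)$depth
}

#' GVMAG horizontal coverage (breadth) in one sample
#'
#' Fraction of the GVMAG's bases covered by at least one read:
#' `sum(covered_bases) / total_length`, over member contigs.
#'
#' @inheritParams gvmag_depth
#' @return numeric in \[0, 1\].
#' @export
gvmag_breadth <- function(depth, catalog, gvmag_id) {
  coverage_stats(depth, catalog, gvmag_id)$breadth
}

# Depth and breadth for one or all GVMAGs of the catalog in one sample.
coverage_stats <- function(depth, catalog, gvmag_id = NULL) {
  if (!is.null(gvmag_id)) {
    catalog <- catalog[catalog$gvmag_id %in% gvmag_id, , drop = FALSE]
    if (!nrow(catalog)) {
      stop("GVMAG not in catalog (or empty): ", gvmag_id, call. = FALSE)
    }
  }
  idx <- match(catalog$contig_id, depth$contig_id)
  d <- ifelse(is.na(idx), 0, depth$total_avg_depth[idx])
  cb <- ifelse(is.na(idx), 0, depth$covered_bases[idx])
  ids <- unique(catalog$gvmag_id)
  f <- factor(catalog$gvmag_id, levels = ids)
  tot_len <- as.numeric(rowsum(as.numeric(catalog$contig_len), f))
  data.frame(
    gvmag_id = ids,
    depth = as.numeric(rowsum(catalog$contig_len * d, f)) / tot_len,
    breadth = as.numeric(rowsum(as.numeric(cb), f)) / tot_len,
    stringsAsFactors = FALSE)
}

#' Library-size normalization of a coverage value
#'
#' Divides by library size (reads) and multiplies by the scale constant
#' (10^9 by default), yielding coverage per 10^9 library reads.
#'
#' @param depth_value GVMAG read-depth coverage.
#' @param library_size sequencing library size in reads (> 0).
#' @param scale_factor normalization constant.
#' @return normalized coverage.
#' @export
normalize_coverage <- function(depth_value, library_size,
                               scale_factor = 1e9) {
  if (any(library_size <= 0)) stop("library_size must be positive",
                                   call. = FALSE)
  depth_value / library_size * scale_factor
}

#' Build the samples x GVMAGs normalized abundance table
#'
#' For every sample, computes each GVMAG's read-depth coverage and
#' breadth, normalizes coverage by the sample's library size (x
#' `scale_factor`), and zeroes entries whose breadth is below the cutoff.
#' The cutoff comparison is inclusive: breadth >= cutoff counts as
#' present. Two cutoffs are used in practice: 0.25 for distance-based
#' analyses (ordination, UniFrac) and 0.70 for presence/absence and
#' sharing analyses.
#'
#' @param depths named list of `gvlake_depth` tables, one per sample
#'   (names are sample ids, or taken from each table's `sample_id`
#'   attribute).
#' @param catalog a `gvlake_catalog`.
#' @param metadata sample metadata (provides library sizes).
#' @param breadth_cutoff minimum fraction of bases covered, in (0, 1].
#' @param scale_factor normalization constant (see
#'   [normalize_coverage()]).
#' @return numeric matrix samples x GVMAGs with attributes
#'   `breadth_cutoff` and `scale_factor`.
#' @export
build_abundance_table <- function(depths, catalog, metadata,
                                  breadth_cutoff = 0.25,
                                  scale_factor = 1e9) {
  stopifnot(breadth_cutoff > 0, breadth_cutoff <= 1)
  if (is.null(names(depths)) || any(names(depths) == "")) {
    names(depths) <- vapply(depths, attr, "", "sample_id")
  }
  unknown <- setdiff(names(depths), metadata$sample_id)
  if (length(unknown)) {
    stop("sample(s) missing from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- unique(catalog$gvmag_id)
  samples <- names(depths)
  ab <- matrix(0, length(samples), length(ids),
               dimnames = list(samples, ids))
  lib <- stats::setNames(metadata$library_size, metadata$sample_id)
  for (s in samples) {
    st <- coverage_stats(depths[[s]], catalog)
    v <- normalize_coverage(st$depth, lib[[s]], scale_factor)
    v[st$breadth < breadth_cutoff] <- 0
    ab[s, st$gvmag_id] <- v
  }
  attr(ab, "breadth_cutoff") <- breadth_cutoff
  attr(ab, "scale_factor") <- scale_factor
  ab
}

#' Binary presence table from an abundance table
#' @param ab matrix from [build_abundance_table()].
#' @return integer 0/1 matrix of the same shape.
#' @export
presence_table <- function(ab) {
  p <- (ab > 0) + 0L
  attr(p, "breadth_cutoff") <- attr(ab, "breadth_cutoff")
  p
}

#' GVOG7 marker inclusion filter for the species tree
#'
#' Retains GVMAGs carrying at least `min_markers` of the seven GVOG7
#' marker genes, with no marker exceeding `max_copies` copies.
#'
#' @param markers data frame from [read_markers()] (`gvmag_id` + 7
#'   integer columns).
#' @param min_markers minimum number of distinct markers present.
#' @param max_copies maximum copy count allowed for any marker.
#' @return character vector of retained GVMAG ids.
#' @export
marker_filter <- function(markers, min_markers = 4, max_copies = 4) {
  cols <- setdiff(names(markers), "gvmag_id")
  if (length(cols) != 7) {
    stop("marker_filter: expected 7 marker columns, found ", length(cols),
         call. = FALSE)
  }
  m <- as.matrix(markers[cols])
  keep <- rowSums(m >= 1) >= min_markers &
    apply(m, 1, max) <= max_copies
  markers$gvmag_id[keep]
}

#' Restrict a catalog to contigs flagged as viral
#'
#' Drops non-viral contigs from GVMAG membership, recomputes total
#' lengths, and removes GVMAGs falling below the minimum length. Used for
#' the sensitivity re-run that checks whether results are driven by genes
#' on bona fide viral contigs.
#'
#' @param catalog a `gvlake_catalog`.
#' @param viral_flags named logical vector (contig id -> is viral); must
#'   cover all catalog contigs. Flags for unknown contigs are ignored
#'   with a warning.
#' @param min_length minimum GVMAG total length after restriction.
#' @return a restricted `gvlake_catalog` (possibly with zero rows).
#' @export
restrict_to_viral <- function(catalog, viral_flags, min_length = 75000) {
  extra <- setdiff(names(viral_flags), catalog$contig_id)
  if (length(extra)) {
    warning("viral flags for ", length(extra),
            " contig(s) not in catalog; ignored")
  }
  missing <- setdiff(catalog$contig_id, names(viral_flags))
  if (length(missing)) {
    stop("viral flags missing for contig(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  kept <- catalog[viral_flags[catalog$contig_id], , drop = FALSE]
  if (nrow(kept)) {
    tot <- gvmag_lengths(kept)
    kept <- kept[kept$gvmag_id %in% names(tot)[tot >= min_length], ,
                 drop = FALSE]
  }
  if (!nrow(kept)) warning("no GVMAG survives the viral-contig restriction")
  class(kept) <- c("gvlake_catalog", "data.frame")
  kept
}
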