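#' Read a per-contig depth table for one sample
#'
#' Parses the `jgi_summarize_bam_contig_depths` TSV dialect: mandatory
#' columns `contigName`, `contigLen`, `totalAvgDepth`, plus the breadth
#' extension column `coveredBases` (number of bases of the contig covered
#' by at least one read in this sample). Any other columns (per-sample
#' depth/variance pairs emitted by the tool) are ignored.
#'
#' @param path path to the TSV file ('#' comment lines ignored).
#' @param sample_id sample identifier attached to the returned table.
#' @return a `gvlake_depth` data frame with columns `contig_id`,
#'   `contig_len`, `total_avg_depth`, `covered_bases` and attribute
#'   `sample_id`.
#' @export
read_depth_table <- function(path, sample_id) {
  df <- read_tsv_file(path)
  require_columns(df, c("contigName", "contigLen", "totalAvgDepth",
                        "coveredBases"), "depth table")
  out <- data.frame(contig_id = as.character(df$contigName),
                    contig_len = as.integer(df$contigLen),
                    total_avg_depth = as.numeric(df$totalAvgDepth),
                    covered_bases = as.integer(df$coveredBases),
                    stringsAsFactors = FALSE)
  validate_depth_table(out)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("gvlake_depth", "data.frame")
  out
}

validate_depth_table <- function(df) {
  if (any(df$total_avg_depth < 0)) {
    stop("depth table: negative totalAvgDepth for contig(s) ",
         paste(utils::head(df$contig_id[df$total_avg_depth < 0], 5),
               collapse = ", "), call. = FALSE)
  }
  bad <- df$covered_bases < 0 | df$covered_bases > df$contig_len
  if (any(bad)) {
    stop("depth table: coveredBases outside [0, contigLen] for contig(s) ",
         paste(utils::head(df$contig_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  ghost <- df$total_avg_depth == 0 & df$covered_bases > 0
  if (any(ghost)) {
    stop("depth table: zero depth but nonzero coveredBases for contig(s) ",
         paste(utils::head(df$contig_id[ghost], 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_depth_table
#' @param depth a `gvlake_depth` table.
#' @export
write_depth_table <- function(depth, path) {
  df <- data.frame(contigName = depth$contig_id,
                   contigLen = depth$contig_len,
                   totalAvgDepth = depth$total_avg_depth,
                   coveredBases = depth$covered_bases)
  write_tsv_file(df, path)
}

#' Read a newick species tree
#'
#' Single-tree newick; tip labels preserved verbatim. Edges with missing
#' branch lengths are set to 0 with a warning; duplicate tip labels are an
#' error (tips must identify GVMAGs uniquely).
#'
#' @param path path to a newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE),
                   warning = function(w) stop("newick parse error in ", path,
                                              ": ", conditionMessage(w),
                                              call. = FALSE))
  if (is.null(tree)) stop("newick parse error in ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s) in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; treating them as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Read a GVMAG-to-contig membership catalog
#'
#' TSV with columns `gvmag_id`, `contig_id`, `contig_len`. Every GVMAG
#' must reach the minimum assembly length (default 75 000 bp) and contig
#' membership must be a partition (no contig in two GVMAGs).
#'
#' @param path path to the catalog TSV.
#' @param min_length minimum GVMAG total length in bp.
#' @return a `gvlake_catalog` data frame (`gvmag_id`, `contig_id`,
#'   `contig_len`).
#' @export
read_catalog <- function(path, min_length = 75000) {
  df <- read_tsv_file(path)
  require_columns(df, c("gvmag_id", "contig_id", "contig_len"), "catalog")
  new_catalog(df[c("gvmag_id", "contig_id", "contig_len")],
              min_length = min_length)
}

new_catalog <- function(df, min_length = 75000) {
  df$gvmag_id <- as.character(df$gvmag_id)
  df$contig_id <- as.character(df$contig_id)
  df$contig_len <- as.integer(df$contig_len)
  if (anyDuplicated(df$contig_id)) {
    stop("catalog: contig(s) assigned to more than one GVMAG: ",
         paste(unique(df$contig_id[duplicated(df$contig_id)]),
               collapse = ", "), call. = FALSE)
  }
  tot <- gvmag_lengths(df)
  short <- tot[tot < min_length]
  if (length(short)) {
    stop("catalog: GVMAG(s) below the ", min_length, " bp minimum length: ",
         paste(paste0(names(short), " (", short, " bp)"), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("gvlake_catalog", "data.frame")
  df
}

#' Total assembly length per GVMAG
#' @param catalog a `gvlake_catalog`.
#' @return named numeric vector of total lengths (bp).
#' @export
gvmag_lengths <- function(catalog) {
  tapply(catalog$contig_len, catalog$gvmag_id, sum)[
    unique(catalog$gvmag_id)]
}

#' Read GVMAG taxonomy (order/family labels)
#'
#' Missing or empty rank labels are filled with `"undetermined"`, the
#' category used for GVMAGs whose taxonomy could not be confidently
#' assigned.
#'
#' @param path TSV with columns `gvmag_id`, `order`, `family`.
#' @return data frame with those three character columns.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("gvmag_id", "order", "family"), "taxonomy")
  for (col in c("order", "family")) {
    x <- as.character(df[[col]])
    x[is.na(x) | x == ""] <- "undetermined"
    df[[col]] <- x
  }
  df$gvmag_id <- as.character(df$gvmag_id)
  df[c("gvmag_id", "order", "family")]
}

#' Read GVOG7 marker copy counts
#'
#' TSV with `gvmag_id` plus exactly seven marker columns of integer copy
#' counts (the GVOG7 phylogenetic marker set).
#'
#' @param path path to the marker TSV.
#' @return data frame `gvmag_id` + 7 integer columns.
#' @export
read_markers <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, "gvmag_id", "markers")
  marker_cols <- setdiff(names(df), "gvmag_id")
  if (length(marker_cols) != 7) {
    stop("markers: expected exactly 7 marker columns, found ",
         length(marker_cols), call. = FALSE)
  }
  df$gvmag_id <- as.character(df$gvmag_id)
  for (col in marker_cols) df[[col]] <- as.integer(df[[col]])
  df
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `lake`, `region`, `library_size` and an
#' optional `conductivity` (mS/cm). Sample ids must be unique, every
#' sample maps to one lake and every lake to one region.
#'
#' @param path path to the metadata TSV.
#' @return validated data frame.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("sample_id", "lake", "region", "library_size"),
                  "metadata")
  validate_metadata(df)
}

validate_metadata <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  df$lake <- as.character(df$lake)
  df$region <- as.character(df$region)
  df$library_size <- as.integer(df$library_size)
  if (anyDuplicated(df$sample_id)) {
    stop("metadata: duplicate sample_id(s)", call. = FALSE)
  }
  if (any(df$library_size <= 0)) {
    stop("metadata: library_size must be positive", call. = FALSE)
  }
  lake_regions <- tapply(df$region, df$lake, function(r) length(unique(r)))
  if (any(lake_regions > 1)) {
    stop("metadata: lake(s) mapped to more than one region: ",
         paste(names(lake_regions)[lake_regions > 1], collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read eukaryote clade read counts
#' @param path TSV with columns `sample_id`, `clade`, `read_count`.
#' @return data frame with those columns.
#' @export
read_euk_counts <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("sample_id", "clade", "read_count"), "euk counts")
  df$sample_id <- as.character(df$sample_id)
  df$clade <- as.character(df$clade)
  df$read_count <- as.numeric(df$read_count)
  if (any(df$read_count < 0)) stop("euk counts: negative read_count",
                                   call. = FALSE)
  df[c("sample_id", "clade", "read_count")]
}

#' Read protein-cluster membership
#' @param path TSV with columns `cluster_id`, `gvmag_id`, `protein_id`
#'   (MMseqs2-style member-to-representative mapping, long form).
#' @return data frame with those columns.
#' @export
read_protein_clusters <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("cluster_id", "gvmag_id", "protein_id"),
                  "protein clusters")
  for (col in c("cluster_id", "gvmag_id", "protein_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  df[c("cluster_id", "gvmag_id", "protein_id")]
}

#' Read per-contig viral/non-viral flags
#' @param path TSV with columns `contig_id`, `is_viral` (0/1 or
#'   TRUE/FALSE).
#' @return named logical vector keyed by contig id.
#' @export
read_viral_flags <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("contig_id", "is_viral"), "viral flags")
  flags <- as.logical(df$is_viral)
  if (anyNA(flags)) stop("viral flags: is_viral must be boolean",
                         call. = FALSE)
  stats::setNames(flags, as.character(df$contig_id))
}

#' Write / read an abundance table with its provenance header
#'
#' The TSV carries header comments recording the breadth cutoff and the
#' normalization scale so a written table can be re-read without loss.
#'
#' @param ab abundance matrix from [build_abundance_table()].
#' @param path output TSV path.
#' @export
write_abundance_table <- function(ab, path) {
  df <- data.frame(sample_id = rownames(ab), ab, check.names = FALSE)
  write_tsv_file(df, path, comments = c(
    paste0("breadth_cutoff=", attr(ab, "breadth_cutoff")),
    paste0("scale_factor=", format(attr(ab, "scale_factor"),
                                   scientific = FALSE))))
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  kv <- sub("^#\\s*", "", hdr)
  get_num <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit)) as.numeric(sub(".*=", "", hit[1])) else NA_real_
  }
  attr(m, "breadth_cutoff") <- get_num("breadth_cutoff")
  attr(m, "scale_factor") <- get_num("scale_factor")
  m
}
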