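#' Configuration for the synthetic lake-community generator
#'
#' Defines the structure of a simulated survey: regions, lakes and
#' samples; endemic and shared GVMAG pools; contig/genome geometry;
#' coverage depth and breadth distributions for present genomes;
#' cross-mapping noise for absent ones; eukaryote clades with planted
#' clade-family associations; and region-biased protein clusters. The
#' defaults describe a 4-region, 20-lake survey with roughly 490 GVMAGs
#' (the "medium" scale used for integration and recovery analyses).
#'
#' @param n_regions number of regions, up to 4 (`LIM`,
#'   `Arctic_subarctic`, `Temperate`, `Antarctic`, in that order).
#' @param lakes_per_region lakes per region.
#' @param samples_per_lake samples per lake.
#' @param n_endemic_per_lake GVMAGs found only in one lake.
#' @param n_shared_within_region GVMAGs per region present in all of the
#'   region's lakes.
#' @param shared_between data frame `region1`, `region2`, `n`: GVMAGs
#'   present in one lake of each of the two regions. Pairs involving
#'   unavailable regions are dropped.
#' @param contigs_per_gvmag integer range (min, max) of contigs per
#'   GVMAG.
#' @param gvmag_length_range genome length range in bp; the lower bound
#'   must respect the 75 000 bp assembly floor.
#' @param depth_meanlog,depth_sdlog log-normal parameters of a present
#'   GVMAG's per-sample base depth (reads per base).
#' @param breadth_shape1,breadth_shape2 Beta parameters of a present
#'   GVMAG's covered fraction (defaults give mean ~0.91, so present
#'   genomes virtually always clear the 70% cutoff).
#' @param cross_map_prob probability that an absent GVMAG picks up
#'   cross-mapped reads in a sample.
#' @param cross_map_max_breadth upper bound on cross-mapping breadth
#'   (strictly below the 25% presence cutoff by construction).
#' @param library_size_range sequencing library size range (reads).
#' @param n_euk_clades number of eukaryote clades (including planted
#'   ones).
#' @param planted_associations data frame `clade`, `family`, `effect`
#'   (positive effect sizes; ~3 is a strong, reliably recoverable
#'   signal).
#' @param n_protein_clusters number of protein clusters.
#' @param polar_specific_cluster_fraction fraction of clusters whose
#'   members all come from GVMAGs of a single polar region.
#' @param seed integer seed.
#' @return list of class `gvlake_sim_config`.
#' @export
simulation_config <- function(
    n_regions = 4, lakes_per_region = 5, samples_per_lake = 2,
    n_endemic_per_lake = 20, n_shared_within_region = 15,
    shared_between = data.frame(
      region1 = c("LIM", "LIM", "Arctic_subarctic", "Temperate",
                  "Arctic_subarctic"),
      region2 = c("Arctic_subarctic", "Antarctic", "Temperate",
                  "Antarctic", "Antarctic"),
      n = c(12L, 6L, 6L, 2L, 4L),
      stringsAsFactors = FALSE),
    contigs_per_gvmag = c(3L, 10L),
    gvmag_length_range = c(75000, 2126000),
    depth_meanlog = log(5), depth_sdlog = 1,
    breadth_shape1 = 20, breadth_shape2 = 2,
    cross_map_prob = 0.25, cross_map_max_breadth = 0.20,
    library_size_range = c(5e6, 5e7),
    n_euk_clades = 12,
    planted_associations = data.frame(
      clade = c("Haptophyta", "Chlorophyta", "Ciliophora"),
      family = c("IM-12", "IM-01", "AG-01"),
      effect = c(3, 3, 3),
      stringsAsFactors = FALSE),
    n_protein_clusters = 300,
    polar_specific_cluster_fraction = 0.3,
    seed = 1) {
  regions <- c("LIM", "Arctic_subarctic", "Temperate",
               "Antarctic")[seq_len(n_regions)]
  stopifnot(n_regions >= 1, n_regions <= 4, lakes_per_region >= 1,
            samples_per_lake >= 1, n_endemic_per_lake >= 0,
            n_shared_within_region >= 0,
            gvmag_length_range[1] >= 75000,
            gvmag_length_range[2] >= gvmag_length_range[1],
            contigs_per_gvmag[1] >= 1,
            cross_map_max_breadth < 0.25,
            all(planted_associations$effect > 0),
            polar_specific_cluster_fraction >= 0,
            polar_specific_cluster_fraction <= 1)
  shared_between <- shared_between[
    shared_between$region1 %in% regions &
      shared_between$region2 %in% regions, , drop = FALSE]
  total <- n_endemic_per_lake * n_regions * lakes_per_region +
    n_shared_within_region * n_regions + sum(shared_between$n)
  if (total == 0) stop("config generates an empty community",
                       call. = FALSE)
  structure(list(
    regions = regions, lakes_per_region = lakes_per_region,
    samples_per_lake = samples_per_lake,
    n_endemic_per_lake = n_endemic_per_lake,
    n_shared_within_region = n_shared_within_region,
    shared_between = shared_between,
    contigs_per_gvmag = contigs_per_gvmag,
    gvmag_length_range = gvmag_length_range,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    breadth_shape1 = breadth_shape1, breadth_shape2 = breadth_shape2,
    cross_map_prob = cross_map_prob,
    cross_map_max_breadth = cross_map_max_breadth,
    library_size_range = library_size_range,
    n_euk_clades = n_euk_clades,
    planted_associations = planted_associations,
    n_protein_clusters = n_protein_clusters,
    polar_specific_cluster_fraction = polar_specific_cluster_fraction,
    seed = seed), class = "gvlake_sim_config")
}

# Order/family pools used for synthetic taxonomy. Frequencies follow the
# typical dominance ranking in lake surveys (Imitervirales-dominated).
.sim_orders <- data.frame(
  order = c("Imitervirales", "Algavirales", "Pimascovirales",
            "Asfuvirales", "Chitovirales", "Pandoravirales",
            "undetermined"),
  prob = c(0.76, 0.089, 0.06, 0.019, 0.009, 0.015, 0.048),
  stringsAsFactors = FALSE)
.sim_families <- list(
  Imitervirales = c("IM-01", "IM-12", "IM-13", "IM-16"),
  Algavirales = c("AG-01", "AG-02"),
  Pimascovirales = c("PM-01"),
  Asfuvirales = c("AF-01"),
  Chitovirales = c("CH-01"),
  Pandoravirales = c("PV-incertae-sedis"),
  undetermined = c("undetermined"))
.gvog7 <- c("GVOGm0013", "GVOGm0022", "GVOGm0054", "GVOGm0172",
            "GVOGm0461", "GVOGm0760", "GVOGm0890")

#' Simulate a complete synthetic lake survey
#'
#' Generates every input the pipeline consumes — per-sample contig depth
#' tables (with the coveredBases breadth column), GVMAG catalog,
#' taxonomy, GVOG7 marker counts, sample metadata, a coalescent species
#' tree over all GVMAGs, eukaryote clade counts, protein-cluster
#' membership and per-contig viral flags — together with the ground
#' truth used to score recovery. Present GVMAGs draw log-normal depths
#' and high Beta breadths; absent GVMAGs receive occasional low-breadth
#' cross-mapping noise bounded strictly below the 25% cutoff, so the
#' breadth filter does real work. Eukaryote counts of planted clades
#' increase monotonically with the paired virus family's summed
#' normalized abundance. Deterministic given the config seed.
#'
#' @param config a `gvlake_sim_config`.
#' @return list of class `gvlake_simulation` with elements `depth`
#'   (named list of per-sample `gvlake_depth` tables), `catalog`,
#'   `taxonomy`, `markers`, `metadata`, `tree`, `euk_counts`,
#'   `protein_clusters`, `viral_flags`, `truth`, `config`.
#' @export
simulate_community <- function(config = simulation_config()) {
  stopifnot(inherits(config, "gvlake_sim_config"))
  set.seed(config$seed)
  regions <- config$regions

  lakes <- data.frame(
    lake = paste0(rep(regions, each = config$lakes_per_region), "_lake",
                  seq_len(config$lakes_per_region)),
    region = rep(regions, each = config$lakes_per_region),
    stringsAsFactors = FALSE)
  lakes$conductivity <- round(stats::rlnorm(nrow(lakes), 0, 1.5), 3)
  metadata <- data.frame(
    sample_id = paste0(rep(lakes$lake, each = config$samples_per_lake),
                       "_s", seq_len(config$samples_per_lake)),
    lake = rep(lakes$lake, each = config$samples_per_lake),
    region = rep(lakes$region, each = config$samples_per_lake),
    stringsAsFactors = FALSE)
  metadata$library_size <- as.integer(round(stats::runif(
    nrow(metadata), config$library_size_range[1],
    config$library_size_range[2])))
  metadata$conductivity <- lakes$conductivity[
    match(metadata$lake, lakes$lake)]

  # --- GVMAG pools and true lake presence -------------------------------
  origin <- character(0)
  class_of <- character(0)
  pres_rows <- list()
  add_gvmag <- function(lakes_present, origin_lake, cls) {
    origin <<- c(origin, origin_lake)
    class_of <<- c(class_of, cls)
    pres_rows[[length(pres_rows) + 1L]] <<- lakes_present
  }
  for (l in lakes$lake) {
    for (i in seq_len(config$n_endemic_per_lake)) {
      add_gvmag(l, l, "endemic")
    }
  }
  for (r in regions) {
    rl <- lakes$lake[lakes$region == r]
    for (i in seq_len(config$n_shared_within_region)) {
      add_gvmag(rl, sample(rl, 1), "region_shared")
    }
  }
  sb <- config$shared_between
  for (k in seq_len(nrow(sb))) {
    l1 <- lakes$lake[lakes$region == sb$region1[k]]
    l2 <- lakes$lake[lakes$region == sb$region2[k]]
    for (i in seq_len(sb$n[k])) {
      in_lakes <- c(sample(l1, 1), sample(l2, 1))
      add_gvmag(in_lakes, sample(in_lakes, 1), "cross_region")
    }
  }
  n_gv <- length(origin)
  ids <- sprintf("GVMAG_%04d", seq_len(n_gv))
  names(origin) <- names(class_of) <- ids
  lake_presence <- matrix(FALSE, nrow(lakes), n_gv,
                          dimnames = list(lakes$lake, ids))
  for (g in seq_len(n_gv)) lake_presence[pres_rows[[g]], g] <- TRUE
  sample_presence <- lake_presence[metadata$lake, , drop = FALSE]
  rownames(sample_presence) <- metadata$sample_id

  # --- contig geometry ---------------------------------------------------
  tot_len <- round(exp(stats::runif(
    n_gv, log(config$gvmag_length_range[1]),
    log(config$gvmag_length_range[2]))))
  k_contigs <- sample(seq(config$contigs_per_gvmag[1],
                          config$contigs_per_gvmag[2]),
                      n_gv, replace = TRUE)
  catalog_rows <- vector("list", n_gv)
  for (g in seq_len(n_gv)) {
    k <- k_contigs[g]
    w <- stats::rgamma(k, 2)
    len <- pmax(1500L, as.integer(round(tot_len[g] * w / sum(w))))
    len[which.max(len)] <- len[which.max(len)] +
      (tot_len[g] - sum(len))
    catalog_rows[[g]] <- data.frame(
      gvmag_id = ids[g],
      contig_id = sprintf("%s_c%02d", ids[g], seq_len(k)),
      contig_len = len, stringsAsFactors = FALSE)
  }
  catalog <- new_catalog(do.call(rbind, catalog_rows))
  contig_gv <- factor(catalog$gvmag_id, levels = ids)
  gv_row_idx <- split(seq_len(nrow(catalog)), contig_gv)
  gv_total <- as.numeric(rowsum(as.numeric(catalog$contig_len),
                                contig_gv))

  # --- taxonomy, markers, tree ------------------------------------------
  ord <- sample(.sim_orders$order, n_gv, replace = TRUE,
                prob = .sim_orders$prob)
  fam <- vapply(ord, function(o) sample(.sim_families[[o]], 1), "")
  taxonomy <- data.frame(gvmag_id = ids, order = ord, family = unname(fam),
                         stringsAsFactors = FALSE)
  markers <- as.data.frame(matrix(0L, n_gv, 7,
                                  dimnames = list(NULL, .gvog7)))
  fail <- stats::runif(n_gv) < 0.08
  for (g in seq_len(n_gv)) {
    if (fail[g] && stats::runif(1) < 0.5) {
      idx <- sample(7, 3)
      markers[g, idx] <- sample(1:2, 3, replace = TRUE)
    } else {
      idx <- sample(7, sample(4:7, 1))
      markers[g, idx] <- sample(1:2, length(idx), replace = TRUE)
      if (fail[g]) markers[g, idx[1]] <- 5L
    }
  }
  markers <- cbind(data.frame(gvmag_id = ids, stringsAsFactors = FALSE),
                   markers)
  tree <- ape::rcoal(n_gv, tip.label = ids)

  # --- per-sample depth tables ------------------------------------------
  depth <- vector("list", nrow(metadata))
  names(depth) <- metadata$sample_id
  fam_levels <- sort(unique(taxonomy$family))
  fam_abund <- matrix(0, nrow(metadata), length(fam_levels),
                      dimnames = list(metadata$sample_id, fam_levels))
  for (s in seq_len(nrow(metadata))) {
    pres <- sample_presence[s, ]
    d <- numeric(nrow(catalog))
    cb <- numeric(nrow(catalog))
    for (g in which(pres)) {
      rows <- gv_row_idx[[g]]
      base <- stats::rlnorm(1, config$depth_meanlog, config$depth_sdlog)
      frac <- stats::rbeta(1, config$breadth_shape1,
                           config$breadth_shape2)
      d[rows] <- base * stats::rlnorm(length(rows), 0, 0.2)
      cb[rows] <- pmin(catalog$contig_len[rows],
                       pmax(1, round(frac * catalog$contig_len[rows])))
    }
    for (g in which(!pres)) {
      if (stats::runif(1) >= config$cross_map_prob) next
      rows <- gv_row_idx[[g]]
      j <- rows[sample.int(length(rows), 1)]
      u <- stats::runif(1, 0.01, config$cross_map_max_breadth)
      cov <- min(catalog$contig_len[j], max(1, floor(u * gv_total[g])))
      cb[j] <- cov
      d[j] <- stats::rlnorm(1, log(0.05), 0.5)
    }
    tab <- data.frame(contig_id = catalog$contig_id,
                      contig_len = catalog$contig_len,
                      total_avg_depth = round(d, 4),
                      covered_bases = as.integer(cb),
                      stringsAsFactors = FALSE)
    # invariants: zero depth <=> zero covered bases
    tab$covered_bases[tab$total_avg_depth == 0] <- 0L
    attr(tab, "sample_id") <- metadata$sample_id[s]
    class(tab) <- c("gvlake_depth", "data.frame")
    depth[[s]] <- tab

    gv_depth <- as.numeric(rowsum(catalog$contig_len *
                                    tab$total_avg_depth, contig_gv)) /
      gv_total
    gv_breadth <- as.numeric(rowsum(as.numeric(tab$covered_bases),
                                    contig_gv)) / gv_total
    norm <- gv_depth / metadata$library_size[s] * 1e9
    norm[gv_breadth < 0.25] <- 0
    fam_abund[s, ] <- rowsum(norm, factor(taxonomy$family,
                                          levels = fam_levels))[, 1]
  }

  # --- eukaryote clade counts -------------------------------------------
  planted <- config$planted_associations
  filler_pool <- c("Fungi", "Dinoflagellata", "Cryptophyta",
                   "Chrysophyceae", "Bacillariophyta", "Cercozoa",
                   "Katablepharidophyta", "Telonemia",
                   "Choanoflagellata", "Rhodophyta", "Euglenozoa",
                   "Apusozoa", "Amoebozoa", "Tubulinea")
  n_filler <- max(0, config$n_euk_clades - nrow(planted))
  clades <- c(planted$clade, utils::head(filler_pool, n_filler))
  euk_rows <- list()
  ns <- nrow(metadata)
  for (cl in clades) {
    hit <- match(cl, planted$clade)
    if (!is.na(hit) && planted$family[hit] %in% colnames(fam_abund)) {
      x <- log1p(fam_abund[, planted$family[hit]])
      z <- if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, ns)
      counts <- pmax(0, round(200 + 60 * planted$effect[hit] * z +
                                stats::rnorm(ns, 0, 15)))
    } else {
      counts <- stats::rnbinom(ns, size = 2, mu = 150)
    }
    euk_rows[[cl]] <- data.frame(sample_id = metadata$sample_id,
                                 clade = cl, read_count = counts,
                                 stringsAsFactors = FALSE)
  }
  euk_counts <- do.call(rbind, euk_rows)
  rownames(euk_counts) <- NULL

  # --- protein clusters --------------------------------------------------
  origin_region <- stats::setNames(
    lakes$region[match(origin, lakes$lake)], ids)
  polar <- intersect(c("LIM", "Arctic_subarctic", "Antarctic"), regions)
  has_temperate <- "Temperate" %in% regions
  n_polar_specific <- round(config$polar_specific_cluster_fraction *
                              config$n_protein_clusters)
  pc_rows <- list()
  polar_specific_ids <- character(0)
  for (k in seq_len(config$n_protein_clusters)) {
    cid <- sprintf("PC%05d", k)
    m <- sample(2:8, 1)
    if (k <= n_polar_specific && length(polar)) {
      r <- sample(polar, 1)
      pool <- ids[origin_region == r]
      members <- sample(pool, min(m, length(pool)))
      polar_specific_ids <- c(polar_specific_ids, cid)
    } else if (has_temperate) {
      temp_pool <- ids[origin_region == "Temperate"]
      other_pool <- ids[origin_region != "Temperate"]
      members <- unique(c(sample(temp_pool, 1),
                          sample(ids, max(1, m - 1))))
    } else {
      members <- sample(ids, min(m, length(ids)))
    }
    pc_rows[[k]] <- data.frame(
      cluster_id = cid, gvmag_id = members,
      protein_id = paste0(members, "_p",
                          sample.int(50, length(members),
                                     replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  protein_clusters <- do.call(rbind, pc_rows)
  rownames(protein_clusters) <- NULL

  viral_flags <- stats::setNames(
    stats::runif(nrow(catalog)) < 0.95, catalog$contig_id)

  uniq <- colSums(lake_presence) == 1
  lake_uniqueness <- vapply(lakes$lake, function(l) {
    inl <- lake_presence[l, ]
    if (!any(inl)) return(NA_real_)
    sum(inl & uniq) / sum(inl)
  }, numeric(1))

  structure(list(
    depth = depth, catalog = catalog, taxonomy = taxonomy,
    markers = markers, metadata = metadata, tree = tree,
    euk_counts = euk_counts, protein_clusters = protein_clusters,
    viral_flags = viral_flags,
    truth = list(origin_lake = origin, origin_region = origin_region,
                 origin_class = class_of,
                 lake_presence = lake_presence,
                 sample_presence = sample_presence,
                 planted = planted,
                 polar_specific_clusters = polar_specific_ids,
                 lake_uniqueness = lake_uniqueness),
    config = config), class = "gvlake_simulation")
}

#' Preset simulation scales
#'
#' `tiny` (~16 GVMAGs, 2 regions) for unit tests, `small` (~90 GVMAGs, 4
#' regions), `medium` (~490 GVMAGs, 20 lakes, 40 samples) for
#' integration and recovery analyses.
#'
#' @param size one of `"tiny"`, `"small"`, `"medium"`.
#' @param seed integer seed.
#' @return a `gvlake_sim_config`.
#' @export
preset_config <- function(size = c("tiny", "small", "medium"), seed = 1) {
  size <- match.arg(size)
  switch(size,
    tiny = simulation_config(
      n_regions = 2, lakes_per_region = 1, samples_per_lake = 2,
      n_endemic_per_lake = 6, n_shared_within_region = 0,
      shared_between = data.frame(region1 = "LIM",
                                  region2 = "Arctic_subarctic", n = 2L,
                                  stringsAsFactors = FALSE),
      contigs_per_gvmag = c(2L, 5L),
      gvmag_length_range = c(75000, 300000),
      n_euk_clades = 4,
      planted_associations = data.frame(
        clade = "Haptophyta", family = "IM-12", effect = 3,
        stringsAsFactors = FALSE),
      n_protein_clusters = 20, seed = seed),
    small = simulation_config(
      lakes_per_region = 2, n_endemic_per_lake = 8,
      n_shared_within_region = 4,
      shared_between = data.frame(
        region1 = c("LIM", "Temperate"),
        region2 = c("Arctic_subarctic", "Antarctic"),
        n = c(3L, 2L), stringsAsFactors = FALSE),
      contigs_per_gvmag = c(2L, 6L),
      gvmag_length_range = c(75000, 500000),
      n_protein_clusters = 60, seed = seed),
    medium = simulation_config(seed = seed))
}

#' Write a simulated community as a self-contained fixture directory
#'
#' Emits every table in the pipeline's input formats (one depth TSV per
#' sample, catalog/taxonomy/markers/metadata/eukaryote/protein-cluster/
#' viral-flag TSVs, a newick species tree), the ground truth, and a
#' MANIFEST recording the configuration and seed. Identical seeds give
#' byte-identical directories.
#'
#' @param size preset scale passed to [preset_config()], or a
#'   `gvlake_sim_config` for full control.
#' @param out_dir output directory (created; must be writable).
#' @param seed integer seed (ignored when `size` is a config).
#' @return invisibly, the simulation object that was written.
#' @export
emit_fixture <- function(size = "tiny", out_dir, seed = 1) {
  config <- if (inherits(size, "gvlake_sim_config")) size else
    preset_config(size, seed = seed)
  sim <- simulate_community(config)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  for (s in names(sim$depth)) {
    write_depth_table(sim$depth[[s]],
                      file.path(out_dir, paste0("depth_", s, ".tsv")))
  }
  write_tsv_file(sim$catalog, file.path(out_dir, "catalog.tsv"))
  write_tsv_file(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  write_tsv_file(sim$markers, file.path(out_dir, "markers.tsv"))
  write_tsv_file(sim$metadata, file.path(out_dir, "metadata.tsv"))
  write_tsv_file(sim$euk_counts, file.path(out_dir, "euk_counts.tsv"))
  write_tsv_file(sim$protein_clusters,
                 file.path(out_dir, "protein_clusters.tsv"))
  write_tsv_file(data.frame(contig_id = names(sim$viral_flags),
                            is_viral = as.integer(sim$viral_flags)),
                 file.path(out_dir, "viral_flags.tsv"))
  ape::write.tree(sim$tree, file.path(out_dir, "species_tree.nwk"))
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_tsv_file(data.frame(gvmag_id = names(sim$truth$origin_lake),
                            origin_lake = sim$truth$origin_lake,
                            origin_region = sim$truth$origin_region,
                            origin_class = sim$truth$origin_class),
                 file.path(truth_dir, "origin.tsv"))
  write_tsv_file(data.frame(lake = rownames(sim$truth$lake_presence),
                            sim$truth$lake_presence + 0L,
                            check.names = FALSE),
                 file.path(truth_dir, "lake_presence.tsv"))
  write_tsv_file(sim$truth$planted,
                 file.path(truth_dir, "planted_associations.tsv"))
  writeLines(sim$truth$polar_specific_clusters,
             file.path(truth_dir, "polar_specific_clusters.txt"))
  manifest <- unclass(config)
  manifest$shared_between <- as.list(manifest$shared_between)
  manifest$planted_associations <- as.list(
    manifest$planted_associations)
  yaml::write_yaml(manifest, file.path(out_dir, "MANIFEST.yaml"))
  invisible(sim)
}

#' Load a fixture directory back into memory
#'
#' Reads every table written by [emit_fixture()] through the package's
#' own readers.
#'
#' @param dir fixture directory.
#' @return list with the same table elements as
#'   [simulate_community()] (without `truth`/`config`).
#' @export
read_fixture <- function(dir) {
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  depth <- lapply(stats::setNames(nm = metadata$sample_id), function(s)
    read_depth_table(file.path(dir, paste0("depth_", s, ".tsv")), s))
  list(depth = depth,
       catalog = read_catalog(file.path(dir, "catalog.tsv")),
       taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
       markers = read_markers(file.path(dir, "markers.tsv")),
       metadata = metadata,
       tree = read_newick(file.path(dir, "species_tree.nwk")),
       euk_counts = read_euk_counts(file.path(dir, "euk_counts.tsv")),
       protein_clusters = read_protein_clusters(
         file.path(dir, "protein_clusters.tsv")),
       viral_flags = read_viral_flags(file.path(dir, "viral_flags.tsv")))
}
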