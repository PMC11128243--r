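# Independent oracles used across tests. Each re-derives the quantity by
# a different route than the package implementation.

# Unweighted UniFrac by explicit branch enumeration: descendant tip sets
# come from ape::extract.clade, not from the package's incidence matrix.
unifrac_brute <- function(tree, tips_a, tips_b) {
  ntip <- length(tree$tip.label)
  desc <- lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
  })
  u <- union(tips_a, tips_b)
  num <- 0
  den <- 0
  for (e in seq_along(desc)) {
    in_u <- intersect(desc[[e]], u)
    if (!length(in_u)) next
    den <- den + tree$edge.length[e]
    only_a <- all(in_u %in% tips_a) && !any(in_u %in% tips_b)
    only_b <- all(in_u %in% tips_b) && !any(in_u %in% tips_a)
    if (only_a || only_b) num <- num + tree$edge.length[e]
  }
  num / den
}

# Naive WPGMA producing the cophenetic matrix, merging the closest pair
# with lexicographic tie-break and averaging cluster distances.
wpgma_brute_cophenetic <- function(m) {
  labs <- rownames(m)
  clusters <- as.list(labs)
  names(clusters) <- labs
  cd <- m
  coph <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  while (length(clusters) > 1) {
    cn <- names(clusters)
    best <- NULL
    for (i in seq_along(cn)[-length(cn)]) {
      for (j in seq(i + 1, length(cn))) {
        cand <- sort(c(cn[i], cn[j]))
        if (is.null(best) || cd[cn[i], cn[j]] < best$d - 1e-15 ||
            (abs(cd[cn[i], cn[j]] - best$d) <= 1e-15 &&
             paste(cand, collapse = "|") <
             paste(best$pair, collapse = "|"))) {
          best <- list(pair = cand, d = cd[cn[i], cn[j]])
        }
      }
    }
    a <- best$pair[1]; b <- best$pair[2]
    coph[clusters[[a]], clusters[[b]]] <- best$d
    coph[clusters[[b]], clusters[[a]]] <- best$d
    new_name <- paste0("(", a, ",", b, ")")
    others <- setdiff(names(clusters), c(a, b))
    new_d <- stats::setNames(
      (cd[a, others, drop = TRUE] + cd[b, others, drop = TRUE]) / 2,
      others)
    clusters[[new_name]] <- c(clusters[[a]], clusters[[b]])
    clusters[[a]] <- NULL
    clusters[[b]] <- NULL
    cd2 <- matrix(0, length(clusters), length(clusters),
                  dimnames = list(names(clusters), names(clusters)))
    keep <- intersect(others, rownames(cd))
    cd2[keep, keep] <- cd[keep, keep]
    cd2[new_name, others] <- new_d
    cd2[others, new_name] <- new_d
    cd <- cd2
  }
  coph
}

# Exact-subset counts by exhaustive enumeration over all non-empty unit
# subsets.
upset_brute <- function(p) {
  p <- as.matrix(p) != 0
  units <- rownames(p)
  out <- list()
  for (size in seq_along(units)) {
    combs <- utils::combn(units, size, simplify = FALSE)
    for (s in combs) {
      inside <- colSums(p[s, , drop = FALSE]) == length(s)
      outside <- colSums(p[setdiff(units, s), , drop = FALSE]) == 0
      if (length(setdiff(units, s)) == 0) outside <- rep(TRUE, ncol(p))
      n <- sum(inside & outside)
      if (n > 0) out[[paste(s, collapse = "&")]] <- n
    }
  }
  out
}

# Small random abundance table + exchangeable labels for null studies.
random_null_community <- function(n_samples = 24, n_taxa = 30,
                                  n_groups = 4) {
  x <- matrix(stats::rlnorm(n_samples * n_taxa, 0, 1), n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  groups <- sample(rep(paste0("g", seq_len(n_groups)),
                       length.out = n_samples))
  list(x = x, groups = stats::setNames(groups, rownames(x)))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_community(
      preset_config("tiny", seed = 42))
    cache
  }
})

medium_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_community(
      preset_config("medium", seed = 1))
    cache
  }
})
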