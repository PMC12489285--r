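# Independent oracles used across tests. These deliberately share no code
# with the package implementations they check.

# Literal column-walk re-statement of the each-gap distance definition.
naive_eachgap <- function(a, b, count_ends = FALSE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  L <- length(ca)
  lo <- 1L; hi <- L
  if (!count_ends) {
    fa <- 0L; la <- 0L; fb <- 0L; lb <- 0L
    for (i in 1:L) {
      if (ca[i] != "-") { if (fa == 0L) fa <- i; la <- i }
      if (cb[i] != "-") { if (fb == 0L) fb <- i; lb <- i }
    }
    lo <- max(fa, fb); hi <- min(la, lb)
  }
  nd <- 0L; nc <- 0L
  i <- lo
  while (i <= hi && hi > 0 && lo > 0) {
    skip <- (ca[i] == "-" && cb[i] == "-") || ca[i] == "N" || cb[i] == "N"
    if (!skip) {
      nc <- nc + 1L
      if (ca[i] != cb[i]) nd <- nd + 1L
    }
    i <- i + 1L
  }
  list(distance = if (nc == 0) 0 else nd / nc, n_diff = nd, n_compared = nc)
}

# Random gapped pair of equal width for distance property tests.
random_aligned_pair <- function(max_cols = 200) {
  L <- sample(2:max_cols, 1)
  alpha <- c("A", "C", "G", "T", "N", "-")
  probs <- c(rep(0.21, 4), 0.06, 0.10)
  a <- sample(alpha, L, replace = TRUE, prob = probs)
  b <- sample(alpha, L, replace = TRUE, prob = probs)
  # guarantee at least one residue each
  if (!any(a != "-")) a[sample(L, 1)] <- "A"
  if (!any(b != "-")) b[sample(L, 1)] <- "C"
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# Random symmetric distance matrix with continuous (tie-free) entries.
random_distance_matrix <- function(n, scale = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2) * scale
  m <- m + t(m)
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  m
}

# Partition equality up to cluster relabelling.
same_partition <- function(assign_a, assign_b) {
  ids <- names(assign_a)
  a <- split(ids, assign_a[ids])
  b <- split(ids, assign_b[ids])
  setequal(lapply(a, sort), lapply(b, sort))
}

# Agglomerative partition via stats::hclust (independent cross-check; valid
# on tie-free matrices where the merge order is unambiguous).
hclust_partition <- function(mat, threshold, linkage) {
  method <- switch(linkage, nearest = "single", average = "average",
                   furthest = "complete")
  hc <- stats::hclust(stats::as.dist(mat), method = method)
  grp <- stats::cutree(hc, h = threshold)
  grp[rownames(mat)]
}

# Connected components of the graph {distance <= t} via igraph.
component_partition <- function(mat, threshold) {
  adj <- (mat <= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership[rownames(mat)]
}

# Connected components of the {edit distance <= d} graph via utils::adist
# and igraph (swarm oracle).
adist_component_partition <- function(seqs, d) {
  dm <- utils::adist(seqs)
  dimnames(dm) <- list(names(seqs), names(seqs))
  component_partition(dm, d)
}

# Small strain-only community used by several simulation-driven tests.
strain_community <- function(seed, copies = c(6L, 11L), ...) {
  simulate_community(community_spec(n_species = 1, strains_per_species = 1,
                                    copies_per_strain = copies, seed = seed,
                                    ...))
}
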