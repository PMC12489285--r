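#' OTU clustering at a distance threshold
#'
#' Agglomerative clustering over a precomputed distance matrix: clusters are
#' merged while the inter-cluster linkage distance is at or below the
#' threshold. `nearest` linkage uses the minimum pairwise distance between
#' clusters, `furthest` the maximum, `average` the arithmetic mean over all
#' cross pairs. Merge order is deterministic: lowest linkage distance first,
#' ties broken by the lexicographically smallest pair of cluster ids (a
#' cluster is identified by its smallest member id).
#'
#' @param mat symmetric distance matrix with ids as dimnames.
#' @param threshold distance threshold in `[0, 1]`.
#' @param linkage one of `"average"` (default), `"nearest"`, `"furthest"`.
#' @return an `otu_partition`: list with `threshold`, `linkage`,
#'   `assignment` (named integer vector, cluster indices contiguous from 0 in
#'   order of first appearance), and `n_clusters`.
#' @export
cluster_at_threshold <- function(mat, threshold,
                                 linkage = c("average", "nearest", "furthest")) {
  linkage <- match.arg(linkage)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  ids <- rownames(mat)
  if (is.null(ids)) stop("distance matrix must have ids as dimnames", call. = FALSE)
  link_fun <- switch(linkage, nearest = min, furthest = max, average = mean)
  members <- as.list(seq_along(ids))     # clusters as index vectors
  keys <- ids                            # smallest member id per cluster
  eps <- 1e-12
  while (length(members) > 1) {
    nc <- length(members)
    best <- NULL
    for (p in seq_len(nc - 1)) {
      for (q in (p + 1):nc) {
        d <- link_fun(mat[members[[p]], members[[q]]])
        k <- sort(c(keys[p], keys[q]))
        if (is.null(best) || d < best$d - eps ||
            (abs(d - best$d) <= eps &&
             (k[1] < best$k[1] || (k[1] == best$k[1] && k[2] < best$k[2])))) {
          best <- list(d = d, p = p, q = q, k = k)
        }
      }
    }
    if (best$d > threshold) break
    members[[best$p]] <- c(members[[best$p]], members[[best$q]])
    keys[best$p] <- min(keys[best$p], keys[best$q])
    members[[best$q]] <- NULL
    keys <- keys[-best$q]
  }
  assignment <- integer(length(ids))
  names(assignment) <- ids
  # contiguous indices from 0, ordered by first appearance in input order
  first <- vapply(members, min, integer(1))
  ord <- order(first)
  for (ci in seq_along(ord))
    assignment[members[[ord[ci]]]] <- ci - 1L
  structure(list(threshold = threshold, linkage = linkage,
                 assignment = assignment,
                 n_clusters = length(members)),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("<otu_partition> %d cluster(s) at threshold %g (%s linkage)\n",
              x$n_clusters, x$threshold, x$linkage))
  invisible(x)
}

#' Cluster-count sweep over a threshold grid
#'
#' Number of OTUs at each threshold of an ascending grid (the data behind
#' OTU-count-versus-threshold heatmaps). Counts are non-increasing in the
#' threshold.
#'
#' @param mat symmetric distance matrix with ids as dimnames.
#' @param grid ascending numeric thresholds (default 0 to 0.25 by 0.01, the
#'   percent-integer grid used for strain-level reports).
#' @param linkage passed to [cluster_at_threshold()].
#' @return tibble with `threshold`, `linkage`, `n_clusters`.
#' @export
threshold_sweep <- function(mat, grid = seq(0, 0.25, by = 0.01),
                            linkage = c("average", "nearest", "furthest")) {
  linkage <- match.arg(linkage)
  if (length(grid) == 0) stop("threshold grid is empty", call. = FALSE)
  if (is.unsorted(grid)) stop("grid must be ascending", call. = FALSE)
  n <- vapply(grid, function(t)
    cluster_at_threshold(mat, t, linkage)$n_clusters, integer(1))
  tibble::tibble(threshold = grid, linkage = linkage, n_clusters = n)
}

#' Minimal single-cluster threshold
#'
#' Smallest grid threshold at which all sequences fall into one OTU (the
#' strain-specific "single cluster" thresholds reported per locus). The last
#' grid value is forced to 1.0 so a result always exists.
#'
#' @inheritParams threshold_sweep
#' @return the threshold (numeric scalar).
#' @export
single_cluster_threshold <- function(mat, linkage = c("average", "nearest",
                                                      "furthest"),
                                     grid = seq(0, 0.25, by = 0.01)) {
  linkage <- match.arg(linkage)
  if (length(grid) == 0) stop("threshold grid is empty", call. = FALSE)
  if (is.unsorted(grid)) stop("grid must be ascending", call. = FALSE)
  if (max(grid) < 1) grid <- c(grid, 1.0)
  for (t in grid) {
    if (cluster_at_threshold(mat, t, linkage)$n_clusters == 1L) return(t)
  }
  1.0
}
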