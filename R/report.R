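#' Per-copy locus sequences of a simulated strain
#'
#' Extracts one locus (or the Krüger barcode window) from every rDNA copy of a
#' strain, using the per-copy locus boundaries tracked by the generator.
#'
#' @param truth a `synthetic_truth`.
#' @param strain strain id.
#' @param locus locus name, or `"KRUGER"` for the barcode window.
#' @return named character vector of ungapped locus sequences (one per copy).
#' @export
copy_locus_seqs <- function(truth, strain, locus) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cp <- truth$copies[truth$copies$strain == strain, ]
  if (nrow(cp) == 0) stop("unknown strain: ", strain, call. = FALSE)
  out <- vapply(seq_len(nrow(cp)), function(i) {
    map <- cp$map[[i]]
    win <- if (locus == "KRUGER") krueger_window(map)
           else map[map$locus == locus, ]
    if (nrow(win) == 0) stop("unknown locus: ", locus, call. = FALSE)
    substr(cp$sequence[i], win$start + 1L, win$end)
  }, character(1))
  names(out) <- cp$copy_id
  out
}

#' Intragenomic distance report per strain and locus
#'
#' For every strain and locus (plus the Krüger window), the minimum, mean and
#' maximum pairwise distance among the strain's rDNA copies, computed with the
#' built-in pairwise alignment mode and the each-gap distance. This is the
#' tabular analogue of per-locus intragenomic variation panels.
#'
#' @param truth a `synthetic_truth`.
#' @param loci loci to report (default the five operon loci plus `KRUGER`).
#' @param scores alignment scores for the pairwise mode.
#' @return tibble with `strain`, `locus`, `n_copies`, `min`, `mean`, `max`
#'   (fractions) and `mean_pct`/`max_pct` (rounded percentages).
#' @export
intragenomic_locus_summary <- function(truth,
                                       loci = c(LOCUS_ORDER, "KRUGER"),
                                       scores = default_scores()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- list()
  for (st in unique(truth$copies$strain)) {
    for (lc in loci) {
      seqs <- copy_locus_seqs(truth, st, lc)
      if (length(seqs) < 2) {
        out[[length(out) + 1]] <- tibble::tibble(
          strain = st, locus = lc, n_copies = length(seqs),
          min = NA_real_, mean = NA_real_, max = NA_real_)
        next
      }
      D <- pairwise_distance_matrix(seqs, scores = scores)
      d <- D[upper.tri(D)]
      out[[length(out) + 1]] <- tibble::tibble(
        strain = st, locus = lc, n_copies = length(seqs),
        min = min(d), mean = mean(d), max = max(d))
    }
  }
  res <- dplyr::bind_rows(out)
  res$mean_pct <- percent(res$mean)
  res$max_pct <- percent(res$max)
  res
}

#' OTU threshold report per strain and locus
#'
#' Threshold sweeps (cluster counts on an ascending grid) and minimal
#' single-cluster thresholds for each strain x locus, under all three
#' linkages.
#'
#' @param truth a `synthetic_truth`.
#' @param loci loci to report.
#' @param grid ascending threshold grid.
#' @param linkages linkage criteria to include.
#' @param scores alignment scores for the pairwise mode.
#' @return list with `sweep` (tibble `strain`, `locus`, `linkage`,
#'   `threshold`, `n_clusters`) and `single_cluster` (tibble `strain`,
#'   `locus`, `linkage`, `threshold`).
#' @export
otu_threshold_report <- function(truth, loci = c(LOCUS_ORDER, "KRUGER"),
                                 grid = seq(0, 0.25, by = 0.01),
                                 linkages = c("nearest", "average", "furthest"),
                                 scores = default_scores()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sweeps <- list(); singles <- list()
  for (st in unique(truth$copies$strain)) {
    for (lc in loci) {
      seqs <- copy_locus_seqs(truth, st, lc)
      if (length(seqs) < 2) next
      D <- pairwise_distance_matrix(seqs, scores = scores)
      for (lk in linkages) {
        sw <- threshold_sweep(D, grid, lk)
        sw$strain <- st; sw$locus <- lc
        sweeps[[length(sweeps) + 1]] <- sw
        singles[[length(singles) + 1]] <- tibble::tibble(
          strain = st, locus = lc, linkage = lk,
          threshold = single_cluster_threshold(D, lk, grid))
      }
    }
  }
  list(sweep = dplyr::bind_rows(sweeps)[, c("strain", "locus", "linkage",
                                            "threshold", "n_clusters")],
       single_cluster = dplyr::bind_rows(singles))
}

#' Barcode-gap report over the companion genes
#'
#' Gap tables and indicative conspecific thresholds for each protein-coding
#' gene of a simulated community (and optionally any extra named sequence
#' sets). Gene sequences are generated without indels, so they form a
#' gap-free alignment directly.
#'
#' @param truth a `synthetic_truth`.
#' @param q quantile for [conspecific_threshold()].
#' @return list with `gap` (tibble over genes x species) and `thresholds`
#'   (tibble `gene`, `threshold`, `conspecific_mean`, `heterospecific_mean`).
#' @export
barcode_gap_report <- function(truth, q = 0.95) {
  stopifnot(inherits(truth, "synthetic_truth"))
  gaps <- list(); ths <- list()
  for (g in unique(truth$genes$gene)) {
    gg <- truth$genes[truth$genes$gene == g, ]
    seqs <- stats::setNames(gg$sequence, gg$id)
    labels <- stats::setNames(gg$species, gg$id)
    D <- distance_matrix(aligned_set(seqs, labels = labels))
    gt <- gap_table(D, labels)
    gt$gene <- g
    gaps[[length(gaps) + 1]] <- gt
    parts <- partition_distances(D, labels)
    ths[[length(ths) + 1]] <- tibble::tibble(
      gene = g, threshold = conspecific_threshold(D, labels, q = q),
      conspecific_mean = mean(parts$conspecific),
      heterospecific_mean = mean(parts$heterospecific))
  }
  list(gap = dplyr::bind_rows(gaps)[, c("gene", "species", "n", "max_intra",
                                        "min_inter", "gap")],
       thresholds = dplyr::bind_rows(ths))
}
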