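#' Split pairwise distances into conspecific and heterospecific sets
#'
#' Every unordered pair of sequences is assigned to exactly one of the two
#' lists according to the species labels.
#'
#' @param mat symmetric distance matrix with ids as dimnames.
#' @param species species label per id (named by id, or in matrix order).
#' @return list with numeric vectors `conspecific` and `heterospecific`.
#' @export
partition_distances <- function(mat, species) {
  ids <- rownames(mat)
  species <- resolve_labels(species, ids)
  same <- outer(species, species, "==")
  ut <- upper.tri(mat)
  list(conspecific = mat[ut & same], heterospecific = mat[ut & !same])
}

#' Barcode-gap table
#'
#' One record per species with the maximum conspecific (intraspecific)
#' pairwise distance and the minimum distance from any member to its nearest
#' non-conspecific sequence (spider's nearest-non-conspecific statistic). The
#' species has a barcode gap when `min_inter > max_intra`. Species represented
#' by a single sequence have no defined `max_intra` (NA) and no gap verdict,
#' but still contribute to other species' `min_inter`.
#'
#' @inheritParams partition_distances
#' @return tibble with `species`, `n`, `max_intra`, `min_inter`, `gap`.
#' @export
gap_table <- function(mat, species) {
  ids <- rownames(mat)
  species <- resolve_labels(species, ids)
  if (length(unique(species)) < 2)
    stop("barcode-gap analysis needs at least 2 species", call. = FALSE)
  out <- lapply(unique(species), function(sp) {
    mem <- which(species == sp)
    oth <- which(species != sp)
    max_intra <- if (length(mem) >= 2)
      max(mat[mem, mem][upper.tri(diag(length(mem)))]) else NA_real_
    min_inter <- min(mat[mem, oth, drop = FALSE])
    tibble::tibble(species = sp, n = length(mem), max_intra = max_intra,
                   min_inter = min_inter,
                   gap = if (is.na(max_intra)) NA else min_inter > max_intra)
  })
  dplyr::bind_rows(out)
}

#' Indicative conspecific distance threshold
#'
#' The `q` order-statistic quantile of all conspecific pairwise distances: the
#' smallest distance `d` such that at least a fraction `q` of conspecific
#' pairs lie at distance `<= d` (no interpolation). With `q = 0.95` this is
#' the "95% of conspecific pairs" indicative threshold used to judge whether
#' two sequences are likely conspecific.
#'
#' @inheritParams partition_distances
#' @param q quantile in `(0, 1]`.
#' @return the threshold distance (numeric scalar).
#' @export
conspecific_threshold <- function(mat, species, q = 0.95) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
  d <- sort(partition_distances(mat, species)$conspecific)
  if (length(d) == 0)
    stop("no conspecific pairs: every species is a singleton", call. = FALSE)
  d[ceiling(q * length(d))]
}
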