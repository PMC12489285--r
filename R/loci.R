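#' Locus map for an rDNA operon
#'
#' Ordered, non-overlapping windows (0-based half-open) naming the loci of a
#' ribosomal operon, in either reference ungapped coordinates or alignment
#' columns. Standard locus names are SSU, ITS1, 5.8S, ITS2, LSU; when those
#' names are used their genomic order is enforced.
#'
#' @param locus character vector of locus names.
#' @param start,end integer windows, 0-based half-open.
#' @param coordinates `"reference"` (ungapped) or `"alignment"` (columns).
#' @return a tibble of class `locus_map` with a `coordinates` attribute.
#' @export
locus_map <- function(locus, start, end, coordinates = c("reference", "alignment")) {
  coordinates <- match.arg(coordinates)
  start <- as.integer(start); end <- as.integer(end)
  if (length(locus) == 0) stop("locus map must have at least one window", call. = FALSE)
  if (any(end <= start)) stop("locus windows must satisfy end > start", call. = FALSE)
  o <- order(start)
  locus <- locus[o]; start <- start[o]; end <- end[o]
  if (any(utils::head(end, -1) > utils::tail(start, -1)))
    stop("locus windows must not overlap", call. = FALSE)
  std <- locus[locus %in% LOCUS_ORDER]   # in window order after sorting
  if (length(std) > 1 && !identical(std, LOCUS_ORDER[LOCUS_ORDER %in% std]))
    stop("standard rDNA loci must appear in operon order SSU < ITS1 < 5.8S < ITS2 < LSU",
         call. = FALSE)
  out <- tibble::tibble(locus = locus, start = start, end = end)
  class(out) <- c("locus_map", class(out))
  attr(out, "coordinates") <- coordinates
  out
}

#' Build the default operon locus map from locus lengths
#'
#' @param locus_lengths named integer vector of locus lengths in bp, in operon
#'   order (default SSU 1700, ITS1 250, 5.8S 160, ITS2 250, LSU 800).
#' @return a `locus_map` in reference coordinates.
#' @export
default_locus_map <- function(locus_lengths = c(SSU = 1700L, ITS1 = 250L,
                                                "5.8S" = 160L, ITS2 = 250L,
                                                LSU = 800L)) {
  ends <- cumsum(as.integer(locus_lengths))
  locus_map(names(locus_lengths), c(0L, utils::head(ends, -1)), ends)
}

#' Project a reference locus map onto alignment columns
#'
#' Maps each reference (ungapped) coordinate to its alignment column through
#' the gap structure of the reference row, replacing HMM-based locus detection
#' with reference-anchored coordinates. Projection is monotone.
#'
#' @param x an [aligned_set()] containing the reference row.
#' @param reference_id id of the annotated reference record.
#' @param ref_map a `locus_map` in reference ungapped coordinates.
#' @return a `locus_map` in alignment-column coordinates.
#' @export
project_locus_map <- function(x, reference_id, ref_map) {
  stopifnot(inherits(x, "aligned_set"), inherits(ref_map, "locus_map"))
  if (attr(ref_map, "coordinates") != "reference")
    stop("ref_map must be in reference coordinates", call. = FALSE)
  if (!reference_id %in% names(x$seqs))
    stop("reference id '", reference_id, "' not in alignment", call. = FALSE)
  ch <- strsplit(x$seqs[[reference_id]], "", fixed = TRUE)[[1]]
  res_col <- which(ch != "-")              # alignment column of residue k
  L <- length(res_col)
  if (any(ref_map$end > L))
    stop("locus map exceeds ungapped reference length (", L, ")", call. = FALSE)
  # 0-based half-open [s, e) in residues -> columns [col(s+1)-1, col(e)) half-open
  locus_map(ref_map$locus,
            res_col[ref_map$start + 1L] - 1L,
            res_col[ref_map$end],
            coordinates = "alignment")
}

#' Extract one locus from an alignment
#'
#' Slices the alignment columns of a locus and removes columns that are gaps
#' in every record; record ids, labels and residue order are preserved.
#'
#' @param x an [aligned_set()].
#' @param map a `locus_map` in alignment coordinates (or reference coordinates
#'   if the set is gap-free).
#' @param locus locus name to extract.
#' @return an [aligned_set()] restricted to the locus columns.
#' @export
extract_locus <- function(x, map, locus) {
  stopifnot(inherits(x, "aligned_set"), inherits(map, "locus_map"))
  row <- map[map$locus == locus, ]
  if (nrow(row) == 0) stop("unknown locus: ", locus, call. = FALSE)
  m <- aligned_matrix(x)
  if (row$end > ncol(m))
    stop("locus window exceeds alignment width", call. = FALSE)
  cols <- (row$start + 1L):row$end
  sl <- m[, cols, drop = FALSE]
  keep <- colSums(sl != "-") > 0
  sl <- sl[, keep, drop = FALSE]
  seqs <- apply(sl, 1, paste, collapse = "")
  names(seqs) <- rownames(m)
  aligned_set(seqs, labels = x$labels)
}

#' The Krüger barcode window
#'
#' Window spanning the 3' tail of the SSU (about 280 bp) through the first
#' part of the LSU (800 bp, the D1-D2 domains) - the fragment targeted by the
#' standard AMF barcoding primers. Clipped at the SSU start and LSU end.
#'
#' @param map a `locus_map` containing SSU and LSU.
#' @param ssu_tail bp of SSU tail to include (default 280).
#' @param lsu_head bp of LSU head to include (default 800).
#' @return one-row `locus_map` named `KRUGER`, same coordinate system as `map`.
#' @export
krueger_window <- function(map, ssu_tail = 280, lsu_head = 800) {
  stopifnot(inherits(map, "locus_map"))
  ssu <- map[map$locus == "SSU", ]
  lsu <- map[map$locus == "LSU", ]
  if (nrow(ssu) == 0 || nrow(lsu) == 0)
    stop("locus map must contain SSU and LSU", call. = FALSE)
  start <- max(ssu$start, ssu$end - as.integer(ssu_tail))
  end <- min(lsu$start + as.integer(lsu_head), lsu$end)
  locus_map("KRUGER", start, end, coordinates = attr(map, "coordinates"))
}
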