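#' Aligned sequence set
#'
#' Container for equal-length gapped sequences (the substrate of all distance
#' analyses), with optional per-record group labels (strain or species).
#'
#' @param x named character vector or [Biostrings::XStringSet] of equal-length
#'   sequences over A/C/G/T/N/-.
#' @param labels optional character vector of group labels, either unnamed (in
#'   record order) or named by record id.
#' @return an object of class `aligned_set` with elements `seqs` (named
#'   character) and `labels`.
#' @export
aligned_set <- function(x, labels = NULL) {
  seqs <- as_seq_chr(x)
  if (length(seqs) == 0) stop("aligned_set needs at least one record", call. = FALSE)
  check_alphabet(seqs, gaps = TRUE, context = "aligned record")
  w <- unique(nchar(seqs))
  if (length(w) != 1)
    stop("aligned records must have equal length; got widths ",
         paste(sort(w), collapse = ", "), call. = FALSE)
  if (any(vapply(seqs, function(s) !grepl("[ACGTN]", s), logical(1))))
    stop("aligned records must contain at least one non-gap residue", call. = FALSE)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(names(seqs), names(labels))
      if (length(miss))
        stop("labels missing for: ", paste(miss, collapse = ", "), call. = FALSE)
      labels <- labels[names(seqs)]
    } else {
      if (length(labels) != length(seqs))
        stop("labels must match the number of records", call. = FALSE)
      names(labels) <- names(seqs)
    }
  }
  structure(list(seqs = seqs, labels = labels), class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d records x %d columns%s\n",
              length(x$seqs), nchar(x$seqs[[1]]),
              if (is.null(x$labels)) "" else
                sprintf(" (%d groups)", length(unique(x$labels)))))
  invisible(x)
}

# Character matrix view of an aligned set (records x columns).
aligned_matrix <- function(x) {
  stopifnot(inherits(x, "aligned_set"))
  m <- do.call(rbind, strsplit(unname(x$seqs), "", fixed = TRUE))
  rownames(m) <- names(x$seqs)
  m
}

default_scores <- function() {
  c(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2)
}

check_scores <- function(scores) {
  if (length(scores) != 4 || anyNA(scores))
    stop("scores must be c(match, mismatch, gap_open, gap_extend)", call. = FALSE)
  scores <- as.numeric(scores)
  if (scores[1] <= scores[2])
    stop("invalid scores: match must exceed mismatch", call. = FALSE)
  if (scores[4] >= 0)
    stop("invalid scores: gap_extend must be negative", call. = FALSE)
  if (scores[3] > 0)
    stop("invalid scores: gap_open must be <= 0", call. = FALSE)
  scores
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-style alignment of two ungapped sequences under affine-gap
#' scoring: a gap of length L scores `gap_open + L * gap_extend`. Ties are
#' broken deterministically (match/mismatch preferred over gaps, then the gap
#' is placed in the first sequence). For long sequences a diagonal band is
#' used; `band` must then exceed the expected indel drift.
#'
#' @param a,b ungapped sequences (single strings). An empty sequence aligns
#'   against all gaps.
#' @param scores numeric vector `c(match, mismatch, gap_open, gap_extend)`.
#' @param band half-width of the alignment band; `NULL` chooses the full
#'   matrix for short pairs and a generous band (`0.2 * max length + length
#'   difference`, at least 200) for long ones. `0` forces the full matrix.
#' @param end_free if `TRUE`, terminal gaps are free (overlap alignment, used
#'   for read-to-reference mapping).
#' @return list with gapped strings `a` and `b` and the alignment `score`.
#' @export
#' @examples
#' align_pair("ACGT", "ACT", scores = c(1, -1, 0, -2))
align_pair <- function(a, b, scores = default_scores(), band = NULL,
                       end_free = FALSE) {
  scores <- check_scores(scores)
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (is.null(band)) {
    L <- max(nchar(a), nchar(b))
    band <- if (L <= 1500) 0L else
      as.integer(max(200, abs(nchar(a) - nchar(b)) + ceiling(0.2 * L)))
  }
  cpp_align_affine(toupper(a), toupper(b), scores[1], scores[2], scores[3],
                   scores[4], as.integer(end_free), as.integer(band))
}

#' Identity of an aligned pair
#'
#' Fraction of alignment columns where both sequences carry the same residue
#' (gap and N columns count in the denominator).
#'
#' @param aln a list with gapped strings `a` and `b` as returned by
#'   [align_pair()].
#' @return identity in `[0, 1]`.
#' @export
alignment_identity <- function(aln) {
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  if (length(ca) == 0) return(1)
  sum(ca == cb & ca != "-") / length(ca)
}

#' Pairwise distance with the each-gap convention
#'
#' Distance between two rows of an alignment where every gapped column in the
#' compared span counts as one difference (mothur's `calc = eachgap`), and
#' with `count_ends = FALSE` terminal gaps are excluded (`countends = F`): the
#' compared span runs from the later of the two first non-gap columns through
#' the earlier of the two last non-gap columns. Columns where both sequences
#' are gaps, or where either carries N, are excluded from both numerator and
#' denominator.
#'
#' @param a,b equal-length gapped sequences (single strings).
#' @param count_ends if `TRUE`, terminal gap columns are compared too.
#' @return list with `distance`, `n_diff`, `n_compared`, and `zero_overlap`
#'   (`TRUE` when no column was comparable; the distance is then 0 by
#'   convention and a warning is issued).
#' @export
#' @examples
#' eachgap_distance("AC-GT", "ACCGA")  # 2 differences over 5 columns
eachgap_distance <- function(a, b, count_ends = FALSE) {
  if (nchar(a) != nchar(b))
    stop("eachgap_distance: sequences must have equal length", call. = FALSE)
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  eachgap_core(ca, cb, count_ends)
}

# core on pre-split character vectors (shared with distance_matrix)
eachgap_core <- function(ca, cb, count_ends) {
  L <- length(ca)
  ga <- ca == "-"
  gb <- cb == "-"
  if (count_ends) {
    lo <- 1L; hi <- L
  } else {
    na_ <- which(!ga); nb_ <- which(!gb)
    if (length(na_) == 0 || length(nb_) == 0) {
      warning("zero-overlap pair: distance set to 0 by convention")
      return(list(distance = 0, n_diff = 0L, n_compared = 0L, zero_overlap = TRUE))
    }
    lo <- max(na_[1], nb_[1])
    hi <- min(na_[length(na_)], nb_[length(nb_)])
  }
  if (lo > hi) {
    warning("zero-overlap pair: distance set to 0 by convention")
    return(list(distance = 0, n_diff = 0L, n_compared = 0L, zero_overlap = TRUE))
  }
  idx <- lo:hi
  skip <- (ga[idx] & gb[idx]) | ca[idx] == "N" | cb[idx] == "N"
  use <- idx[!skip]
  n_comp <- length(use)
  if (n_comp == 0) {
    warning("zero-overlap pair: distance set to 0 by convention")
    return(list(distance = 0, n_diff = 0L, n_compared = 0L, zero_overlap = TRUE))
  }
  n_diff <- sum(ca[use] != cb[use])
  list(distance = n_diff / n_comp, n_diff = as.integer(n_diff),
       n_compared = as.integer(n_comp), zero_overlap = FALSE)
}

#' Pairwise distance matrix over an aligned set
#'
#' All unordered pairs via [eachgap_distance()]. The gap-handling convention
#' is recorded in the `convention` attribute; pairs with zero comparable
#' columns are flagged in the `zero_overlap` attribute (their distance is 0).
#'
#' @param x an [aligned_set()].
#' @param count_ends passed to [eachgap_distance()].
#' @return symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
distance_matrix <- function(x, count_ends = FALSE) {
  stopifnot(inherits(x, "aligned_set"))
  n <- length(x$seqs)
  if (n < 2) stop("distance_matrix needs at least 2 sequences", call. = FALSE)
  m <- aligned_matrix(x)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  flagged <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- withCallingHandlers(
        eachgap_core(m[i, ], m[j, ], count_ends),
        warning = function(w) invokeRestart("muffleWarning"))
      D[i, j] <- D[j, i] <- r$distance
      if (r$zero_overlap)
        flagged <- c(flagged, paste(rownames(m)[i], rownames(m)[j], sep = "|"))
    }
  }
  if (length(flagged))
    warning(length(flagged), " zero-overlap pair(s); distances set to 0")
  attr(D, "convention") <- list(calc = "eachgap", count_ends = count_ends,
                                n_handling = "columns with N excluded")
  attr(D, "zero_overlap") <- flagged
  D
}

#' Pairwise distance matrix for unaligned sequences
#'
#' Aligns every unordered pair globally with [align_pair()] and applies the
#' each-gap distance to the aligned pair (the built-in pairwise mode used when
#' no external multiple alignment is supplied).
#'
#' @param x named character vector or XStringSet of ungapped sequences.
#' @param scores,band passed to [align_pair()].
#' @param count_ends passed to [eachgap_distance()].
#' @return symmetric distance matrix as in [distance_matrix()].
#' @export
pairwise_distance_matrix <- function(x, scores = default_scores(),
                                     band = NULL, count_ends = FALSE) {
  seqs <- as_seq_chr(x)
  check_alphabet(seqs, gaps = FALSE, context = "sequence")
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- align_pair(seqs[[i]], seqs[[j]], scores = scores, band = band)
      r <- eachgap_distance(aln$a, aln$b, count_ends = count_ends)
      D[i, j] <- D[j, i] <- r$distance
    }
  }
  attr(D, "convention") <- list(calc = "eachgap", count_ends = count_ends,
                                n_handling = "columns with N excluded",
                                alignment = "pairwise global")
  D
}

#' Within-group distance summaries
#'
#' Per-group minimum, mean and maximum over the unordered within-group pairs
#' of a distance matrix (the per-strain / per-locus statistics of intragenomic
#' variation reports). Groups with fewer than two sequences are kept with an
#' explicit undefined marker (`defined = FALSE`, statistics `NA`).
#'
#' @param mat symmetric distance matrix with ids as dimnames.
#' @param labels group label per id (named by id, or in matrix order).
#' @return tibble with columns `group`, `n`, `min`, `mean`, `max`, `defined`.
#' @export
group_summary <- function(mat, labels) {
  ids <- rownames(mat)
  labels <- resolve_labels(labels, ids)
  out <- lapply(unique(labels), function(g) {
    mem <- ids[labels == g]
    if (length(mem) < 2) {
      tibble::tibble(group = g, n = length(mem), min = NA_real_,
                     mean = NA_real_, max = NA_real_, defined = FALSE)
    } else {
      d <- mat[mem, mem][upper.tri(diag(length(mem)))]
      tibble::tibble(group = g, n = length(mem), min = min(d),
                     mean = mean(d), max = max(d), defined = TRUE)
    }
  })
  dplyr::bind_rows(out)
}

# labels: named by id (must cover all ids; extra names are an error) or
# unnamed in id order.
resolve_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    unknown <- setdiff(names(labels), ids)
    if (length(unknown))
      stop("unknown id(s) in labels: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    miss <- setdiff(ids, names(labels))
    if (length(miss))
      stop("labels missing for id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    labels <- labels[ids]
  } else {
    if (length(labels) != length(ids))
      stop("labels must match the number of ids", call. = FALSE)
    names(labels) <- ids
  }
  as.character(labels)
}

#' Round a fraction to a percentage for reporting
#'
#' Human-facing reports print percentages rounded half-away-from-zero to one
#' decimal; raw fractions are always retained alongside in tables.
#'
#' @param x fraction(s) in `[0, 1]`.
#' @param digits decimals to keep (default 1).
#' @return numeric percentage(s).
#' @export
percent <- function(x, digits = 1) {
  p <- x * 100
  f <- 10^digits
  sign(p) * floor(abs(p) * f + 0.5) / f
}

#' Write a distance matrix as TSV
#'
#' `write_distance_column()` writes mothur-style "column" format (idA, idB,
#' distance; unordered pairs once). `write_distance_square()` writes the full
#' square matrix with an `id` column.
#'
#' @param mat symmetric distance matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_column <- function(mat, path) {
  ids <- rownames(mat)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                                  distance = mat[ut]), path)
  invisible(path)
}

#' @rdname write_distance_column
#' @export
write_distance_square <- function(mat, path) {
  df <- tibble::as_tibble(as.data.frame(mat), rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}
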