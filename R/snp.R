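#' Map reads to a single rDNA reference and build a pileup
#'
#' Each read is aligned to the reference with free terminal gaps (overlap
#' alignment, banded affine scoring), in both orientations, and the better
#' orientation is kept. Reads whose identity over the aligned core falls below
#' `min_identity` are discarded and counted. Per-position counts of
#' A/C/G/T/deletion are accumulated over the reference; insertions relative to
#' the reference are ignored.
#'
#' @param reads named character vector of ungapped reads.
#' @param reference single ungapped reference sequence (the rDNA copy or
#'   Sanger reference the short reads are assembled against).
#' @param band alignment band half-width; must exceed the expected indel
#'   drift between read and reference (default 100).
#' @param min_identity minimum core identity to keep a read (default 0.8).
#' @param scores alignment scores.
#' @return an `rdna_pileup`: list with `reference`, `counts` (5 x L matrix,
#'   rows A/C/G/T/-), `depth` (per-position column sums), `n_mapped`,
#'   `n_discarded`.
#' @export
map_reads <- function(reads, reference, band = 100L, min_identity = 0.8,
                      scores = default_scores()) {
  reference <- toupper(reference)
  if (nchar(reference) == 0) stop("reference must be non-empty", call. = FALSE)
  reads <- as_seq_chr(reads)
  L <- nchar(reference)
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c(BASES, "-"), NULL))
  n_mapped <- 0L; n_discarded <- 0L
  for (r in reads) {
    cand <- list(r, revcomp(r))
    alns <- lapply(cand, function(x)
      align_pair(reference, x, scores = scores, band = band, end_free = TRUE))
    aln <- alns[[which.max(vapply(alns, function(a) a$score, numeric(1)))]]
    ra <- strsplit(aln$a, "", fixed = TRUE)[[1]]
    qa <- strsplit(aln$b, "", fixed = TRUE)[[1]]
    # aligned core: trim terminal gap runs of either sequence
    nong <- which(ra != "-" & qa != "-")
    if (length(nong) == 0) { n_discarded <- n_discarded + 1L; next }
    core <- nong[1]:nong[length(nong)]
    ident <- sum(ra[core] == qa[core]) / length(core)
    if (ident < min_identity) { n_discarded <- n_discarded + 1L; next }
    rp <- cumsum(ra != "-")
    use <- core[ra[core] != "-"]
    base <- match(qa[use], rownames(counts))
    ok <- !is.na(base)                   # N in a read contributes nothing
    idx <- cbind(base[ok], rp[use][ok])
    counts[idx] <- counts[idx] + 1L
    n_mapped <- n_mapped + 1L
  }
  structure(list(reference = reference, counts = counts,
                 depth = colSums(counts), n_mapped = n_mapped,
                 n_discarded = n_discarded), class = "rdna_pileup")
}

#' @export
print.rdna_pileup <- function(x, ...) {
  cat(sprintf("<rdna_pileup> reference %d bp, %d reads mapped, %d discarded, mean depth %.1f\n",
              nchar(x$reference), x$n_mapped, x$n_discarded, mean(x$depth)))
  invisible(x)
}

#' Call intragenomic SNPs from a pileup
#'
#' A position is called when its depth reaches `min_depth` and some
#' non-reference base reaches both `min_alt_count` reads and `min_alt_frac` of
#' the depth. Deletions are never called as SNPs. Thresholds default to
#' min_depth 20, min_alt_frac 0.05, min_alt_count 3 and are recorded in the
#' output attributes.
#'
#' @param pileup an `rdna_pileup` from [map_reads()].
#' @param min_depth minimum depth.
#' @param min_alt_frac minimum alternate-base fraction of depth.
#' @param min_alt_count minimum alternate-base read count.
#' @return tibble with `pos` (1-based), `ref`, `alt` (major alternate),
#'   `alt_count`, `alt_frac`, `depth`.
#' @export
call_snps <- function(pileup, min_depth = 20L, min_alt_frac = 0.05,
                      min_alt_count = 3L) {
  stopifnot(inherits(pileup, "rdna_pileup"))
  refc <- strsplit(pileup$reference, "", fixed = TRUE)[[1]]
  L <- length(refc)
  base_counts <- pileup$counts[BASES, , drop = FALSE]
  ref_idx <- match(refc, BASES)
  alt_counts <- base_counts
  ok_ref <- !is.na(ref_idx)
  alt_counts[cbind(ref_idx[ok_ref], which(ok_ref))] <- -1L  # mask reference base
  best_alt <- apply(alt_counts, 2, which.max)
  best_cnt <- alt_counts[cbind(best_alt, seq_len(L))]
  depth <- pileup$depth
  frac <- ifelse(depth > 0, best_cnt / depth, 0)
  call <- depth >= min_depth & best_cnt >= min_alt_count & frac >= min_alt_frac
  out <- tibble::tibble(pos = which(call),
                        ref = refc[call],
                        alt = BASES[best_alt[call]],
                        alt_count = as.integer(best_cnt[call]),
                        alt_frac = frac[call],
                        depth = as.integer(depth[call]))
  attr(out, "thresholds") <- list(min_depth = min_depth,
                                  min_alt_frac = min_alt_frac,
                                  min_alt_count = min_alt_count)
  out
}

#' Windowed SNP density track
#'
#' Sliding-window SNP density over the reference: for each window start in
#' `0, step, 2*step, ...` the density is the number of called SNPs in
#' `[start, start + window)` divided by the window size. Window/step default
#' to 100/10 bp, appropriate for a few-kb amplicon.
#'
#' @param snps SNP table from [call_snps()] (1-based positions).
#' @param reference_length reference length in bp.
#' @param window window size in bp.
#' @param step step between window starts in bp.
#' @return tibble with `start` (0-based), `end`, `n_snps`, `density`
#'   (SNPs per bp).
#' @export
density_track <- function(snps, reference_length, window = 100L, step = 10L) {
  if (step < 1 || window < step)
    stop("need window >= step >= 1", call. = FALSE)
  if (window > reference_length) {
    n <- sum(snps$pos >= 1 & snps$pos <= reference_length)
    return(tibble::tibble(start = 0L, end = as.integer(reference_length),
                          n_snps = as.integer(n),
                          density = n / reference_length))
  }
  starts <- seq(0L, as.integer(reference_length) - 1L, by = as.integer(step))
  pos0 <- snps$pos - 1L                  # 0-based SNP positions
  n <- vapply(starts, function(s)
    sum(pos0 >= s & pos0 < s + window), integer(1))
  tibble::tibble(start = starts,
                 end = pmin(starts + as.integer(window),
                            as.integer(reference_length)),
                 n_snps = n, density = n / window)
}

#' Mean SNP density per locus
#'
#' Averages the windowed density over the windows whose midpoint falls inside
#' each locus of a reference locus map (the per-locus comparison behind SNP
#' density tracks).
#'
#' @param track density track from [density_track()].
#' @param map a `locus_map` in reference coordinates.
#' @return tibble with `locus` and `mean_density`.
#' @export
locus_density <- function(track, map) {
  stopifnot(inherits(map, "locus_map"))
  mid <- (track$start + track$end) / 2
  out <- lapply(seq_len(nrow(map)), function(i) {
    sel <- mid >= map$start[i] & mid < map$end[i]
    tibble::tibble(locus = map$locus[i],
                   mean_density = if (any(sel)) mean(track$density[sel])
                                  else NA_real_)
  })
  dplyr::bind_rows(out)
}
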