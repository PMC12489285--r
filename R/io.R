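#' Read a FASTA file of rDNA/gene sequences
#'
#' Reads plain or gzipped FASTA via Biostrings, upper-cases residues, and
#' validates them against the A/C/G/T/N/- alphabet (gaps are preserved so
#' aligned FASTA round-trips). IUPAC ambiguity codes other than N are rejected
#' with an error naming the record and offending position, since the distance
#' conventions used downstream are only defined over A/C/G/T/N/-.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] in file order; names are the full
#'   header lines up to the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (length(seqs)) {
    if (any(names(seqs) == ""))
      stop("FASTA record with empty id in ", path, call. = FALSE)
    if (anyDuplicated(names(seqs)))
      stop("duplicate FASTA ids in ", path, ": ",
           paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
           call. = FALSE)
    check_alphabet(seqs, gaps = TRUE, context = "FASTA record")
    if (any(nchar(seqs) == 0))
      stop("empty FASTA record in ", path, call. = FALSE)
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param x named character vector or [Biostrings::XStringSet].
#' @param path output path.
#' @param line_width residues per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 60) {
  seqs <- as_seq_chr(x, require_names = length(x) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a 4-line-per-record FASTQ file.
#' @return a list with `sequences` (named character vector, upper case) and
#'   `qualities` (list of integer Phred scores, same names). Truncated records
#'   or sequence/quality length mismatches raise an error.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0)
    return(list(sequences = stats::setNames(character(), character()),
                qualities = list()))
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record near line ", 4 * (length(lines) %/% 4) + 1,
         " of ", path, call. = FALSE)
  hd <- lines[seq(1, length(lines), by = 4)]
  sq <- toupper(lines[seq(2, length(lines), by = 4)])
  qu <- lines[seq(4, length(lines), by = 4)]
  if (any(substr(hd, 1, 1) != "@"))
    stop("malformed FASTQ header at line ",
         4 * (which(substr(hd, 1, 1) != "@")[1] - 1) + 1, " of ", path,
         call. = FALSE)
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop("sequence/quality length mismatch in FASTQ record at line ",
         4 * (bad[1] - 1) + 1, " of ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", substring(hd, 2))
  names(sq) <- ids
  check_alphabet(sq, gaps = FALSE, context = "FASTQ record")
  quals <- lapply(qu, function(q) as.integer(charToRaw(q)) - 33L)
  names(quals) <- ids
  list(sequences = sq, qualities = quals)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param x named character vector of read sequences.
#' @param path output path.
#' @param qualities either a single integer (constant Phred score for every
#'   base), or a list of per-read integer vectors.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, qualities = 40L) {
  seqs <- as_seq_chr(x, require_names = length(x) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    q <- if (is.list(qualities)) qualities[[i]] else
      rep(as.integer(qualities), nchar(seqs[[i]]))
    if (length(q) != nchar(seqs[[i]]))
      stop("quality length mismatch for read ", names(seqs)[i], call. = FALSE)
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 rawToChar(as.raw(q + 33L))), con)
  }
  invisible(path)
}

#' Read a sample manifest (TSV)
#'
#' Expects a header with at least the columns `id`, `strain`, `species`,
#' `locus` (sequence id, strain label, species label, locus/gene label).
#'
#' @param path path to a tab-separated manifest.
#' @return a tibble with one row per sequence id.
#' @export
read_manifest <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("id", "strain", "species", "locus")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(x)) {
    if (anyDuplicated(x$id))
      stop("duplicate id(s) in manifest: ",
           paste(unique(x$id[duplicated(x$id)]), collapse = ", "),
           call. = FALSE)
    empt <- !vapply(need, function(cn) all(nzchar(x[[cn]]) & !is.na(x[[cn]])),
                    logical(1))
    if (any(empt))
      stop("manifest has empty values in column(s): ",
           paste(need[empt], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read / write a locus map (BED-like TSV)
#'
#' Locus maps are tables with columns `locus`, `start`, `end` in 0-based
#' half-open coordinates (internal convention; reports are 1-based inclusive).
#'
#' @param path file path.
#' @return `read_locus_map()` returns a validated locus-map tibble.
#' @export
read_locus_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    locus = "c", start = "i", end = "i"), progress = FALSE)
  locus_map(x$locus, x$start, x$end)
}

#' @rdname read_locus_map
#' @param map a locus-map tibble (see [locus_map()]).
#' @export
write_locus_map <- function(map, path) {
  readr::write_tsv(map[, c("locus", "start", "end")], path)
  invisible(path)
}
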