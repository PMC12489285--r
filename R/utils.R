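#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulation helpers never disturb the session RNG.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer hash used to give each strain/stage of a simulation
#' its own stream while keeping everything reproducible from one master seed.
#' Results stay below 2^31.
#'
#' @param master integer master seed.
#' @param salt integer distinguishing the consumer (stage index etc.).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, salt) {
  m <- 2147483647
  x <- (as.double(master) %% m) + 1
  for (s in as.double(salt)) {
    x <- (x * 48271 + s + 1) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over A/C/G/T/N (gaps preserved).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a random DNA sequence
#'
#' @param length sequence length in bp.
#' @return a single character string over A/C/G/T drawn uniformly.
#' @keywords internal
random_dna <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

# Normalize sequence input (XStringSet or character) to a named upper-case
# character vector; names are required and must be unique.
as_seq_chr <- function(x, require_names = TRUE) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("sequences must be a character vector or an XStringSet", call. = FALSE)
  }
  out <- toupper(out)
  if (require_names) {
    if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
      stop("sequences must be named (non-empty ids)", call. = FALSE)
    if (anyDuplicated(names(out)))
      stop("duplicate sequence ids: ",
           paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
           call. = FALSE)
  }
  out
}

# Validate residues against the package alphabet; `gaps` allows '-'.
check_alphabet <- function(seqs, gaps = TRUE, context = "sequence") {
  allowed <- if (gaps) ALPHABET else setdiff(ALPHABET, "-")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      id <- if (!is.null(names(seqs))) names(seqs)[i] else as.character(i)
      stop(sprintf(
        "%s '%s' contains invalid residue '%s' at position %d (allowed: %s)",
        context, id, ch[bad[1]], bad[1], paste(allowed, collapse = "")),
        call. = FALSE)
    }
  }
  invisible(seqs)
}

# Hamming mismatches between equal-length strings (used for primer matching).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: length mismatch", call. = FALSE)
  sum(charToRaw(a) != charToRaw(b))
}
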