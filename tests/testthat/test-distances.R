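test_that("global alignment recovers the expected optimum and tie behaviour", {
  # identical sequences: gap-free alignment
  aln <- align_pair("ACGTACGT", "ACGTACGT")
  expect_identical(aln$a, "ACGTACGT")
  expect_identical(aln$b, "ACGTACGT")

  # single-deletion optimum, verified against exhaustive enumeration of all
  # alignments of length <= 7 (match 1, mismatch -1, gap -2)
  sc <- c(1, -1, 0, -2)
  aln <- align_pair("ACGT", "ACT", scores = sc)
  expect_equal(aln$score, 1)
  expect_identical(aln$a, "ACGT")
  expect_identical(aln$b, "AC-T")
  brute <- function(a, b) {
    # enumerate all monotone alignments recursively
    best <- -Inf
    rec <- function(i, j, s) {
      if (i > nchar(a) && j > nchar(b)) { best <<- max(best, s); return() }
      if (i <= nchar(a) && j <= nchar(b))
        rec(i + 1, j + 1, s + if (substr(a, i, i) == substr(b, j, j)) 1 else -1)
      if (i <= nchar(a)) rec(i + 1, j, s - 2)
      if (j <= nchar(b)) rec(i, j + 1, s - 2)
    }
    rec(1, 1, 0)
    best
  }
  expect_equal(aln$score, brute("ACGT", "ACT"))
  for (k in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:5, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:5, 1), TRUE), collapse = "")
    expect_equal(align_pair(a, b, scores = sc)$score, brute(a, b))
  }

  # empty sequence aligns against all gaps
  aln <- align_pair("ACGT", "")
  expect_identical(aln$b, "----")
  expect_error(align_pair("AC", "AC", scores = c(1, 2, 0, -1)), "invalid scores")
})

test_that("each-gap distance matches the hand-enumerated spans", {
  r <- eachgap_distance("ACGTACGT", "ACGTACGT")
  expect_equal(r[c("distance", "n_diff", "n_compared")],
               list(distance = 0, n_diff = 0L, n_compared = 8L))

  # internal gap and terminal mismatch, span = all 5 columns
  r <- eachgap_distance("AC-GT", "ACCGA")
  expect_equal(r$distance, 0.4)
  expect_identical(r$n_diff, 2L)
  expect_identical(r$n_compared, 5L)

  # terminal gaps excluded from the compared span
  r <- eachgap_distance("--ACGT", "TTACGT")
  expect_equal(r$distance, 0)
  expect_identical(r$n_compared, 4L)
  # ... but compared when count_ends = TRUE
  r <- eachgap_distance("--ACGT", "TTACGT", count_ends = TRUE)
  expect_identical(r$n_diff, 2L)
  expect_identical(r$n_compared, 6L)

  # a pair differing at 128 of 2808 compared columns
  base <- strsplit(paste(rep("ACGT", 702), collapse = ""), "")[[1]]
  other <- base
  other[seq_len(128) * 20] <- ifelse(base[seq_len(128) * 20] == "A", "C", "A")
  r <- eachgap_distance(paste(base, collapse = ""), paste(other, collapse = ""))
  expect_identical(r$n_diff, 128L)
  expect_identical(r$n_compared, 2808L)
  expect_equal(r$distance, 128 / 2808)
  expect_equal(percent(r$distance), 4.6)  # rounded half-away-from-zero

  # N columns are excluded from numerator and denominator
  r <- eachgap_distance("ANGT", "AAGT")
  expect_identical(r$n_compared, 3L)
  expect_equal(r$distance, 0)

  # zero-overlap pair: distance 0 with a warning flag
  expect_warning(r <- eachgap_distance("AA----", "----TT"), "zero-overlap")
  expect_true(r$zero_overlap)
  expect_equal(r$distance, 0)

  expect_error(eachgap_distance("AC", "ACG"), "equal length")
})

test_that("each-gap distance equals Hamming/length on gap-free pairs", {
  withr::local_seed(42)
  for (k in 1:50) {
    L <- sample(5:80, 1)
    a <- sample(c("A", "C", "G", "T"), L, TRUE)
    b <- sample(c("A", "C", "G", "T"), L, TRUE)
    r <- eachgap_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_equal(r$distance, sum(a != b) / L)
  }
})

test_that("each-gap distance agrees with the naive column-walk oracle", {
  withr::local_seed(7)
  for (k in 1:300) {
    p <- random_aligned_pair(120)
    for (ce in c(FALSE, TRUE)) {
      got <- suppressWarnings(eachgap_distance(p$a, p$b, count_ends = ce))
      want <- naive_eachgap(p$a, p$b, count_ends = ce)
      expect_identical(got$n_diff, want$n_diff)
      expect_identical(got$n_compared, want$n_compared)
      expect_equal(got$distance, want$distance)
    }
  }
})

test_that("distance matrices are symmetric, zero-diagonal and match per-pair", {
  s <- aligned_set(c(a = "ACGT-ACGT", b = "ACGTTACGA", c = "AC-TTACGT"))
  D <- distance_matrix(s)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_identical(D, t(D))
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    want <- eachgap_distance(s$seqs[[p[1]]], s$seqs[[p[2]]])$distance
    expect_equal(D[p[1], p[2]], want)
  }
  expect_identical(attr(D, "convention")$calc, "eachgap")
  expect_error(distance_matrix(aligned_set(c(a = "ACGT"))), "at least 2")
})

test_that("pairwise mode reproduces aligned-mode distances on gap-free sets", {
  withr::local_seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  seqs <- c(x = base,
            y = mutate_sequence(base, 0.03)$sequence,
            z = mutate_sequence(base, 0.03)$sequence)
  D1 <- pairwise_distance_matrix(seqs)
  D2 <- distance_matrix(aligned_set(seqs))  # equal lengths, no indels
  expect_equal(D1, D2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("group summaries match brute-force per-group statistics", {
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["a1", "a2"] <- m["a2", "a1"] <- 0.02
  m["b1", "b2"] <- m["b2", "b1"] <- 0.10
  m["a1", "b1"] <- m["b1", "a1"] <- 0.30
  m["a1", "b2"] <- m["b2", "a1"] <- 0.25
  m["a2", "b1"] <- m["b1", "a2"] <- 0.28
  m["a2", "b2"] <- m["b2", "a2"] <- 0.31
  gs <- group_summary(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(gs$min, c(0.02, 0.10))
  expect_equal(gs$mean, c(0.02, 0.10))
  expect_equal(gs$max, c(0.02, 0.10))
  expect_true(all(gs$defined))

  # identical sequences: all-zero summary
  s <- aligned_set(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  gs <- group_summary(distance_matrix(s), c(x = "g", y = "g", z = "g"))
  expect_equal(unlist(gs[, c("min", "mean", "max")]), c(0, 0, 0),
               ignore_attr = TRUE)

  # singleton group carries an explicit undefined marker
  gs <- group_summary(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"))
  expect_false(gs$defined[gs$group == "C"])
  expect_true(is.na(gs$max[gs$group == "C"]))

  expect_error(group_summary(m, c(zz = "A")), "unknown id")
})

test_that("percent() rounds half away from zero to one decimal", {
  expect_equal(percent(0.0456), 4.6)
  expect_equal(percent(0.04555), 4.6)
  expect_equal(percent(0.0445), 4.5)
  expect_equal(percent(0.01), 1.0)
})

test_that("distance matrix TSV writers emit column and square formats", {
  s <- aligned_set(c(a = "ACGT", b = "ACGA", c = "TCGA"))
  D <- distance_matrix(s)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_column(D, f1)
  col <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_identical(nrow(col), 3L)
  expect_equal(col$distance[col$id_a == "a" & col$id_b == "b"], D["a", "b"])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_square(D, f2)
  sq <- readr::read_tsv(f2, show_col_types = FALSE)
  expect_identical(dim(sq), c(3L, 4L))
})
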