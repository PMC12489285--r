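make_read <- function(insert, fwd = DEFAULT_FWD_PRIMER, rev = DEFAULT_REV_PRIMER) {
  paste0(fwd, insert, revcomp(rev))
}

test_that("primer trimming recovers the insert in both orientations", {
  cfg <- recovery_config()
  insert <- paste(rep("ACGT", 25), collapse = "")
  reads <- c(r1 = make_read(insert), r2 = revcomp(make_read(insert)),
             r3 = paste0(DEFAULT_FWD_PRIMER, insert))       # missing rev
  tr <- trim_primers(reads, cfg)
  expect_identical(tr$trimmed[["r1"]], insert)
  expect_identical(tr$trimmed[["r2"]], insert)              # revcomp symmetry
  expect_identical(tr$rejected$id, "r3")
  expect_identical(tr$rejected$reason, "no_rev")

  # up to max_mismatch substitutions in a primer are tolerated
  fwd_mut <- DEFAULT_FWD_PRIMER
  substr(fwd_mut, 3, 4) <- "AA"
  r4 <- c(r4 = make_read(insert, fwd = fwd_mut))
  expect_identical(trim_primers(r4, cfg)$trimmed[["r4"]], insert)
  cfg0 <- recovery_config(max_mismatch = 0)
  tr0 <- trim_primers(r4, cfg0)
  expect_identical(nrow(tr0$rejected), 1L)
})

test_that("length filter drops out-of-window and ambiguous reads", {
  reads <- c(a = paste(rep("A", 50), collapse = ""),
             b = paste(rep("C", 30), collapse = ""),
             c = paste0(paste(rep("G", 49), collapse = ""), "N"))
  lf <- length_filter(reads, 40, 60)
  expect_identical(names(lf$retained), "a")
  expect_setequal(lf$rejected$reason, c("length", "ambiguous_base"))
  expect_error(length_filter(reads, 60, 40), "min_len")
})

test_that("dereplication counts exactly and orders deterministically", {
  reads <- c(rep("ACGT", 10))
  names(reads) <- sprintf("r%d", 1:10)
  amps <- dereplicate(reads)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$abundance, 10L)

  # abundance ties break by ascending sequence
  reads <- c(a1 = "TTTT", a2 = "TTTT", a3 = "TTTT",
             b1 = "AAAA", b2 = "AAAA", b3 = "AAAA")
  amps <- dereplicate(reads)
  expect_identical(amps$sequence, c("AAAA", "TTTT"))

  # counting oracle on a random multiset
  withr::local_seed(2)
  pool <- replicate(5, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                             collapse = ""))
  draw <- sample(pool, 200, replace = TRUE)
  names(draw) <- sprintf("r%03d", seq_along(draw))
  amps <- dereplicate(draw)
  want <- table(draw)
  expect_identical(sum(amps$abundance), 200L)
  expect_identical(amps$abundance[match(names(want), amps$sequence)],
                   as.integer(want))

  expect_identical(nrow(dereplicate(character(0))), 0L)
})

test_that("constructed 50/50 chimeras are flagged with their parent pair", {
  withr::local_seed(8)
  root <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  pa <- mutate_sequence(root, 0.04)$sequence
  pb <- mutate_sequence(root, 0.04)$sequence
  chim <- make_chimera(pa, pb, 300)
  amps <- tibble::tibble(id = c("amp1", "amp2", "amp3"),
                         sequence = c(pa, pb, chim),
                         abundance = c(100L, 90L, 10L))
  v <- detect_chimeras(amps)
  expect_identical(v$chimeric, c(FALSE, FALSE, TRUE))
  expect_setequal(c(v$parent_a[3], v$parent_b[3]), c("amp1", "amp2"))
  expect_gte(v$model_identity[3], 0.99)
  expect_equal(v$breakpoint[3], 300, tolerance = 0.1)

  # candidate identical to one parent: clean (no crossover gain)
  amps2 <- tibble::tibble(id = c("amp1", "amp2", "amp3"),
                          sequence = c(pa, pb, pa),
                          abundance = c(100L, 90L, 10L))
  expect_false(detect_chimeras(amps2)$chimeric[3])

  # nothing can be chimeric without two higher-abundance parents
  amps3 <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = c(pa, pb, chim),
                          abundance = c(10L, 10L, 10L))
  expect_false(any(detect_chimeras(amps3)$chimeric))
})

test_that("swarm clustering links chains but separates distant amplicons", {
  # pairwise distance > d: every amplicon is its own cluster
  amps <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = c("AAAAAAAA", "TTTTTTTT", "GGGGGGGG"),
                         abundance = c(5L, 4L, 3L))
  sw <- swarm_cluster(amps, d = 1)
  expect_identical(nrow(sw$clusters), 3L)

  # chain A-B-C with consecutive distance 1 joins even though d(A,C) = 2
  amps <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = c("AAAAAAAA", "AAAAAAAT", "AAAAAATT"),
                         abundance = c(5L, 4L, 3L))
  expect_equal(utils::adist("AAAAAAAA", "AAAAAATT")[1, 1], 2)
  sw <- swarm_cluster(amps, d = 1)
  expect_identical(nrow(sw$clusters), 1L)
  expect_identical(sw$clusters$seed_id, "a")
  expect_identical(sw$clusters$total_abundance, 12L)

  # d = 0: clusters are the amplicons themselves
  expect_identical(nrow(swarm_cluster(amps, d = 0)$clusters), 3L)
})

test_that("swarm clusters equal connected components of the edit-distance graph", {
  skip_if_not_installed("igraph")
  withr::local_seed(14)
  for (trial in 1:20) {
    n_seed <- sample(3:6, 1)
    seeds <- replicate(n_seed, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                                     collapse = ""))
    reads <- unlist(lapply(seeds, function(s)
      replicate(sample(3:8, 1), mutate_sequence(s, 0.02, 0.01)$sequence)))
    names(reads) <- sprintf("r%03d", seq_along(reads))
    amps <- dereplicate(reads)
    d <- sample(1:3, 1)
    got <- swarm_cluster(amps, d)$members
    assign_got <- stats::setNames(got$cluster, got$id)
    seqs <- stats::setNames(amps$sequence, amps$id)
    assign_want <- adist_component_partition(seqs, d)
    expect_true(same_partition(assign_got, assign_want))
    # seeds are the abundance maxima of their clusters
    cl <- swarm_cluster(amps, d)$clusters
    for (i in seq_len(nrow(cl))) {
      mem <- got[got$cluster == cl$cluster[i], ]
      expect_gte(cl$total_abundance[i], max(mem$abundance))
      expect_identical(max(mem$abundance),
                       amps$abundance[amps$id == cl$seed_id[i]])
    }
  }
})

test_that("reference filtering keeps members and drops contaminants", {
  withr::local_seed(33)
  ref <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  member <- mutate_sequence(ref, 0.05)$sequence
  alien <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  amps <- tibble::tibble(id = c("m", "x", "r"),
                         sequence = c(member, alien, ref),
                         abundance = c(30L, 20L, 10L))
  sw <- swarm_cluster(amps, d = 1)
  rf <- reference_filter(sw, c(panel1 = ref), min_identity = 0.8)
  kept <- rf$clusters$seed_sequence
  expect_true(ref %in% kept && member %in% kept)
  expect_false(alien %in% kept)
  # threshold 0 retains everything
  rf0 <- reference_filter(sw, c(panel1 = ref), min_identity = 0)
  expect_identical(nrow(rf0$clusters), 3L)
  expect_error(reference_filter(sw, character(0)), "empty")
})

test_that("the two-means abundance gate separates signal from noise", {
  mk <- function(ab) {
    amps <- tibble::tibble(id = sprintf("a%d", seq_along(ab)),
                           sequence = replicate(length(ab),
                             paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                   collapse = "")),
                           abundance = as.integer(ab))
    swarm_cluster(amps[order(-amps$abundance, amps$sequence), ], d = 0)
  }
  withr::local_seed(51)
  # exhaustive 1-D two-group split of log10 abundance by within-group variance
  ab <- c(1000, 900, 800, 5, 3, 2)
  x <- sort(log10(ab))
  wss <- sapply(1:(length(x) - 1), function(k)
    sum((x[1:k] - mean(x[1:k]))^2) + sum((x[-(1:k)] - mean(x[-(1:k)]))^2))
  cut <- which.min(wss)
  expect_identical(length(x) - cut, 3L)       # oracle: top three retained
  ag <- abundance_gate(mk(ab))
  expect_setequal(ag$clusters$total_abundance, c(1000L, 900L, 800L))

  # degenerate cases: single cluster and all-equal abundances are retained
  expect_identical(nrow(abundance_gate(mk(7))$clusters), 1L)
  expect_identical(nrow(abundance_gate(mk(c(5, 5, 5)))$clusters), 3L)
  # close abundance groups are not split (no 10-fold noise mode)
  expect_identical(nrow(abundance_gate(mk(c(60, 40, 30, 12)))$clusters), 4L)
  # fixed_min mode
  expect_identical(nrow(abundance_gate(mk(c(9, 5, 1)), mode = "fixed_min",
                                       min_abundance = 5)$clusters), 2L)
})

test_that("an error-free run recovers exactly the distinct true copies", {
  tr <- strain_community(seed = 7, copies = c(6, 6))
  rs <- read_sim_spec(depth = 50, substitution_error = 0, indel_error = 0,
                      chimera_rate = 0, contaminant_fraction = 0, seed = 3)
  sim <- simulate_hifi_reads(tr, rs)
  cfg <- recovery_config(reference_panel = tr$strain_ancestors)
  rec <- recover_copies(sim$reads, cfg)
  expect_setequal(rec$copies$sequence, unique(tr$copies$sequence))
  expect_null(rec$failed_stage)
  # per-stage conservation: retained + rejected = input
  rej_by_stage <- table(rec$rejected$stage)
  for (i in seq_len(nrow(rec$report))) {
    st <- rec$report$stage[i]
    if (st %in% c("dereplicate", "swarm_cluster")) next  # unit change
    n_rej <- if (st %in% names(rej_by_stage)) rej_by_stage[[st]] else 0L
    expect_identical(rec$report$n_in[i] - rec$report$n_out[i], n_rej)
  }
})

test_that("identical genomic copies collapse into one recovered sequence", {
  tr <- strain_community(seed = 29, copies = c(8, 8))
  tr$copies$sequence[2] <- tr$copies$sequence[1]   # two identical copies
  tr$copies$map[[2]] <- tr$copies$map[[1]]
  rs <- read_sim_spec(depth = 40, substitution_error = 0, indel_error = 0,
                      chimera_rate = 0, contaminant_fraction = 0, seed = 5)
  sim <- simulate_hifi_reads(tr, rs)
  rec <- recover_copies(sim$reads, recovery_config())
  expect_identical(nrow(rec$copies), 7L)
  expect_setequal(rec$copies$sequence, unique(tr$copies$sequence))
})

test_that("swarm output is invariant to read order", {
  tr <- strain_community(seed = 41, copies = c(6, 6))
  rs <- read_sim_spec(depth = 10, seed = 2)
  sim <- simulate_hifi_reads(tr, rs)
  cfg <- recovery_config(swarm_d = 16, representative = "consensus",
                         reference_panel = tr$strain_ancestors)
  rec1 <- recover_copies(sim$reads, cfg)
  shuffled <- sim$reads[sample(length(sim$reads))]
  rec2 <- recover_copies(shuffled, cfg)
  expect_identical(rec1$copies$sequence, rec2$copies$sequence)
})

test_that("an empty surviving stage is reported, not an error", {
  reads <- c(r1 = paste(rep("ACGT", 30), collapse = ""))  # no primers at all
  rec <- recover_copies(reads, recovery_config())
  expect_identical(rec$failed_stage, "trim_primers")
  expect_identical(nrow(rec$copies), 0L)
})
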