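test_that("mutate_sequence is an identity at zero rates and logs every event", {
  r <- mutate_sequence("ACGTACGTAC", 0, 0)
  expect_identical(r$sequence, "ACGTACGTAC")
  expect_identical(nrow(r$log), 0L)

  r <- mutate_sequence(paste(rep("A", 500), collapse = ""), 0.2, 0.05, seed = 3)
  subs <- r$log[r$log$type == "substitution", ]
  expect_true(all(subs$from == "A" & subs$to != "A"))
  ins <- r$log[r$log$type == "insertion", ]
  del <- r$log[r$log$type == "deletion", ]
  expect_identical(nchar(r$sequence), 500L + nrow(ins) - nrow(del))
})

test_that("substitution counts follow the binomial model", {
  L <- 10000
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  r <- mutate_sequence(s, 0.05, 0, seed = 99)
  n_sub <- sum(r$log$type == "substitution")
  expect_lt(abs(n_sub - 500), 3 * sqrt(L * 0.05 * 0.95))
})

test_that("mutation is reproducible from its seed", {
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  a <- mutate_sequence(s, 0.05, 0.01, seed = 11)
  b <- mutate_sequence(s, 0.05, 0.01, seed = 11)
  expect_identical(a, b)
  c <- mutate_sequence(s, 0.05, 0.01, seed = 12)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("a divergence-free community yields identical copies", {
  spec <- community_spec(n_species = 1, strains_per_species = 1,
                         copies_per_strain = c(6, 6),
                         species_divergence = 0, strain_divergence = 0,
                         per_locus_copy_divergence = c(SSU = 0, ITS1 = 0,
                                                       "5.8S" = 0, ITS2 = 0,
                                                       LSU = 0),
                         indel_prob = 0, seed = 5)
  tr <- simulate_community(spec)
  expect_identical(nrow(tr$copies), 6L)
  expect_identical(length(unique(tr$copies$sequence)), 1L)
  expect_identical(tr$copies$sequence[1], tr$strain_ancestors[[1]])
})

test_that("community simulation is deterministic in the master seed", {
  a <- simulate_community(community_spec(seed = 42))
  b <- simulate_community(community_spec(seed = 42))
  expect_identical(a$copies$sequence, b$copies$sequence)
  expect_identical(a$genes$sequence, b$genes$sequence)
  c <- simulate_community(community_spec(seed = 43))
  expect_false(identical(a$copies$sequence, c$copies$sequence))
})

test_that("community structure matches the spec counts and invariants", {
  spec <- community_spec(n_species = 2, strains_per_species = 2, seed = 8)
  tr <- simulate_community(spec)
  expect_identical(length(unique(tr$copies$strain)), 4L)
  expect_true(all(table(tr$copies$strain) >= 6 &
                    table(tr$copies$strain) <= 11))
  expect_true(all(tr$copies$chromosome >= 1 & tr$copies$chromosome <= 6))
  # locus boundaries partition each copy
  for (i in seq_len(nrow(tr$copies))) {
    map <- tr$copies$map[[i]]
    expect_identical(map$start[1], 0L)
    expect_identical(map$end[nrow(map)], nchar(tr$copies$sequence[i]))
    expect_identical(map$start[-1], utils::head(map$end, -1))
  }
  # genes: one per strain per gene, low intraspecific variation by design
  expect_identical(nrow(tr$genes), 3L * 4L)
  expect_error(simulate_community(community_spec(n_species = 0)),
               "at least one species")
})

test_that("intragenomic ITS1 divergence exceeds SSU divergence on truth", {
  tr <- simulate_community(community_spec(seed = 17))
  st <- unique(tr$copies$strain)[1]
  ssu <- pairwise_distance_matrix(copy_locus_seqs(tr, st, "SSU"))
  its <- pairwise_distance_matrix(copy_locus_seqs(tr, st, "ITS1"))
  expect_gt(mean(its[upper.tri(its)]), mean(ssu[upper.tri(ssu)]))
})

test_that("chimera construction honours breakpoint edge cases", {
  a <- "ACGTACGTACGTACGTACGT"
  b <- "TGCATGCATGCATGCATGCA"
  expect_identical(make_chimera(a, b, 0), b)
  expect_identical(make_chimera(a, b, nchar(a)), a)
  expect_identical(make_chimera(a, a, 7), a)
  expect_error(make_chimera(a, b, 21), "breakpoint")
  # homologous parents: prefix comes from a, suffix from b
  withr::local_seed(2)
  p <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  q <- mutate_sequence(p, 0.05)$sequence  # no indels: coordinates shared
  ch <- make_chimera(p, q, 200)
  expect_identical(substr(ch, 1, 200), substr(p, 1, 200))
  expect_identical(substr(ch, 201, nchar(ch)), substr(q, 201, nchar(q)))
})

test_that("error-free reads equal their source copies with primers attached", {
  tr <- strain_community(seed = 3, copies = c(6, 6))
  rs <- read_sim_spec(depth = 4, substitution_error = 0, indel_error = 0,
                      chimera_rate = 0, contaminant_fraction = 0, seed = 9)
  sim <- simulate_hifi_reads(tr, rs)
  expect_true(all(sim$truth$class == "copy"))
  for (i in seq_along(sim$reads)) {
    src <- tr$copies$sequence[tr$copies$copy_id == sim$truth$source[i]]
    fwd_read <- if (sim$truth$orientation[i] == "reverse")
      revcomp(sim$reads[[i]]) else sim$reads[[i]]
    expect_identical(fwd_read,
                     paste0(DEFAULT_FWD_PRIMER, src, revcomp(DEFAULT_REV_PRIMER)))
  }
})

test_that("read counts are conserved and chimera counts follow the binomial", {
  # miniature operon so thousands of reads stay cheap
  spec <- community_spec(n_species = 1, strains_per_species = 1,
                         copies_per_strain = c(4, 4),
                         locus_lengths = c(SSU = 120L, ITS1 = 40L, "5.8S" = 20L,
                                           ITS2 = 40L, LSU = 60L),
                         seed = 31)
  tr <- simulate_community(spec)
  rs <- read_sim_spec(depth = 2500, chimera_rate = 0.05,
                      contaminant_fraction = 0.02, seed = 13)
  sim <- simulate_hifi_reads(tr, rs)
  tab <- table(sim$truth$class)
  expect_identical(length(sim$reads), as.integer(sum(tab)))
  n_src <- tab[["copy"]]
  expect_lt(abs(tab[["chimera"]] - 0.05 * n_src),
            3 * sqrt(n_src * 0.05 * 0.95))
  expect_lt(abs(tab[["contaminant"]] - 0.02 * n_src),
            3 * sqrt(n_src * 0.02 * 0.98))
})

test_that("read simulation is byte-reproducible from its seed", {
  tr <- strain_community(seed = 3, copies = c(6, 6))
  rs <- read_sim_spec(depth = 3, seed = 77)
  a <- simulate_hifi_reads(tr, rs)
  b <- simulate_hifi_reads(tr, rs)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(a$reads, f1, a$phred)
  write_fastq(b$reads, f2, b$phred)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the long-insert variant adds one 100-300 bp ITS block", {
  spec <- community_spec(n_species = 1, strains_per_species = 1,
                         copies_per_strain = c(6, 6), long_insert = TRUE,
                         seed = 19)
  plain <- simulate_community(community_spec(
    n_species = 1, strains_per_species = 1, copies_per_strain = c(6, 6),
    seed = 19))
  tr <- simulate_community(spec)
  dl <- nchar(tr$copies$sequence) - nchar(plain$copies$sequence)
  expect_identical(sum(dl != 0), 1L)
  expect_true(dl[dl != 0] >= 100 && dl[dl != 0] <= 300)
  i <- which(dl != 0)
  expect_identical(tr$copies$map[[i]]$end[5],
                   nchar(tr$copies$sequence[i]))
})
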