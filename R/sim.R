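#' Default synthetic amplification primers
#'
#' Fixed arbitrary 20-mers flanking every simulated amplicon: reads are
#' simulated as `fwd_primer + amplicon + revcomp(rev_primer)` and the recovery
#' pipeline trims the same pair. They are synthetic stand-ins, not the wet-lab
#' AMF primers.
#'
#' @format character scalars.
#' @name default-primers
NULL

#' @rdname default-primers
#' @export
DEFAULT_FWD_PRIMER <- "ATCGGTAAGGTACCTGACGT"

#' @rdname default-primers
#' @export
DEFAULT_REV_PRIMER <- "TGCAATCCGGTTAGACCTGA"

#' Specification of a synthetic multi-copy rDNA community
#'
#' Describes a community of species and strains in which every strain carries
#' several divergent copies of the complete rDNA operon (the situation found
#' in *Rhizophagus irregularis*, whose strains carry 9-11 divergent operon
#' copies spread over 4-6 chromosomes), together with low-variability
#' single-copy protein-coding genes. Per-locus copy divergence defaults encode
#' the empirical ordering SSU lowest, ITS highest.
#'
#' @param n_species number of species.
#' @param strains_per_species strains per species.
#' @param copies_per_strain integer range (length-2) of rDNA copies per strain.
#' @param locus_lengths named locus lengths in bp.
#' @param species_divergence per-site substitution probability from the root
#'   to each species ancestor.
#' @param strain_divergence per-site substitution probability from a species
#'   ancestor to each strain ancestor.
#' @param per_locus_copy_divergence named per-site substitution probabilities
#'   from the strain ancestor to each copy, one per locus.
#' @param indel_prob per-site 1-bp indel probability among copies (copies
#'   only; species/strain ancestors stay indel-free so locus coordinates stay
#'   commensurable across strains).
#' @param gene_specs tibble with columns `gene`, `length`, `intra`, `inter`:
#'   per-gene length and intra-/interspecific per-site divergence for the
#'   companion protein-coding genes (no indels; coding).
#' @param abundance_sdlog sdlog of the lognormal per-copy abundance weights.
#' @param long_insert if `TRUE`, one random copy receives a 100-300 bp
#'   insertion in its ITS region (length-polymorphism variant mode).
#' @param seed master random seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_species = 3,
                           strains_per_species = 2,
                           copies_per_strain = c(6L, 11L),
                           locus_lengths = c(SSU = 1700L, ITS1 = 250L,
                                             "5.8S" = 160L, ITS2 = 250L,
                                             LSU = 800L),
                           species_divergence = 0.05,
                           strain_divergence = 0.01,
                           per_locus_copy_divergence = c(SSU = 0.001,
                                                         ITS1 = 0.05,
                                                         "5.8S" = 0.01,
                                                         ITS2 = 0.05,
                                                         LSU = 0.02),
                           indel_prob = 0.002,
                           gene_specs = tibble::tibble(
                             gene = c("glomalin", "RPB1", "ATPase"),
                             length = c(900L, 1100L, 1000L),
                             intra = 0.004,
                             inter = 0.04),
                           abundance_sdlog = 0.5,
                           long_insert = FALSE,
                           seed = 1L) {
  probs <- c(species_divergence, strain_divergence, per_locus_copy_divergence,
             indel_prob, gene_specs$intra, gene_specs$inter)
  if (any(probs < 0 | probs > 1))
    stop("all divergence/indel probabilities must be in [0, 1]", call. = FALSE)
  if (n_species < 1 || strains_per_species < 1)
    stop("need at least one species and one strain per species", call. = FALSE)
  copies_per_strain <- as.integer(copies_per_strain)
  if (length(copies_per_strain) == 1) copies_per_strain <- rep(copies_per_strain, 2)
  if (any(copies_per_strain < 1 | copies_per_strain > 64) ||
      copies_per_strain[2] < copies_per_strain[1])
    stop("copies_per_strain must be an increasing range within 1-64", call. = FALSE)
  if (any(locus_lengths <= 0) || any(gene_specs$length <= 0))
    stop("lengths must be positive", call. = FALSE)
  miss <- setdiff(names(locus_lengths), names(per_locus_copy_divergence))
  if (length(miss))
    stop("per_locus_copy_divergence missing loci: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(
    n_species = as.integer(n_species),
    strains_per_species = as.integer(strains_per_species),
    copies_per_strain = copies_per_strain,
    locus_lengths = locus_lengths,
    species_divergence = species_divergence,
    strain_divergence = strain_divergence,
    per_locus_copy_divergence = per_locus_copy_divergence,
    indel_prob = indel_prob,
    gene_specs = gene_specs,
    abundance_sdlog = abundance_sdlog,
    long_insert = long_insert,
    seed = as.integer(seed)), class = "community_spec")
}

#' Specification of a simulated HiFi amplicon sequencing run
#'
#' @param depth expected reads per rDNA copy (Poisson mean, scaled by the
#'   copy's abundance weight).
#' @param substitution_error per-base substitution error probability.
#' @param indel_error per-base 1-bp indel error probability.
#' @param chimera_rate fraction of reads formed as two-parent crossovers.
#' @param contaminant_fraction fraction of reads drawn from a divergent
#'   outgroup pool.
#' @param n_contaminant_templates size of the outgroup pool.
#' @param fwd_primer,rev_primer primer pair flanking every amplicon.
#' @param phred constant per-base Phred score of the HiFi-like reads.
#' @param seed random seed.
#' @return a `read_sim_spec` list.
#' @export
read_sim_spec <- function(depth = 30,
                          substitution_error = 0.002,
                          indel_error = 0.0005,
                          chimera_rate = 0.05,
                          contaminant_fraction = 0.02,
                          n_contaminant_templates = 3L,
                          fwd_primer = DEFAULT_FWD_PRIMER,
                          rev_primer = DEFAULT_REV_PRIMER,
                          phred = 40L,
                          seed = 1L) {
  rates <- c(substitution_error, indel_error, chimera_rate, contaminant_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  structure(list(depth = depth, substitution_error = substitution_error,
                 indel_error = indel_error, chimera_rate = chimera_rate,
                 contaminant_fraction = contaminant_fraction,
                 n_contaminant_templates = as.integer(n_contaminant_templates),
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 phred = as.integer(phred), seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Mutate a sequence with independent substitutions and 1-bp indels
#'
#' Each site is substituted with probability `sub_prob` (uniform over the
#' three alternative bases) and independently hit by a 1-bp indel with
#' probability `indel_prob` (insertion before the site or deletion of the
#' site, equiprobable; inserted bases uniform over A/C/G/T). Every event is
#' logged with its position in the *input* sequence.
#'
#' @param seq single ungapped sequence.
#' @param sub_prob per-site substitution probability.
#' @param indel_prob per-site indel probability.
#' @param seed optional seed (current RNG stream used when `NULL`).
#' @return list with `sequence` and `log` (tibble `pos`, `type`, `from`, `to`).
#' @export
mutate_sequence <- function(seq, sub_prob, indel_prob = 0, seed = NULL) {
  if (sub_prob < 0 || sub_prob > 1 || indel_prob < 0 || indel_prob > 1)
    stop("probabilities must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (L == 0)
      return(list(sequence = "", log = tibble::tibble(
        pos = integer(), type = character(), from = character(),
        to = character())))
    logs <- list()
    # substitutions
    hit <- which(runif(L) < sub_prob & ch %in% BASES)
    if (length(hit)) {
      old <- ch[hit]
      alt <- vapply(old, function(b) sample(setdiff(BASES, b), 1), character(1))
      ch[hit] <- alt
      logs[[length(logs) + 1]] <- tibble::tibble(
        pos = hit, type = "substitution", from = old, to = alt)
    }
    # 1-bp indels
    ihit <- which(runif(L) < indel_prob)
    pieces <- as.list(ch)
    if (length(ihit)) {
      ins <- runif(length(ihit)) < 0.5
      ins_base <- sample(BASES, length(ihit), replace = TRUE)
      for (k in seq_along(ihit)) {
        i <- ihit[k]
        if (ins[k]) {
          pieces[[i]] <- c(ins_base[k], pieces[[i]])
          logs[[length(logs) + 1]] <- tibble::tibble(
            pos = i, type = "insertion", from = "", to = ins_base[k])
        } else {
          del <- pieces[[i]][length(pieces[[i]])]
          pieces[[i]] <- pieces[[i]][-length(pieces[[i]])]
          logs[[length(logs) + 1]] <- tibble::tibble(
            pos = i, type = "deletion", from = del, to = "")
        }
      }
    }
    log <- if (length(logs)) dplyr::arrange(dplyr::bind_rows(logs), .data$pos)
           else tibble::tibble(pos = integer(), type = character(),
                               from = character(), to = character())
    list(sequence = paste(unlist(pieces), collapse = ""), log = log)
  })
}

# mutate a set of locus segments with per-locus substitution rates, returning
# the concatenated copy plus its (indel-adjusted) locus map and mutation log.
mutate_operon <- function(segments, rates, indel_prob) {
  out <- character(length(segments))
  lens <- integer(length(segments))
  logs <- list()
  for (i in seq_along(segments)) {
    m <- mutate_sequence(segments[[i]], rates[[names(segments)[i]]], indel_prob)
    out[i] <- m$sequence
    lens[i] <- nchar(m$sequence)
    if (nrow(m$log)) {
      m$log$locus <- names(segments)[i]
      logs[[length(logs) + 1]] <- m$log
    }
  }
  ends <- cumsum(lens)
  list(sequence = paste(out, collapse = ""),
       map = locus_map(names(segments), c(0L, utils::head(ends, -1)), ends),
       log = if (length(logs)) dplyr::bind_rows(logs) else NULL)
}

#' Simulate a multi-copy rDNA community
#'
#' Generates a root operon, derives species ancestors, strain ancestors, and
#' star-shaped copies within each strain (no within-strain tree: copy
#' variation in AMF genomes is unstructured), applying per-locus substitution
#' rates and 1-bp indels at the copy level only. Companion protein-coding
#' genes are generated analogously with their own intra/inter rates and no
#' indels. Fully reproducible from `spec$seed`.
#'
#' @param spec a [community_spec()].
#' @return a `synthetic_truth` list with elements `spec`, `root`,
#'   `species_ancestors`, `strain_ancestors` (named character vectors),
#'   `copies` (tibble: `copy_id`, `species`, `strain`, `chromosome`, `weight`,
#'   `sequence`, list-columns `map` and `mutations`), `genes` (tibble: `gene`,
#'   `id`, `species`, `strain`, `sequence`), and `root_map` (the reference
#'   locus map).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    ll <- spec$locus_lengths
    root_seg <- lapply(ll, random_dna)
    names(root_seg) <- names(ll)
    root <- paste(unlist(root_seg), collapse = "")
    root_map <- default_locus_map(ll)
    sp_ids <- sprintf("sp%02d", seq_len(spec$n_species))
    species_anc <- character(0)
    strain_anc <- character(0)
    copies <- list()
    sp_seg <- list()
    for (s in seq_len(spec$n_species)) {
      seg_s <- lapply(root_seg, function(x)
        mutate_sequence(x, spec$species_divergence)$sequence)
      sp_seg[[sp_ids[s]]] <- seg_s
      species_anc[sp_ids[s]] <- paste(unlist(seg_s), collapse = "")
      for (st in seq_len(spec$strains_per_species)) {
        st_id <- sprintf("%s_st%02d", sp_ids[s], st)
        seg_t <- lapply(seg_s, function(x)
          mutate_sequence(x, spec$strain_divergence)$sequence)
        strain_anc[st_id] <- paste(unlist(seg_t), collapse = "")
        krange <- spec$copies_per_strain[1]:spec$copies_per_strain[2]
        k <- krange[sample.int(length(krange), 1)]
        n_chrom <- sample(4:6, 1)
        w <- exp(rnorm(k, 0, spec$abundance_sdlog))
        w <- w / mean(w)
        for (cp in seq_len(k)) {
          op <- mutate_operon(seg_t, spec$per_locus_copy_divergence,
                              spec$indel_prob)
          copies[[length(copies) + 1]] <- tibble::tibble(
            copy_id = sprintf("%s_c%02d", st_id, cp),
            species = sp_ids[s], strain = st_id,
            chromosome = sample.int(n_chrom, 1),
            weight = w[cp], sequence = op$sequence,
            map = list(op$map), mutations = list(op$log))
        }
      }
    }
    copies <- dplyr::bind_rows(copies)
    if (spec$long_insert) {
      # length-polymorphism variant: one long block inside a random copy's ITS
      i <- sample.int(nrow(copies), 1)
      map <- copies$map[[i]]
      its <- map[map$locus == "ITS1", ]
      block <- random_dna(sample(100:300, 1))
      at_range <- its$start:(its$end - 1)
      at <- at_range[sample.int(length(at_range), 1)]
      s <- copies$sequence[[i]]
      copies$sequence[[i]] <- paste0(substr(s, 1, at), block,
                                     substr(s, at + 1, nchar(s)))
      shift <- nchar(block)
      map$end[map$locus == "ITS1"] <- map$end[map$locus == "ITS1"] + shift
      after <- which(map$start >= its$end)
      map$start[after] <- map$start[after] + shift
      map$end[after] <- map$end[after] + shift
      copies$map[[i]] <- locus_map(map$locus, map$start, map$end)
    }
    genes <- list()
    for (g in seq_len(nrow(spec$gene_specs))) {
      gs <- spec$gene_specs[g, ]
      groot <- random_dna(gs$length)
      for (s in seq_len(spec$n_species)) {
        ganc <- mutate_sequence(groot, gs$inter)$sequence
        for (st in seq_len(spec$strains_per_species)) {
          st_id <- sprintf("%s_st%02d", sp_ids[s], st)
          genes[[length(genes) + 1]] <- tibble::tibble(
            gene = gs$gene, id = paste(gs$gene, st_id, sep = "_"),
            species = sp_ids[s], strain = st_id,
            sequence = mutate_sequence(ganc, gs$intra)$sequence)
        }
      }
    }
    structure(list(spec = spec, root = root, root_map = root_map,
                   species_ancestors = species_anc,
                   strain_ancestors = strain_anc,
                   copies = copies, genes = dplyr::bind_rows(genes)),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d species, %d strains, %d rDNA copies, %d gene sequences\n",
    length(x$species_ancestors), length(x$strain_ancestors), nrow(x$copies),
    nrow(x$genes)))
  invisible(x)
}

#' Construct a two-parent chimera
#'
#' Prefix of `parent_a` up to `breakpoint` (in `parent_a` residues) joined to
#' the suffix of `parent_b` from the homologous position, found through a
#' global alignment of the two parents (nearest ungapped coordinate).
#'
#' @param parent_a,parent_b ungapped parent sequences.
#' @param breakpoint integer in `[0, nchar(parent_a)]`; 0 returns `parent_b`,
#'   the full length returns `parent_a`.
#' @param scores,band passed to [align_pair()].
#' @return the chimeric sequence (single string).
#' @export
make_chimera <- function(parent_a, parent_b, breakpoint,
                         scores = default_scores(), band = NULL) {
  la <- nchar(parent_a)
  if (breakpoint < 0 || breakpoint > la)
    stop("breakpoint must be in [0, ", la, "]", call. = FALSE)
  if (breakpoint == 0) return(toupper(parent_b))
  if (breakpoint == la) return(toupper(parent_a))
  aln <- align_pair(parent_a, parent_b, scores = scores, band = band)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  col <- which(cumsum(ca != "-") == breakpoint)[1]  # column of a's bp-th residue
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  paste0(paste(ca[seq_len(col)][ca[seq_len(col)] != "-"], collapse = ""),
         paste(cb[-seq_len(col)][cb[-seq_len(col)] != "-"], collapse = ""))
}

#' Simulate HiFi amplicon reads from a synthetic community
#'
#' Per-copy read counts are Poisson with mean `depth` times the copy's
#' abundance weight; chimeric reads (two-parent crossovers at a uniform
#' breakpoint) and contaminant reads (from a pool of unrelated random
#' templates) are added as binomial fractions of the source read count. Every
#' read is flanked by the primer pair, hit by substitution/indel errors, and
#' reverse-complemented with probability one half. Qualities are a constant
#' high Phred score, as in HiFi consensus reads.
#'
#' @param truth a `synthetic_truth` from [simulate_community()].
#' @param rspec a [read_sim_spec()].
#' @return list with `reads` (named character vector), `phred` (constant
#'   score), and `truth` (tibble: `read_id`, `class` = copy|chimera|
#'   contaminant, `source`, `parent_a`, `parent_b`, `breakpoint`,
#'   `orientation`).
#' @export
simulate_hifi_reads <- function(truth, rspec) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(rspec, "read_sim_spec"))
  if (nrow(truth$copies) == 0) stop("truth has no copies", call. = FALSE)
  with_seed(rspec$seed, {
    cp <- truth$copies
    counts <- rpois(nrow(cp), rspec$depth * cp$weight)
    n_src <- sum(counts)
    n_chim <- rbinom(1, n_src, rspec$chimera_rate)
    n_cont <- rbinom(1, n_src, rspec$contaminant_fraction)
    med_len <- as.integer(stats::median(nchar(cp$sequence)))
    pool <- vapply(seq_len(max(1L, rspec$n_contaminant_templates)),
                   function(i) random_dna(med_len), character(1))
    names(pool) <- sprintf("contaminant%02d", seq_along(pool))
    templates <- character(0)
    info <- list()
    # source reads
    for (i in seq_len(nrow(cp))) {
      if (counts[i] == 0) next
      templates <- c(templates, rep(cp$sequence[i], counts[i]))
      info[[length(info) + 1]] <- tibble::tibble(
        class = "copy", source = rep(cp$copy_id[i], counts[i]),
        parent_a = NA_character_, parent_b = NA_character_,
        breakpoint = NA_integer_)
    }
    # chimeras
    if (n_chim > 0) {
      for (k in seq_len(n_chim)) {
        pr <- sample.int(nrow(cp), 2)
        bp <- sample.int(nchar(cp$sequence[pr[1]]) - 1, 1)
        templates <- c(templates,
                       make_chimera(cp$sequence[pr[1]], cp$sequence[pr[2]], bp,
                                    band = 200))
        info[[length(info) + 1]] <- tibble::tibble(
          class = "chimera", source = NA_character_,
          parent_a = cp$copy_id[pr[1]], parent_b = cp$copy_id[pr[2]],
          breakpoint = bp)
      }
    }
    # contaminants
    if (n_cont > 0) {
      pick <- sample.int(length(pool), n_cont, replace = TRUE)
      templates <- c(templates, unname(pool[pick]))
      info[[length(info) + 1]] <- tibble::tibble(
        class = "contaminant", source = names(pool)[pick],
        parent_a = NA_character_, parent_b = NA_character_,
        breakpoint = NA_integer_)
    }
    info <- dplyr::bind_rows(info)
    n <- length(templates)
    reads <- character(n)
    flip <- logical(n)
    for (r in seq_len(n)) {
      raw <- paste0(rspec$fwd_primer, templates[r], revcomp(rspec$rev_primer))
      mut <- mutate_sequence(raw, rspec$substitution_error, rspec$indel_error)
      flip[r] <- runif(1) < 0.5
      reads[r] <- if (flip[r]) revcomp(mut$sequence) else mut$sequence
    }
    ids <- sprintf("read%06d", seq_len(n))
    names(reads) <- ids
    info$read_id <- ids
    info$orientation <- ifelse(flip, "reverse", "forward")
    list(reads = reads, phred = rspec$phred,
         truth = info[, c("read_id", "class", "source", "parent_a",
                          "parent_b", "breakpoint", "orientation")])
  })
}
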