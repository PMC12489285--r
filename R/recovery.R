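#' Configuration of the rDNA copy-recovery pipeline
#'
#' Parameters for the HiFi amplicon pipeline: primer trimming, length/N
#' filtering, dereplication, two-parent chimera removal, swarm agglomeration,
#' reference-panel identity filtering, and abundance gating.
#'
#' @param fwd_primer,rev_primer primer pair (the read is expected to start
#'   with `fwd_primer` and end with `revcomp(rev_primer)`, in either
#'   orientation).
#' @param max_mismatch maximum substitutions tolerated per primer (no indels).
#' @param min_len,max_len retained insert length window in bp.
#' @param swarm_d swarm linking radius (edit distance), `0..16`. `d = 1` is
#'   the classical choice for near-exact amplicons; with error-laden reads a
#'   larger radius on the order of twice the expected per-read error count is
#'   needed for reads of one copy to agglomerate.
#' @param chimera_skew minimum parent/candidate abundance ratio for a
#'   candidate to be tested against a parent pair.
#' @param chimera_min_gain minimum identity gain of the best two-parent
#'   crossover model over the best single parent.
#' @param chimera_model_identity minimum candidate identity to the crossover
#'   model.
#' @param reference_panel named character vector (or XStringSet) of trusted
#'   reference sequences; clusters whose seed falls below
#'   `min_reference_identity` to every panel sequence are discarded
#'   (contaminant screening). `NULL` skips the stage.
#' @param min_reference_identity identity threshold in `[0, 1]`.
#' @param abundance_gate_mode `"two_means"` (1-D 2-means on log10 cluster
#'   abundance, keep the high group) or `"fixed_min"`.
#' @param min_abundance minimum cluster abundance for `fixed_min`.
#' @param representative `"seed"` (highest-abundance amplicon of the cluster)
#'   or `"consensus"` (abundance-weighted column consensus of the members
#'   projected onto the seed, which also repairs seed indel errors).
#' @param scores alignment scores used by the chimera and reference stages.
#' @return a `recovery_config` list.
#' @export
recovery_config <- function(fwd_primer = DEFAULT_FWD_PRIMER,
                            rev_primer = DEFAULT_REV_PRIMER,
                            max_mismatch = 2L,
                            min_len = 2300L, max_len = 3300L,
                            swarm_d = 1L,
                            chimera_skew = 2.0,
                            chimera_min_gain = 0.02,
                            chimera_model_identity = 0.99,
                            reference_panel = NULL,
                            min_reference_identity = 0.8,
                            abundance_gate_mode = c("two_means", "fixed_min"),
                            min_abundance = 2L,
                            representative = c("seed", "consensus"),
                            scores = default_scores()) {
  abundance_gate_mode <- match.arg(abundance_gate_mode)
  representative <- match.arg(representative)
  swarm_d <- as.integer(swarm_d)
  if (swarm_d < 0 || swarm_d > 16)
    stop("swarm_d must be in 0..16", call. = FALSE)
  if (min_reference_identity < 0 || min_reference_identity > 1)
    stop("min_reference_identity must be in [0, 1]", call. = FALSE)
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  if (!is.null(reference_panel))
    reference_panel <- as_seq_chr(reference_panel, require_names = FALSE)
  structure(list(fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 max_mismatch = as.integer(max_mismatch),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 swarm_d = swarm_d, chimera_skew = chimera_skew,
                 chimera_min_gain = chimera_min_gain,
                 chimera_model_identity = chimera_model_identity,
                 reference_panel = reference_panel,
                 min_reference_identity = min_reference_identity,
                 abundance_gate_mode = abundance_gate_mode,
                 min_abundance = as.integer(min_abundance),
                 representative = representative,
                 scores = check_scores(scores)), class = "recovery_config")
}

#' Trim amplification primers from reads
#'
#' Locates the forward primer at the 5' end and the reverse complement of the
#' reverse primer at the 3' end (anchored, substitutions only, at most
#' `max_mismatch` each), trying the read in both orientations, and returns the
#' insert between the primers. Failure is a result (reason code), not an
#' error.
#'
#' @param reads named character vector of ungapped reads.
#' @param config a [recovery_config()].
#' @return list with `trimmed` (named character vector, forward orientation)
#'   and `rejected` (tibble `id`, `reason` with codes `no_fwd`, `no_rev`,
#'   `too_short`).
#' @export
trim_primers <- function(reads, config) {
  reads <- as_seq_chr(reads)
  fwd <- config$fwd_primer
  rcr <- revcomp(config$rev_primer)
  lf <- nchar(fwd); lr <- nchar(rcr); mm <- config$max_mismatch
  try_one <- function(x) {
    n <- nchar(x)
    if (n < lf + lr + 1) return(list(ok = FALSE, reason = "too_short"))
    fwd_ok <- hamming(substr(x, 1, lf), fwd) <= mm
    rev_ok <- hamming(substr(x, n - lr + 1, n), rcr) <= mm
    if (fwd_ok && rev_ok)
      return(list(ok = TRUE, insert = substr(x, lf + 1, n - lr)))
    list(ok = FALSE, reason = if (!fwd_ok) "no_fwd" else "no_rev")
  }
  trimmed <- character(0)
  rej <- list()
  for (i in seq_along(reads)) {
    r1 <- try_one(reads[[i]])
    if (r1$ok) {
      trimmed[names(reads)[i]] <- r1$insert
      next
    }
    r2 <- try_one(revcomp(reads[[i]]))
    if (r2$ok) {
      trimmed[names(reads)[i]] <- r2$insert
    } else {
      rej[[length(rej) + 1]] <- tibble::tibble(
        id = names(reads)[i],
        reason = if (r1$reason == "no_rev" || r2$reason == "no_rev")
          "no_rev" else r1$reason)
    }
  }
  list(trimmed = trimmed,
       rejected = if (length(rej)) dplyr::bind_rows(rej)
                  else tibble::tibble(id = character(), reason = character()))
}

#' Length and N filter
#'
#' Keeps reads whose length lies in `[min_len, max_len]` and which contain no
#' ambiguous base (N).
#'
#' @param reads named character vector.
#' @param min_len,max_len inclusive length window.
#' @return list with `retained` and `rejected` (tibble `id`, `reason`).
#' @export
length_filter <- function(reads, min_len, max_len) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  reads <- as_seq_chr(reads)
  n <- nchar(reads)
  has_n <- grepl("N", reads, fixed = TRUE)
  bad_len <- n < min_len | n > max_len
  keep <- !bad_len & !has_n
  rejected <- tibble::tibble(
    id = names(reads)[!keep],
    reason = ifelse(bad_len[!keep], "length", "ambiguous_base"))
  list(retained = reads[keep], rejected = rejected)
}

#' Dereplicate reads into unique amplicons
#'
#' Exact-sequence grouping; amplicons are sorted by abundance (descending)
#' with ties broken by the sequence itself (ascending), which fixes the
#' deterministic processing order of all downstream stages.
#'
#' @param reads named character vector.
#' @return tibble with `id` (stable `ampNNNNN` identifiers in sorted order),
#'   `sequence`, `abundance`.
#' @export
dereplicate <- function(reads) {
  if (length(reads) == 0)
    return(tibble::tibble(id = character(), sequence = character(),
                          abundance = integer()))
  reads <- as_seq_chr(reads)
  tb <- table(unname(reads))
  out <- tibble::tibble(sequence = names(tb), abundance = as.integer(tb))
  out <- out[order(-out$abundance, out$sequence), ]
  out$id <- sprintf("amp%05d", seq_len(nrow(out)))
  out[, c("id", "sequence", "abundance")]
}

# per-candidate-position match profile against one parent; identities are
# expressed per candidate base so single-parent and crossover-model scores
# share a denominator.
match_profile <- function(candidate, parent, scores, band = NULL) {
  aln <- align_pair(candidate, parent, scores = scores, band = band)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  idx <- ca != "-"
  (ca == cb)[idx]                        # logical, length = nchar(candidate)
}

#' Detect two-parent chimeric amplicons
#'
#' Processes dereplicated amplicons in decreasing abundance. Each candidate is
#' tested against every pair of already-accepted amplicons with abundance at
#' least `skew` times its own: the candidate is aligned to both parents, all
#' crossover positions are scanned (prefix of one parent's match profile plus
#' suffix of the other's), and the candidate is called chimeric when the best
#' crossover model explains it better than the best single parent by at least
#' `min_gain` and reaches `model_identity`. Accepted (clean) amplicons become
#' eligible parents for later candidates.
#'
#' @param amplicons dereplicated amplicon tibble (see [dereplicate()]).
#' @param skew parent/candidate abundance ratio (default 2).
#' @param min_gain identity gain threshold (default 0.02).
#' @param model_identity minimum crossover-model identity (default 0.99).
#' @param scores alignment scores.
#' @param band alignment band (`NULL` = automatic).
#' @return tibble with `id`, `chimeric`, `parent_a`, `parent_b`,
#'   `breakpoint` (candidate position, 1-based last base of the 5' parent),
#'   `model_identity`, `best_single_identity`.
#' @export
detect_chimeras <- function(amplicons, skew = 2.0, min_gain = 0.02,
                            model_identity = 0.99, scores = default_scores(),
                            band = NULL) {
  n <- nrow(amplicons)
  out <- tibble::tibble(id = amplicons$id,
                        chimeric = rep(FALSE, n),
                        parent_a = NA_character_, parent_b = NA_character_,
                        breakpoint = NA_integer_,
                        model_identity = NA_real_,
                        best_single_identity = NA_real_)
  if (n == 0) return(out)
  accepted <- integer(0)
  for (i in seq_len(n)) {
    cand <- amplicons$sequence[i]
    Lc <- nchar(cand)
    par_idx <- accepted[amplicons$abundance[accepted] >=
                          skew * amplicons$abundance[i]]
    if (length(par_idx) >= 2) {
      profs <- lapply(par_idx, function(j)
        match_profile(cand, amplicons$sequence[j], scores, band))
      singles <- vapply(profs, function(p) sum(p) / Lc, numeric(1))
      best_single <- max(singles)
      cums <- lapply(profs, cumsum)
      tots <- vapply(cums, function(x) x[Lc], numeric(1))
      best <- list(score = -Inf, a = NA, b = NA, bp = NA)
      np <- length(par_idx)
      for (p in seq_len(np - 1)) {
        for (q in (p + 1):np) {
          # crossover p -> q and q -> p over all breakpoints 0..Lc
          m_pq <- c(tots[q], cums[[p]] + tots[q] - cums[[q]])
          m_qp <- c(tots[p], cums[[q]] + tots[p] - cums[[p]])
          w_pq <- which.max(m_pq); w_qp <- which.max(m_qp)
          if (m_pq[w_pq] >= m_qp[w_qp]) {
            sc <- m_pq[w_pq] / Lc
            if (sc > best$score)
              best <- list(score = sc, a = par_idx[p], b = par_idx[q],
                           bp = w_pq - 1L)
          } else {
            sc <- m_qp[w_qp] / Lc
            if (sc > best$score)
              best <- list(score = sc, a = par_idx[q], b = par_idx[p],
                           bp = w_qp - 1L)
          }
        }
      }
      out$best_single_identity[i] <- best_single
      out$model_identity[i] <- best$score
      if (best$score >= best_single + min_gain &&
          best$score >= model_identity) {
        out$chimeric[i] <- TRUE
        out$parent_a[i] <- amplicons$id[best$a]
        out$parent_b[i] <- amplicons$id[best$b]
        out$breakpoint[i] <- as.integer(best$bp)
      }
    }
    if (!out$chimeric[i]) accepted <- c(accepted, i)
  }
  out
}

#' Swarm-style agglomerative clustering of amplicons
#'
#' Iterated agglomeration without a global radius: the highest-abundance
#' unassigned amplicon seeds a cluster, which grows breadth-first by adding
#' every unassigned amplicon within edit distance `d` (unit-cost Levenshtein)
#' of any current member; the cluster is closed and the process repeats.
#' Deterministic given the dereplication sort order. `d = 0` returns one
#' cluster per amplicon.
#'
#' @param amplicons dereplicated amplicon tibble (sorted; see [dereplicate()]).
#' @param d linking radius (edit distance), `0..16`.
#' @return list with `clusters` (tibble `cluster`, `seed_id`, `seed_sequence`,
#'   `n_members`, `total_abundance`) and `members` (the amplicon tibble plus a
#'   `cluster` column).
#' @export
swarm_cluster <- function(amplicons, d = 1L) {
  d <- as.integer(d)
  if (d < 0 || d > 16) stop("d must be in 0..16", call. = FALSE)
  n <- nrow(amplicons)
  if (n == 0)
    return(list(clusters = tibble::tibble(cluster = integer(),
                                          seed_id = character(),
                                          seed_sequence = character(),
                                          n_members = integer(),
                                          total_abundance = integer()),
                members = dplyr::mutate(amplicons, cluster = integer(0))))
  cl <- if (d == 0) seq_len(n) else cpp_swarm_components(amplicons$sequence, d)
  members <- dplyr::mutate(amplicons, cluster = as.integer(cl))
  clusters <- members |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(seed_id = .data$id[1],
                     seed_sequence = .data$sequence[1],
                     n_members = dplyr::n(),
                     total_abundance = sum(.data$abundance),
                     .groups = "drop") |>
    dplyr::arrange(.data$cluster)
  list(clusters = clusters, members = members)
}

# identity of a cluster seed to the best panel sequence. A bounded-edit screen
# (identity >= 1 - d/maxlen) decides clear cases; borderline seeds fall back
# to an exact banded global alignment with matches/columns identity.
panel_identity <- function(seq, panel, min_identity, scores) {
  best_est <- -Inf
  best_ref <- NULL
  for (ref in panel) {
    ml <- max(nchar(seq), nchar(ref))
    kmax <- as.integer(ceiling((1 - max(0, min_identity - 0.1)) * ml))
    # staged radius: clear members resolve at a narrow band, clear
    # contaminants abandon it almost immediately
    k <- min(kmax, max(64L, as.integer(ceiling(0.05 * ml))))
    d <- cpp_bounded_edit(seq, ref, k)
    if (d > k && k < kmax) d <- cpp_bounded_edit(seq, ref, kmax)
    est <- 1 - d / ml
    if (est > best_est) { best_est <- est; best_ref <- ref }
  }
  if (best_est >= min_identity) return(best_est)
  if (best_est < min_identity - 0.05) return(best_est)
  aln <- align_pair(seq, best_ref, scores = scores)
  alignment_identity(aln)
}

#' Reference-panel identity filter
#'
#' Keeps clusters whose seed reaches at least `min_identity` to the best
#' sequence of a trusted reference panel (global-alignment identity,
#' matches over alignment columns); contaminant clusters from unrelated
#' organisms fall far below the threshold.
#'
#' @param swarm result of [swarm_cluster()].
#' @param panel character vector / XStringSet of reference sequences.
#' @param min_identity identity threshold (default 0.8).
#' @param scores alignment scores.
#' @return `swarm` with non-matching clusters removed; discarded cluster ids
#'   are recorded in the `discarded` element.
#' @export
reference_filter <- function(swarm, panel, min_identity = 0.8,
                             scores = default_scores()) {
  panel <- as_seq_chr(panel, require_names = FALSE)
  if (length(panel) == 0) stop("reference panel is empty", call. = FALSE)
  ident <- vapply(swarm$clusters$seed_sequence, panel_identity,
                  numeric(1), panel = panel, min_identity = min_identity,
                  scores = scores, USE.NAMES = FALSE)
  keep <- ident >= min_identity
  list(clusters = swarm$clusters[keep, ],
       members = swarm$members[swarm$members$cluster %in%
                                 swarm$clusters$cluster[keep], ],
       discarded = swarm$clusters$cluster[!keep],
       identity = ident)
}

#' Abundance gate for swarm clusters
#'
#' Separates true-copy clusters from low-abundance noise. `two_means` runs
#' 1-D 2-means on log10 total abundance (centers initialized at the minimum
#' and maximum, Lloyd iterations to convergence) and retains the higher-mean
#' group; if all abundances are equal every cluster is retained. `fixed_min`
#' retains clusters with total abundance at least `min_abundance`.
#'
#' @param swarm result of [swarm_cluster()] (or [reference_filter()]).
#' @param mode `"two_means"` or `"fixed_min"`.
#' @param min_abundance threshold for `fixed_min`.
#' @param min_separation minimum distance between the two group centers, in
#'   log10 abundance units, for the `two_means` split to be considered real
#'   (default 1, i.e. a 10-fold abundance gap). When the groups are closer
#'   than this the data contain no noise mode and every cluster is retained.
#' @return `swarm` restricted to retained clusters, with `discarded` ids.
#' @export
abundance_gate <- function(swarm, mode = c("two_means", "fixed_min"),
                           min_abundance = 2L, min_separation = 1) {
  mode <- match.arg(mode)
  ab <- swarm$clusters$total_abundance
  if (length(ab) == 0) return(c(swarm[c("clusters", "members")],
                                list(discarded = integer())))
  keep <- if (mode == "fixed_min") {
    ab >= min_abundance
  } else if (length(unique(ab)) == 1) {
    rep(TRUE, length(ab))
  } else {
    x <- log10(ab)
    centers <- c(min(x), max(x))
    for (it in 1:100) {
      grp <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
      new <- c(mean(x[grp == 1L]), mean(x[grp == 2L]))
      if (anyNA(new) || isTRUE(all.equal(new, centers))) break
      centers <- new
    }
    if (abs(centers[1] - centers[2]) < min_separation)
      rep(TRUE, length(ab))
    else
      grp == which.max(centers)
  }
  list(clusters = swarm$clusters[keep, ],
       members = swarm$members[swarm$members$cluster %in%
                                 swarm$clusters$cluster[keep], ],
       discarded = swarm$clusters$cluster[!keep])
}

# abundance-weighted column consensus of cluster members projected onto the
# seed; repairs seed substitution errors and, via junction insertions, seed
# deletion errors.
cluster_consensus <- function(member_seqs, member_ab, seed, scores, band) {
  L <- nchar(seed)
  votes <- matrix(0, nrow = 5, ncol = L,
                  dimnames = list(c(BASES, "-"), NULL))
  ins_tab <- list()                      # junction -> named weight vector
  total_w <- 0
  for (k in seq_along(member_seqs)) {
    w <- member_ab[k]
    total_w <- total_w + w
    if (member_seqs[k] == seed) {
      idx <- cbind(match(strsplit(seed, "", fixed = TRUE)[[1]], rownames(votes)),
                   seq_len(L))
      votes[idx] <- votes[idx] + w
      next
    }
    aln <- align_pair(seed, member_seqs[k], scores = scores, band = band)
    sa <- strsplit(aln$a, "", fixed = TRUE)[[1]]
    ma <- strsplit(aln$b, "", fixed = TRUE)[[1]]
    sp <- cumsum(sa != "-")
    res <- sa != "-"
    m_idx <- match(ma[res], rownames(votes))
    votes[cbind(m_idx, sp[res])] <- votes[cbind(m_idx, sp[res])] + w
    gap_cols <- which(!res)
    if (length(gap_cols)) {
      for (j in split(gap_cols, sp[gap_cols])) {
        junction <- as.character(sp[j[1]])
        str <- paste(ma[j], collapse = "")
        cur <- ins_tab[[junction]]
        if (is.null(cur)) cur <- numeric(0)
        cur[str] <- (if (is.na(cur[str])) 0 else cur[str]) + w
        ins_tab[[junction]] <- cur
      }
    }
  }
  cons <- rownames(votes)[apply(votes, 2, which.max)]
  out <- character(0)
  for (p in 0:L) {
    junc <- ins_tab[[as.character(p)]]
    if (!is.null(junc) && max(junc) > total_w / 2)
      out <- c(out, names(junc)[which.max(junc)])
    if (p < L && cons[p + 1] != "-") out <- c(out, cons[p + 1])
  }
  paste(out, collapse = "")
}

#' Recover rDNA copy sequences from HiFi amplicon reads
#'
#' Full pipeline: primer trimming, length/N filtering, dereplication,
#' two-parent chimera removal, swarm agglomeration, reference-panel identity
#' filtering (if a panel is configured), and abundance gating. Each surviving
#' cluster yields one copy sequence - its seed, or the member consensus when
#' `config$representative = "consensus"`. Identical genomic copies collapse
#' into one recovered sequence (they are indistinguishable by amplicon
#' sequencing).
#'
#' @param reads named character vector of raw reads (with primers).
#' @param config a [recovery_config()].
#' @return list with `copies` (tibble `id`, `sequence`, `abundance`,
#'   `n_members`), `report` (tibble `stage`, `n_in`, `n_out`; units are reads
#'   up to dereplication and clusters afterwards), `rejected` (tibble `id`,
#'   `stage`, `reason`), and `chimeras` (the [detect_chimeras()] verdicts).
#'   If some stage leaves nothing, `copies` is empty and `failed_stage` names
#'   the stage.
#' @export
recover_copies <- function(reads, config) {
  stopifnot(inherits(config, "recovery_config"))
  report <- list()
  rejected <- list()
  note <- function(stage, n_in, n_out)
    report[[length(report) + 1]] <<- tibble::tibble(
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out))
  empty_result <- function(stage) {
    list(copies = tibble::tibble(id = character(), sequence = character(),
                                 abundance = integer(), n_members = integer()),
         report = dplyr::bind_rows(report),
         rejected = dplyr::bind_rows(rejected),
         chimeras = NULL, failed_stage = stage)
  }

  tr <- trim_primers(reads, config)
  note("trim_primers", length(reads), length(tr$trimmed))
  if (nrow(tr$rejected))
    rejected[[length(rejected) + 1]] <-
      dplyr::mutate(tr$rejected, stage = "trim_primers")
  if (length(tr$trimmed) == 0) return(empty_result("trim_primers"))

  lf <- length_filter(tr$trimmed, config$min_len, config$max_len)
  note("length_filter", length(tr$trimmed), length(lf$retained))
  if (nrow(lf$rejected))
    rejected[[length(rejected) + 1]] <-
      dplyr::mutate(lf$rejected, stage = "length_filter")
  if (length(lf$retained) == 0) return(empty_result("length_filter"))

  amps <- dereplicate(lf$retained)
  note("dereplicate", length(lf$retained), nrow(amps))

  chim <- detect_chimeras(amps, skew = config$chimera_skew,
                          min_gain = config$chimera_min_gain,
                          model_identity = config$chimera_model_identity,
                          scores = config$scores)
  clean <- amps[!chim$chimeric, ]
  note("detect_chimeras", nrow(amps), nrow(clean))
  if (any(chim$chimeric))
    rejected[[length(rejected) + 1]] <- tibble::tibble(
      id = chim$id[chim$chimeric], stage = "detect_chimeras",
      reason = "chimeric")
  if (nrow(clean) == 0) return(empty_result("detect_chimeras"))

  sw <- swarm_cluster(clean, d = config$swarm_d)
  note("swarm_cluster", nrow(clean), nrow(sw$clusters))

  if (!is.null(config$reference_panel)) {
    rf <- reference_filter(sw, config$reference_panel,
                           min_identity = config$min_reference_identity,
                           scores = config$scores)
    note("reference_filter", nrow(sw$clusters), nrow(rf$clusters))
    if (length(rf$discarded))
      rejected[[length(rejected) + 1]] <- tibble::tibble(
        id = sw$clusters$seed_id[sw$clusters$cluster %in% rf$discarded],
        stage = "reference_filter", reason = "low_reference_identity")
    sw <- rf
    if (nrow(sw$clusters) == 0) return(empty_result("reference_filter"))
  }

  ag <- abundance_gate(sw, mode = config$abundance_gate_mode,
                       min_abundance = config$min_abundance)
  note("abundance_gate", nrow(sw$clusters), nrow(ag$clusters))
  if (length(ag$discarded))
    rejected[[length(rejected) + 1]] <- tibble::tibble(
      id = sw$clusters$seed_id[sw$clusters$cluster %in% ag$discarded],
      stage = "abundance_gate", reason = "low_abundance")
  if (nrow(ag$clusters) == 0) return(empty_result("abundance_gate"))

  seqs <- character(nrow(ag$clusters))
  for (i in seq_len(nrow(ag$clusters))) {
    if (config$representative == "seed" || ag$clusters$n_members[i] < 3) {
      seqs[i] <- ag$clusters$seed_sequence[i]
    } else {
      mem <- ag$members[ag$members$cluster == ag$clusters$cluster[i], ]
      seqs[i] <- cluster_consensus(mem$sequence, mem$abundance,
                                   ag$clusters$seed_sequence[i],
                                   config$scores,
                                   band = max(64L, 4L * config$swarm_d))
    }
  }
  copies <- tibble::tibble(
    id = sprintf("copy%03d;size=%d", seq_len(nrow(ag$clusters)),
                 ag$clusters$total_abundance),
    sequence = seqs,
    abundance = ag$clusters$total_abundance,
    n_members = ag$clusters$n_members)
  list(copies = copies, report = dplyr::bind_rows(report),
       rejected = if (length(rejected)) dplyr::bind_rows(rejected)
                  else tibble::tibble(id = character(), stage = character(),
                                      reason = character()),
       chimeras = chim, failed_stage = NULL)
}
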