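## tagcall: per-individual unique-tag collapsing, quality-weighted
## clustering into candidate RAD loci, allele calling with error
## correction, and paired-end fragment counting.

#' Collapse identical tags into unique sequences
#'
#' Identical 40-base tags are collapsed into one record with a read count,
#' per-position median qualities, and the multiset of paired-end mate
#' sequences carried along. Singleton tags (a single supporting read) are
#' discarded as unverifiable.
#'
#' @param tags `data.table` with columns `tag`, `tag_qual` (Phred+33
#'   strings), `mate_seq` (as produced by [demultiplex()]).
#' @param min_reads minimum supporting reads per unique (default 2, i.e.
#'   singleton removal).
#' @return `data.table` of class `rad_uniques`: `seq`, `read_count`,
#'   `med_qual` (list column, numeric vector of length 40 per unique),
#'   `mates` (list column of mate sequences, one per supporting read).
#' @export
collapse_uniques <- function(tags, min_reads = 2L) {
  empty <- data.table::data.table(
    seq = character(), read_count = integer(),
    med_qual = list(), mates = list()
  )
  if (is.null(tags) || nrow(tags) == 0L) return(empty)
  stopifnot(all(nchar(tags$tag) == nchar(tags$tag[1L])))
  grp <- match(tags$tag, unique(tags$tag))
  cnt <- tabulate(grp)
  keep_grp <- which(cnt >= min_reads)
  if (!length(keep_grp)) return(empty)
  keep_row <- grp %in% keep_grp
  sub <- tags[keep_row]
  g2 <- match(grp[keep_row], keep_grp)
  qmat <- decode_qualities(sub$tag_qual)
  med <- .group_col_medians(qmat, g2, length(keep_grp))
  out <- data.table::data.table(
    seq = unique(tags$tag)[keep_grp],
    read_count = cnt[keep_grp],
    med_qual = lapply(seq_len(nrow(med)), function(r) med[r, ]),
    mates = split(sub$mate_seq, g2)
  )
  data.table::setorder(out, -read_count, seq)
  data.table::setattr(out, "class", c("rad_uniques", class(out)))
  out[]
}

#' Quality-weighted distance between two unique tags
#'
#' Sum over mismatching positions of the product of the two correct-call
#' probabilities, `(1 - 10^(-q1/10)) * (1 - 10^(-q2/10))`, with `q` the
#' per-position median Phred quality of each unique. A mismatch between two
#' confident bases contributes close to 1 (like an unweighted Hamming
#' mismatch), while mismatches involving unreliable bases count for less.
#' Always symmetric, never exceeds the Hamming distance, and equals 0 iff
#' the sequences are identical.
#'
#' @param seq1,seq2 equal-length DNA strings.
#' @param qual1,qual2 numeric vectors of per-position median qualities.
#' @return non-negative distance.
#' @export
weighted_distance <- function(seq1, seq2, qual1, qual2) {
  if (nchar(seq1) != nchar(seq2)) stop("sequences must have equal length")
  qm <- rbind(as.numeric(qual1), as.numeric(qual2))
  if (ncol(qm) != nchar(seq1)) stop("qualities must match sequence length")
  as.numeric(.weighted_dist_pairs(c(seq1, seq2), qm, 1L, 2L))
}

#' Cluster unique tags into candidate RAD loci
#'
#' Single-linkage clustering: two uniques are linked when their
#' quality-weighted distance is at most `locus_threshold`; connected
#' components become candidate loci. The default threshold of 7 bases is
#' deliberately liberal (it tolerates substantial within-locus diversity
#' plus sequencing error) because downstream filters prune spurious alleles
#' later.
#'
#' Candidate neighbour pairs are pre-screened by Hamming distance: since
#' the weighted distance never exceeds the Hamming distance and each
#' mismatch contributes at least `(1 - 10^(-qmin/10))^2` (with `qmin` the
#' lowest median quality present), any pair with weighted distance below
#' the threshold has Hamming distance at most
#' `locus_threshold / (1 - 10^(-qmin/10))^2`. The screen is therefore
#' exact, not heuristic.
#'
#' @param uniques a `rad_uniques` table.
#' @param locus_threshold maximum weighted distance joining two uniques.
#' @return the input with a `locus` integer column appended; class
#'   `rad_loci`.
#' @export
cluster_uniques <- function(uniques, locus_threshold = 7) {
  stopifnot(locus_threshold > 0)
  n <- nrow(uniques)
  if (n == 0L) {
    out <- data.table::copy(uniques)[, locus := integer(0)]
    data.table::setattr(out, "class", c("rad_loci", class(out)))
    return(out[])
  }
  L <- nchar(uniques$seq[1L])
  qmat <- do.call(rbind, uniques$med_qual)
  qmin <- max(min(qmat), 1)
  pmin2 <- (1 - 10^(-qmin / 10))^2
  max_h <- min(L, max(1L, ceiling(locus_threshold / pmin2)))
  cand <- .hamming_neighbors(uniques$seq, as.integer(max_h))
  if (nrow(cand)) {
    w <- .weighted_dist_pairs(uniques$seq, qmat, cand$i, cand$j)
    keep <- w <= locus_threshold
    comp <- single_linkage(n, cand$i[keep], cand$j[keep])
  } else {
    comp <- seq_len(n)
  }
  out <- data.table::copy(uniques)[, locus := comp]
  data.table::setattr(out, "class", c("rad_loci", class(out)))
  out[]
}

#' Call candidate RAD alleles within a locus
#'
#' Error correction inside one candidate locus. For every position and
#' base, the mean of the per-unique median qualities across the uniques
#' carrying that base is computed. A base observed in exactly one unique is
#' rejected (masked) as a likely sequencing error, but only when that
#' unique holds less than `max_error_frac` of the locus read count:
#' a base private to a well-supported unique is a genuine haplotype
#' difference (in a clean heterozygous locus both alleles are private at
#' every SNP position), whereas error-derived uniques are rare relative to
#' the alleles they derive from. Uniques identical after (a) masking
#' rejected bases and (b) ignoring positions whose mean base quality falls
#' below `qual_threshold` are merged into one allele: its sequence is that
#' of the highest-read-count member (ties broken lexicographically), its
#' read count the sum of merged counts, and mates are pooled. A masked
#' unique that matches no allele at its unmasked positions is kept as its
#' own allele, so downstream frequency filters make the final call.
#'
#' @param locus_uniques `rad_uniques` rows forming one locus.
#' @param qual_threshold mean base quality below which a position is
#'   ignored when comparing uniques (default Q20).
#' @param max_error_frac single-unique bases are treated as errors only in
#'   uniques holding less than this fraction of the locus reads
#'   (default 0.1).
#' @return `data.table`: `seq`, `read_count`, `n_uniques`, `mates`
#'   (pooled list column), `fragment_count_raw` (distinct mate sequences,
#'   see [count_fragments()]).
#' @export
call_alleles <- function(locus_uniques, qual_threshold = 20, max_error_frac = 0.1) {
  k <- nrow(locus_uniques)
  stopifnot(k >= 1L)
  u <- locus_uniques[order(-locus_uniques$read_count, locus_uniques$seq)]
  if (k == 1L) {
    return(data.table::data.table(
      seq = u$seq, read_count = u$read_count, n_uniques = 1L,
      mates = list(u$mates[[1L]]),
      fragment_count_raw = count_fragments(u$mates[[1L]])
    ))
  }
  L <- nchar(u$seq[1L])
  qm <- do.call(rbind, u$med_qual)
  total_reads <- sum(u$read_count)
  weak <- u$read_count / total_reads < max_error_frac
  pos_ignored <- colMeans(qm) < qual_threshold

  ## fast path: with no weak unique nothing is ever masked, and with no
  ## ignored position two distinct uniques can never compare equal, so
  ## every unique is its own allele
  if (!any(weak) && !any(pos_ignored)) {
    return(data.table::rbindlist(lapply(seq_len(k), function(ii) {
      data.table::data.table(
        seq = u$seq[ii], read_count = u$read_count[ii], n_uniques = 1L,
        mates = list(u$mates[[ii]]),
        fragment_count_raw = count_fragments(u$mates[[ii]])
      )
    })))
  }

  sm <- do.call(rbind, strsplit(u$seq, "", fixed = TRUE))
  masked <- matrix(FALSE, nrow = k, ncol = L)
  for (jj in seq_len(L)) {
    bases <- sm[, jj]
    ub <- unique(bases)
    if (length(ub) == 1L) next
    cnt <- tabulate(match(bases, ub), nbins = length(ub))
    for (b in ub[cnt == 1L]) {
      carrier <- which(bases == b)
      if (weak[carrier]) masked[carrier, jj] <- TRUE
    }
  }

  rep_idx <- integer(0)          # representative unique per allele
  members <- list()
  for (ii in seq_len(k)) {
    placed <- FALSE
    for (a in seq_along(rep_idx)) {
      r <- rep_idx[a]
      ok <- pos_ignored | masked[ii, ] | masked[r, ] | (sm[ii, ] == sm[r, ])
      if (all(ok)) {
        members[[a]] <- c(members[[a]], ii)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, ii)
      members[[length(rep_idx)]] <- ii
    }
  }

  data.table::rbindlist(lapply(seq_along(rep_idx), function(a) {
    m <- members[[a]]
    pooled <- unlist(u$mates[m], use.names = FALSE)
    data.table::data.table(
      seq = u$seq[rep_idx[a]],
      read_count = sum(u$read_count[m]),
      n_uniques = length(m),
      mates = list(pooled),
      fragment_count_raw = count_fragments(pooled)
    )
  }))
}

#' Count DNA fragments supporting an allele
#'
#' PCR duplicates of the same sheared fragment yield identical paired-end
#' mate sequences, so the number of *distinct* mates estimates the number
#' of independent DNA fragments -- a duplicate-corrected depth proxy used
#' in place of raw read counts.
#'
#' @param mates character vector of mate sequences pooled on an allele.
#' @return integer fragment count.
#' @export
count_fragments <- function(mates) length(unique(mates))

#' Call alleles for every individual of a demultiplexed run
#'
#' Convenience driver over [call_individual()]. With `free = TRUE`
#' (default) each individual's tag table is released from the `rad_demux`
#' object as soon as its alleles are called, which roughly halves the peak
#' memory of a full-lane run.
#'
#' @param demux a `rad_demux` object.
#' @param individuals ids to process (default: all with assigned reads).
#' @param free release per-individual tag tables after use.
#' @inheritParams call_individual
#' @return list of per-individual allele tables.
#' @export
call_all_individuals <- function(demux, individuals = NULL,
                                 locus_threshold = 7, qual_threshold = 20,
                                 max_error_frac = 0.1, free = TRUE) {
  if (is.null(individuals)) individuals <- ls(demux$tags)
  out <- lapply(individuals, function(id) {
    res <- call_individual(demux$tags[[id]], id,
                           locus_threshold = locus_threshold,
                           qual_threshold = qual_threshold,
                           max_error_frac = max_error_frac)
    if (free) rm(list = id, envir = demux$tags)
    res
  })
  names(out) <- individuals
  out
}

#' Call alleles for one individual
#'
#' Runs [collapse_uniques()], [cluster_uniques()] and [call_alleles()] for
#' a single individual's demultiplexed tags.
#'
#' @param tags per-individual tag table from [demultiplex()].
#' @param individual_id id recorded on the output rows.
#' @param locus_threshold see [cluster_uniques()].
#' @param qual_threshold,max_error_frac see [call_alleles()].
#' @return `data.table`: `individual_id`, `locus` (per-individual locus
#'   index), `allele_seq`, `read_count`, `n_uniques`, `fragment_count_raw`.
#' @export
call_individual <- function(tags, individual_id,
                            locus_threshold = 7,
                            qual_threshold = 20,
                            max_error_frac = 0.1) {
  uq <- collapse_uniques(tags)
  cl <- cluster_uniques(uq, locus_threshold)
  if (nrow(cl) == 0L) {
    return(data.table::data.table(
      individual_id = character(), locus = integer(),
      allele_seq = character(), read_count = integer(),
      n_uniques = integer(), fragment_count_raw = integer()
    ))
  }
  res <- cl[, {
    al <- call_alleles(.SD, qual_threshold, max_error_frac)
    list(allele_seq = al$seq, read_count = al$read_count,
         n_uniques = al$n_uniques, fragment_count_raw = al$fragment_count_raw)
  }, by = locus]
  res[, individual_id := individual_id]
  data.table::setcolorder(res, c("individual_id", "locus", "allele_seq",
                                 "read_count", "n_uniques", "fragment_count_raw"))
  res[]
}
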