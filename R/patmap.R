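## patmap: chromosome assignment of paternal alleles (allelic homology +
## pattern propagation), collapsing into >=3-allele RAD markers, two-point
## LOD grouping/ordering, and map statistics.

#' Assign paternal alleles to chromosomes by allelic homology
#'
#' A paternal allele is placed on a chromosome when (a) it is within
#' `mismatches` base differences of a maternally derived,
#' chromosome-assigned allele in the 40-base forward sequence and (b) all
#' such matches lie on a single chromosome. Alleles matching several
#' chromosomes, or none, stay unassigned.
#'
#' @param paternal [paternal_candidates()] output.
#' @param maternal_assigned `data.table` with columns `allele_seq` and
#'   `chrom_id` for chromosome-assigned maternal alleles (see
#'   [maternal_assignments()]).
#' @param mismatches maximum Hamming distance for allelism (default 3).
#' @return `data.table` of class `rad_assignments`: `allele_id`,
#'   `allele_seq`, `pattern`, `chrom_id` (NA if unassigned), `basis`
#'   (`allelism`/`unassigned`).
#' @export
assign_by_allelism <- function(paternal, maternal_assigned, mismatches = 3L) {
  out <- data.table::data.table(
    allele_id = paternal$allele_id,
    allele_seq = paternal$allele_seq,
    pattern = paternal$pattern,
    chrom_id = NA_integer_,
    basis = "unassigned"
  )
  if (nrow(out) && nrow(maternal_assigned)) {
    nb <- .hamming_neighbors_xy(out$allele_seq, maternal_assigned$allele_seq,
                                as.integer(mismatches))
    if (nrow(nb)) {
      nb <- data.table::as.data.table(nb)
      nb[, chrom := maternal_assigned$chrom_id[j]]
      hit <- nb[, .(nchrom = data.table::uniqueN(chrom), chrom = chrom[1L]), by = i]
      ok <- hit[nchrom == 1L]
      out[ok$i, `:=`(chrom_id = ok$chrom, basis = "allelism")]
    }
  }
  data.table::setattr(out, "class", c("rad_assignments", class(out)))
  out[]
}

#' Maternal allele-to-chromosome table from prints
#'
#' Flattens a `rad_prints` object into one row per chromosome-assigned
#' maternal allele, for use as the allelism reference.
#'
#' @param prints a `rad_prints`.
#' @param candidates the [maternal_candidates()] table (provides
#'   sequences).
#' @return `data.table`: `allele_id`, `allele_seq`, `chrom_id`, `homolog`
#'   (1 or 2, the print side carrying the allele).
#' @export
maternal_assignments <- function(prints, candidates) {
  pr <- prints$prints
  rows <- lapply(seq_len(nrow(pr)), function(r) {
    data.table::data.table(
      allele_id = c(pr$allele_ids_1[[r]], pr$allele_ids_2[[r]]),
      chrom_id = pr$chrom_id[r],
      homolog = rep(1:2, c(length(pr$allele_ids_1[[r]]),
                           length(pr$allele_ids_2[[r]])))
    )
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table::data.table(allele_id = character(),
                                  allele_seq = character(),
                                  chrom_id = integer(), homolog = integer()))
  merge(out, candidates[, .(allele_id, allele_seq)], by = "allele_id")[]
}

#' Propagate chromosome assignments by segregation pattern
#'
#' Three passes, in order: alleles whose pattern is (1) identical to, (2)
#' the exact complement of, (3) at Hamming distance one from the pattern
#' of an already-assigned allele inherit that chromosome. Each pass
#' re-anchors on everything assigned so far. A pattern claimed by more
#' than one chromosome is a conflict: the allele stays unassigned and the
#' conflict is recorded in the `conflicts` attribute.
#'
#' @param assignments a `rad_assignments` from [assign_by_allelism()].
#' @return updated `rad_assignments`; `basis` gains values
#'   `identical-pattern`, `inverse-pattern`, `one-off-pattern`.
#' @export
propagate_patterns <- function(assignments) {
  out <- data.table::copy(assignments)
  conflicts <- character(0)
  passes <- c("identical-pattern", "inverse-pattern", "one-off-pattern")
  for (pass in passes) {
    anchors <- out[!is.na(chrom_id),
                   .(nchrom = data.table::uniqueN(chrom_id),
                     chrom = chrom_id[1L]), by = pattern]
    conflicts <- union(conflicts, anchors[nchrom > 1L, pattern])
    amap <- anchors[nchrom == 1L]
    lookup <- stats::setNames(amap$chrom, amap$pattern)
    todo <- which(is.na(out$chrom_id))
    if (!length(todo)) break
    for (ix in todo) {
      p <- out$pattern[ix]
      cands <- switch(pass,
        "identical-pattern" = p,
        "inverse-pattern" = complement_pattern(p),
        "one-off-pattern" = one_off_patterns(p)
      )
      hits <- lookup[cands[cands %in% names(lookup)]]
      ## conflicting anchor patterns never assign; multiple hits must agree
      if (length(hits) && !any(cands %in% conflicts)) {
        ch <- unique(unname(hits))
        if (length(ch) == 1L) {
          data.table::set(out, ix, "chrom_id", ch)
          data.table::set(out, ix, "basis", pass)
        } else {
          conflicts <- union(conflicts, p)
        }
      }
    }
  }
  data.table::setattr(out, "conflicts", conflicts)
  out[]
}

## All patterns at Hamming distance exactly 1.
one_off_patterns <- function(p) {
  n <- nchar(p)
  vapply(seq_len(n), function(k) {
    b <- substr(p, k, k)
    paste0(substr(p, 1L, k - 1L), if (b == "1") "0" else "1",
           substr(p, k + 1L, n))
  }, character(1))
}

#' Collapse assigned paternal alleles into RAD markers
#'
#' Alleles sharing a chromosome and a segregation pattern -- counting a
#' pattern and its bitwise complement as the same marker position in
#' opposite phase -- are collapsed into one RAD marker. Markers supported
#' by fewer than `min_alleles` distinct alleles (default 3) are discarded
#' as unreliable. The marker's reported pattern is the phase carried by
#' the majority of its alleles (ties: lexicographically smaller pattern).
#'
#' @param assignments a `rad_assignments` (after [propagate_patterns()]).
#' @param min_alleles minimum distinct supporting alleles per marker.
#' @return `data.table` of class `rad_markers`: `marker_id`, `chrom_id`,
#'   `pattern`, `allele_count`, `allele_ids` (list column).
#' @export
collapse_markers <- function(assignments, min_alleles = 3L) {
  a <- assignments[!is.na(chrom_id)]
  if (nrow(a) == 0L) {
    out <- data.table::data.table(marker_id = integer(), chrom_id = integer(),
                                  pattern = character(), allele_count = integer(),
                                  allele_ids = list())
    data.table::setattr(out, "class", c("rad_markers", class(out)))
    return(out[])
  }
  a[, pat_key := pattern_key(pattern)]
  mk <- a[, {
    tab <- sort(table(pattern), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    list(pattern = min(top), allele_count = .N, allele_ids = list(allele_id))
  }, by = .(chrom_id, pat_key)]
  mk <- mk[allele_count >= min_alleles]
  data.table::setorder(mk, chrom_id, -allele_count, pattern)
  mk[, marker_id := .I]
  out <- mk[, .(marker_id, chrom_id, pattern, allele_count, allele_ids)]
  data.table::setattr(out, "class", c("rad_markers", class(out)))
  out[]
}

#' Two-point recombination fraction and LOD for a backcross
#'
#' For two dominant markers scored as presence/absence over `N` backcross
#' progeny, the recombinant count is `R = min(d, N - d)` with `d` the
#' Hamming distance between the patterns (phase folding: a pattern and its
#' complement represent the same position). The recombination-fraction
#' estimate is `r = R/N` and the LOD score is the base-10 log likelihood
#' ratio of linkage at `r` against independent assortment:
#' `LOD = (N-R) log10(1-r) + R log10(r) - N log10(0.5)`, with the `r = 0`
#' limit `N log10(2)`.
#'
#' @param p1,p2 pattern strings (equal length `N`).
#' @return list: `R` (recombinants), `r`, `lod`.
#' @export
two_point_stats <- function(p1, p2) {
  N <- nchar(p1)
  if (N == 0L || nchar(p2) != N) stop("patterns must be non-empty and equal length")
  d <- hamming(p1, p2)
  R <- min(d, N - d)
  r <- R / N
  lod <- if (R == 0L) {
    N * log10(2)
  } else if (r >= 0.5) {
    0
  } else {
    (N - R) * log10(1 - r) + R * log10(r) - N * log10(0.5)
  }
  list(R = R, r = r, lod = lod)
}

#' Order markers along a linkage group
#'
#' Finds a marker order minimizing the total adjacent recombinant count.
#' With at most `exhaustive_max` markers every order is enumerated
#' (optimal); larger groups use greedy double-ended nearest-neighbour
#' construction refined by 2-opt moves.
#'
#' @param D symmetric recombinant-count matrix.
#' @param method `"auto"` (exhaustive when small), `"greedy"`, or
#'   `"exhaustive"`.
#' @param exhaustive_max size limit for enumeration.
#' @return integer order of markers.
#' @export
order_markers <- function(D, method = c("auto", "greedy", "exhaustive"),
                          exhaustive_max = 8L) {
  method <- match.arg(method)
  n <- nrow(D)
  if (n <= 2L) return(seq_len(n))
  if (method == "exhaustive" || (method == "auto" && n <= exhaustive_max)) {
    return(order_exhaustive(D))
  }
  order_greedy_2opt(D)
}

path_cost <- function(D, ord) {
  sum(D[cbind(ord[-length(ord)], ord[-1L])])
}

order_exhaustive <- function(D) {
  n <- nrow(D)
  perms <- permutations_of(n)
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    if (p[1L] > p[n]) next # path symmetry
    cost <- path_cost(D, p)
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

order_greedy_2opt <- function(D) {
  n <- nrow(D)
  ## start from the pair with the largest distance endpoints? use the
  ## marker with the greatest total distance to others as a likely end
  start <- which.max(rowSums(D))
  path <- c(start)
  remaining <- setdiff(seq_len(n), start)
  while (length(remaining)) {
    ends <- c(path[1L], path[length(path)])
    cand <- expand.grid(e = ends, r = remaining)
    costs <- D[cbind(cand$e, cand$r)]
    b <- which.min(costs)
    if (cand$e[b] == path[1L]) path <- c(cand$r[b], path)
    else path <- c(path, cand$r[b])
    remaining <- setdiff(remaining, cand$r[b])
  }
  ## 2-opt refinement on total adjacent cost
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        cand <- path
        cand[a:b] <- rev(cand[a:b])
        if (path_cost(D, cand) < path_cost(D, path)) {
          path <- cand
          improved <- TRUE
        }
      }
    }
  }
  path
}

#' Build linkage groups from RAD markers
#'
#' Within each chromosome, markers are linked when their two-point LOD
#' exceeds `lod_group` *and* their recombinant count is at most
#' `max_link_diffs` (default 5 of 20: more distant markers are left in
#' separate components rather than chained through unreliable long links).
#' Connected components are ordered with [order_markers()]; adjacent
#' distances are `R_adj * cm_per_event` cM, where `cm_per_event` defaults
#' to `100/N` -- the direct count-based approximation (5 cM per crossover
#' at N = 20), not a mapping function. Markers without a chromosome are
#' grouped de novo by the same linkage rule. Markers that join no
#' component form singleton groups of length 0.
#'
#' @param markers a `rad_markers` table.
#' @param lod_group minimum LOD to link two markers.
#' @param max_link_diffs maximum recombinant count to link two markers.
#' @param cm_per_event centimorgans per observed crossover; `NULL` for
#'   `100/N`.
#' @return list of class `rad_map`:
#'   \describe{
#'     \item{map}{`data.table`: `chrom_id`, `component`, `position`,
#'       `marker_id`, `pattern`, `allele_count`, `cum_cm`.}
#'     \item{groups}{`data.table`: `chrom_id`, `component`, `n_markers`,
#'       `length_cm`.}
#'   }
#' @export
build_groups <- function(markers, lod_group = 2, max_link_diffs = 5L,
                         cm_per_event = NULL) {
  if (nrow(markers) == 0L) stop("no markers to group")
  N <- nchar(markers$pattern[1L])
  cm_ev <- if (is.null(cm_per_event)) 100 / N else cm_per_event

  map_rows <- list(); grp_rows <- list()
  chroms <- unique(markers$chrom_id)
  for (ch in chroms) {
    mk <- markers[is.na(chrom_id) == is.na(ch) &
                    (is.na(ch) | chrom_id == ch)]
    k <- nrow(mk)
    ## pairwise recombinant counts (phase-folded)
    D <- matrix(0L, k, k)
    lodm <- matrix(Inf, k, k)
    if (k > 1L) {
      for (a in seq_len(k - 1L)) {
        for (b in (a + 1L):k) {
          tp <- two_point_stats(mk$pattern[a], mk$pattern[b])
          D[a, b] <- D[b, a] <- tp$R
          lodm[a, b] <- lodm[b, a] <- tp$lod
        }
      }
    }
    link <- lodm > lod_group & D <= max_link_diffs
    edges <- which(upper.tri(link) & link, arr.ind = TRUE)
    comp <- single_linkage(k, edges[, 1L], edges[, 2L])
    for (cp in unique(comp)) {
      idx <- which(comp == cp)
      ord <- idx[order_markers(D[idx, idx, drop = FALSE])]
      adj <- if (length(ord) > 1L)
        D[cbind(ord[-length(ord)], ord[-1L])] else integer(0)
      cum <- c(0, cumsum(adj * cm_ev))
      map_rows[[length(map_rows) + 1L]] <- data.table::data.table(
        chrom_id = ch, component = cp, position = seq_along(ord),
        marker_id = mk$marker_id[ord], pattern = mk$pattern[ord],
        allele_count = mk$allele_count[ord], cum_cm = cum
      )
      grp_rows[[length(grp_rows) + 1L]] <- data.table::data.table(
        chrom_id = ch, component = cp, n_markers = length(ord),
        length_cm = max(cum)
      )
    }
  }
  structure(list(map = data.table::rbindlist(map_rows),
                 groups = data.table::rbindlist(grp_rows)),
            class = "rad_map")
}

#' Map summary statistics
#'
#' @param map a `rad_map` from [build_groups()].
#' @param genome_size_bp haploid genome size in base pairs (optional).
#' @return list: `total_cm`, `n_markers`, `n_groups`, `kb_per_cm`
#'   (physical DNA per centimorgan, 1 decimal; `NA` when the map length is
#'   zero or no genome size is given).
#' @export
map_stats <- function(map, genome_size_bp = NULL) {
  total_cm <- sum(map$groups$length_cm)
  kb_per_cm <- NA_real_
  if (!is.null(genome_size_bp) && total_cm > 0) {
    kb_per_cm <- round((genome_size_bp / 1000) / total_cm, 1L)
  }
  list(total_cm = total_cm,
       n_markers = nrow(map$map),
       n_groups = nrow(map$groups),
       kb_per_cm = kb_per_cm)
}

#' Write marker and map tables
#'
#' The marker table uses the `i_ii_iii` naming convention (marker id,
#' chromosome, supporting-allele count) familiar from JoinMap-style loc
#' exports.
#'
#' @param map a `rad_map`.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- data.table::copy(map$map)
  mk[, name := sprintf("%d_%s_%d", marker_id,
                       ifelse(is.na(chrom_id), "NA", chrom_id), allele_count)]
  p1 <- file.path(dir, "markers.tsv")
  data.table::fwrite(mk[, .(name, chrom_id, component, position, pattern,
                            allele_count)], p1, sep = "\t")
  p2 <- file.path(dir, "map.tsv")
  data.table::fwrite(map$map[, .(chrom_id, component, position, marker_id,
                                 cum_cm)], p2, sep = "\t")
  invisible(c(p1, p2))
}
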