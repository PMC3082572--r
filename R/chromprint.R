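## chromprint: maternal segregation patterns, complementary pattern pairs
## (chromosome prints), homozygous-maternal alleles, sex chromosomes.
##
## Female Lepidoptera lack crossing over, so each progeny inherits one of
## the mother's two homologs intact per chromosome. Alleles on one homolog
## share one presence/absence pattern across progeny; alleles on the other
## homolog share its exact bitwise complement. The pair identifies the
## chromosome.

#' Maternal-specific candidate alleles with segregation patterns
#'
#' Alleles present in the mother and absent from the father, with their
#' presence/absence pattern over the retained progeny (manifest order).
#' Excluded progeny are omitted from the patterns.
#'
#' @param catalog normalized `rad_catalog`.
#' @param manifest `rad_manifest`.
#' @return `data.table`: `allele_id`, `allele_seq`, `pattern` (string of
#'   0/1 over retained progeny), `n_present`.
#' @export
maternal_candidates <- function(catalog, manifest) {
  parent_specific_candidates(catalog, manifest,
                             keep = mother_id(manifest),
                             drop = father_id(manifest))
}

#' Paternal-specific segregating candidate alleles
#'
#' Alleles present in the father, absent from the mother, and actually
#' segregating among the retained progeny (patterns that are all ones or
#' all zeros are uninformative for linkage and are excluded).
#'
#' @inheritParams maternal_candidates
#' @return as [maternal_candidates()].
#' @export
paternal_candidates <- function(catalog, manifest) {
  out <- parent_specific_candidates(catalog, manifest,
                                    keep = father_id(manifest),
                                    drop = mother_id(manifest))
  out[n_present > 0L & n_present < nchar(pattern)]
}

parent_specific_candidates <- function(catalog, manifest, keep, drop) {
  manifest <- as_manifest(manifest)
  prog <- progeny_ids(manifest)
  inds <- unique(catalog$counts$individual_id)
  if (!keep %in% inds || !drop %in% inds)
    stop("mother/father missing from catalog")
  pm <- presence_matrix(catalog, c(keep, drop, prog))
  sel <- pm[, keep] & !pm[, drop]
  patt <- apply(pm[, prog, drop = FALSE], 1L, function(v) paste(as.integer(v), collapse = ""))
  out <- data.table::data.table(
    allele_id = catalog$alleles$allele_id,
    allele_seq = catalog$alleles$allele_seq,
    pattern = patt,
    n_present = as.integer(rowSums(pm[, prog, drop = FALSE]))
  )[sel]
  out[]
}

#' Group candidate alleles by exact segregation pattern
#'
#' @param candidates output of [maternal_candidates()].
#' @return list:
#'   \describe{
#'     \item{segregating}{`data.table` (`pattern`, `n_alleles`,
#'       `allele_ids` list column) for patterns that are neither all ones
#'       nor all zeros.}
#'     \item{homozygous}{the all-ones group (alleles present in every
#'       progeny: the mother is likely homozygous; not
#'       chromosome-assignable).}
#'     \item{null}{the all-zeros group (alleles seen in no progeny).}
#'   }
#' @export
group_patterns <- function(candidates) {
  g <- candidates[, .(n_alleles = .N, allele_ids = list(allele_id)), by = pattern]
  if (nrow(g)) {
    w <- pattern_weight(g$pattern)
    n <- nchar(g$pattern)
    all1 <- w == n
    all0 <- w == 0L
  } else {
    all1 <- all0 <- logical(0)
  }
  list(segregating = g[!all1 & !all0][order(-n_alleles, pattern)],
       homozygous = g[all1],
       null = g[all0])
}

#' Pair complementary patterns into chromosome prints
#'
#' Each pattern is matched with its exact bitwise complement; a matched
#' pair is one chromosome print. Pairs are ranked by total supporting
#' alleles (ties by lexicographic pattern) and numbered `1..k`. With
#' `expected_chromosomes` given, only the top-k pairs become prints and
#' the rest join the residuals; if fewer pairs exist than expected, a
#' warning is issued and all found pairs are returned. Patterns with no
#' complement present are residuals.
#'
#' @param groups `segregating` table from [group_patterns()].
#' @param expected_chromosomes expected number of chromosomes, or `NULL`
#'   to return every complementary pair.
#' @return list of class `rad_prints`:
#'   \describe{
#'     \item{prints}{`data.table`: `chrom_id`, `pattern_1`, `n_alleles_1`,
#'       `allele_ids_1`, `pattern_2`, `n_alleles_2`, `allele_ids_2`,
#'       `total`. `pattern_1` is the better-supported side.}
#'     \item{residuals}{unpaired or unselected groups.}
#'   }
#' @export
pair_complements <- function(groups, expected_chromosomes = NULL) {
  g <- data.table::copy(groups)
  if (nrow(g) == 0L) {
    return(structure(list(prints = empty_prints(), residuals = g),
                     class = "rad_prints"))
  }
  g[, key_ := pattern_key(pattern)]
  paired_keys <- g[, .N, by = key_][N == 2L, key_]
  pg <- g[key_ %in% paired_keys]
  resid <- g[!key_ %in% paired_keys][, key_ := NULL]

  if (nrow(pg)) {
    pr <- pg[, {
      o <- order(-n_alleles, pattern)
      list(pattern_1 = pattern[o[1L]], n_alleles_1 = n_alleles[o[1L]],
           allele_ids_1 = allele_ids[o[1L]],
           pattern_2 = pattern[o[2L]], n_alleles_2 = n_alleles[o[2L]],
           allele_ids_2 = allele_ids[o[2L]],
           total = sum(n_alleles))
    }, by = key_]
    data.table::setorder(pr, -total, pattern_1)
  } else {
    pr <- empty_prints()[, key_ := character(0)]
  }

  if (!is.null(expected_chromosomes) && nrow(pr) < expected_chromosomes)
    warning("found ", nrow(pr), " complementary pattern pairs, fewer than the ",
            expected_chromosomes, " expected")
  if (!is.null(expected_chromosomes) && nrow(pr) > expected_chromosomes) {
    demoted <- pr[-seq_len(expected_chromosomes)]
    resid <- rbind(resid,
                   demoted[, .(pattern = pattern_1, n_alleles = n_alleles_1,
                               allele_ids = allele_ids_1)],
                   demoted[, .(pattern = pattern_2, n_alleles = n_alleles_2,
                               allele_ids = allele_ids_2)])
    pr <- pr[seq_len(expected_chromosomes)]
  }
  pr[, chrom_id := .I][, key_ := NULL]
  data.table::setcolorder(pr, c("chrom_id", "pattern_1", "n_alleles_1",
                                "allele_ids_1", "pattern_2", "n_alleles_2",
                                "allele_ids_2", "total"))
  structure(list(prints = pr[], residuals = resid[]), class = "rad_prints")
}

empty_prints <- function() {
  data.table::data.table(
    chrom_id = integer(), pattern_1 = character(), n_alleles_1 = integer(),
    allele_ids_1 = list(), pattern_2 = character(), n_alleles_2 = integer(),
    allele_ids_2 = list(), total = integer()
  )
}

#' Alleles homozygous in the mother
#'
#' Maternal-specific alleles present in *all* retained progeny: the mother
#' carries them on both homologs, so they do not segregate and cannot be
#' assigned to a chromosome print.
#'
#' @param candidates output of [maternal_candidates()].
#' @return subset of `candidates` with all-ones patterns.
#' @export
classify_homozygous_maternal <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates[pattern_weight(pattern) == nchar(pattern)]
}

#' Match a binary progeny label against chromosome prints
#'
#' Generic co-segregation test: any binary label over the retained progeny
#' (sex, a phenotype such as insecticide-resistance survival, ...) is
#' compared with every print pattern; a perfect match or perfect
#' complement is reported with the matching side.
#'
#' @param prints a `rad_prints` object.
#' @param labels logical (or 0/1) vector named by progeny id, `TRUE` for
#'   the labelled class, in the same progeny order as the print patterns.
#' @return `data.table`: `chrom_id`, `side` (1 or 2), `match`
#'   (`pattern`/`complement`); zero rows when nothing co-segregates.
#' @export
match_label <- function(prints, labels) {
  vec <- paste(as.integer(labels), collapse = "")
  pr <- prints$prints
  res <- list()
  for (r in seq_len(nrow(pr))) {
    for (side in 1:2) {
      p <- pr[[paste0("pattern_", side)]][r]
      if (p == vec) {
        res[[length(res) + 1L]] <- data.table::data.table(
          chrom_id = pr$chrom_id[r], side = side, match = "pattern")
      } else if (p == complement_pattern(vec)) {
        res[[length(res) + 1L]] <- data.table::data.table(
          chrom_id = pr$chrom_id[r], side = side, match = "complement")
      }
    }
  }
  if (!length(res))
    return(data.table::data.table(chrom_id = integer(), side = integer(),
                                  match = character()))
  data.table::rbindlist(res)
}

#' Identify the W/Z sex chromosome pair
#'
#' In Lepidoptera females are the heterogametic sex (WZ); the W chromosome
#' is transmitted from mother to daughters only. A print whose pattern
#' equals the female-indicator vector over progeny is therefore the sex
#' chromosome: the female-matching side is the W, its complement the Z.
#'
#' @param prints a `rad_prints` object.
#' @param sexes character vector (`"M"`/`"F"`) named by progeny id, in the
#'   progeny order used to build the patterns.
#' @return list (`chrom_id`, `w_pattern`, `z_pattern`, `n_w`, `n_z`) or
#'   `NULL` when no print matches (autosomal-only information).
#' @export
identify_sex_chromosome <- function(prints, sexes) {
  if (any(!sexes %in% c("M", "F")))
    stop("sexes must be M or F for all progeny")
  m <- match_label(prints, sexes == "F")
  m <- m[match == "pattern"]
  if (nrow(m) == 0L) return(NULL)
  r <- prints$prints[chrom_id == m$chrom_id[1L]]
  side <- m$side[1L]
  other <- 3L - side
  list(chrom_id = r$chrom_id,
       w_pattern = r[[paste0("pattern_", side)]],
       z_pattern = r[[paste0("pattern_", other)]],
       n_w = r[[paste0("n_alleles_", side)]],
       n_z = r[[paste0("n_alleles_", other)]])
}

#' Automatic low-coverage exclusion rule
#'
#' Flags individuals whose assigned read count is below a fraction of the
#' median read count (default 25%), the rule used to drop low-coverage
#' progeny before segregation analysis.
#'
#' @param counts named integer vector of per-individual read counts.
#' @param fraction exclusion threshold relative to the median.
#' @return logical vector, `TRUE` = exclude.
#' @export
flag_low_coverage <- function(counts, fraction = 0.25) {
  counts < fraction * stats::median(counts)
}
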