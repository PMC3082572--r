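## crosscat: merge candidate loci across individuals, normalize fragment
## counts by histogram-derived scale factors, and apply presence thresholds.

#' Merge candidate loci across individuals
#'
#' Two haplotypes are *allelic* -- they belong to the same locus -- when
#' they differ at no more than `allele_mismatches` of the 40 bases.
#' Per-individual loci are unioned (single linkage) whenever any haplotype
#' pair across them is allelic by this rule, so orthologous loci sequenced
#' in different individuals merge even when the individuals carry
#' different alleles. Allele *identity* across individuals, by contrast,
#' is exact sequence equality: after within-individual error correction,
#' the same haplotype reads out as the same 40-base string, and tolerating
#' mismatches in identity would fuse genuinely distinct alleles of
#' heterozygous loci.
#'
#' @param per_individual_alleles list (or rbound `data.table`) of
#'   [call_individual()] outputs.
#' @param allele_mismatches maximum Hamming distance at which two
#'   haplotypes are considered allelic (default 3, configurable 0-6).
#' @return list of class `rad_catalog`:
#'   \describe{
#'     \item{alleles}{`data.table`: `allele_id`, `locus_id`, `allele_seq`.}
#'     \item{counts}{`data.table`: `allele_id`, `individual_id`,
#'       `read_count`, `fragment_raw`.}
#'   }
#' @export
merge_loci <- function(per_individual_alleles, allele_mismatches = 3L) {
  dt <- data.table::rbindlist(
    if (data.table::is.data.table(per_individual_alleles))
      list(per_individual_alleles) else per_individual_alleles
  )
  if (nrow(dt) == 0L) stop("no alleles to merge")
  seqs <- unique(dt$allele_seq)
  dt[, cls := match(allele_seq, seqs)]

  ## union per-individual loci: an edge for every allelic haplotype pair
  ## (Hamming <= allele_mismatches, including identical sequences seen in
  ## different loci)
  dt[, loc_key := paste(individual_id, locus, sep = "\r")]
  locs <- unique(dt$loc_key)
  dt[, li := match(loc_key, locs)]
  ## loci sharing an identical haplotype
  e_same <- dt[, .(l1 = li[1L], l2 = li), by = cls][l1 != l2]
  ## loci linked through near-identical haplotypes
  nb <- .hamming_neighbors(seqs, as.integer(allele_mismatches))
  cls_loci <- unique(dt[, .(cls, li)])
  e_near <- if (nrow(nb)) {
    merge(merge(data.table::as.data.table(nb)[, .(cls = i, cls2 = j)],
                cls_loci, by = "cls", allow.cartesian = TRUE),
          cls_loci[, .(cls2 = cls, li2 = li)], by = "cls2",
          allow.cartesian = TRUE)[li != li2, .(l1 = li, l2 = li2)]
  } else {
    data.table::data.table(l1 = integer(), l2 = integer())
  }
  comp <- single_linkage(length(locs), c(e_same$l1, e_near$l1),
                         c(e_same$l2, e_near$l2))
  cls2comp <- dt[, .(comp = comp[li[1L]]), by = cls]

  ## allele ids ordered by locus component then sequence
  amap <- merge(unique(dt[, .(cls, allele_seq)]), cls2comp, by = "cls")
  data.table::setorder(amap, comp, allele_seq)
  amap[, allele_id := sprintf("A%06d", .I)]
  locus_lvls <- unique(amap$comp)
  amap[, locus_id := sprintf("L%05d", match(comp, locus_lvls))]

  counts <- merge(dt[, .(cls, individual_id, read_count, fragment_raw = fragment_count_raw)],
                  amap[, .(cls, allele_id)], by = "cls")
  counts <- counts[, .(read_count = sum(read_count),
                       fragment_raw = sum(fragment_raw)),
                   by = .(allele_id, individual_id)]
  data.table::setorder(counts, allele_id, individual_id)
  structure(list(
    alleles = amap[, .(allele_id, locus_id, allele_seq)],
    counts = counts[]
  ), class = "rad_catalog")
}

#' Fragment-count histogram for one individual
#'
#' Number of candidate alleles (y) carrying each paired-end fragment count
#' (x). In real libraries the curve is multi-phased: a large error peak at
#' very low counts, a trough, a main peak near the per-allele sequencing
#' depth, and a long repeat-derived tail.
#'
#' @param fragment_counts integer vector of per-allele raw fragment counts
#'   for one individual.
#' @param individual_id optional id stored as an attribute.
#' @return `data.table` of class `fragment_histogram` with columns `x`
#'   (fragment count) and `y` (number of alleles), sorted by `x`.
#' @export
fragment_histogram <- function(fragment_counts, individual_id = NULL) {
  if (length(fragment_counts) == 0L) {
    h <- data.table::data.table(x = integer(), y = integer())
  } else {
    tab <- table(fragment_counts)
    h <- data.table::data.table(x = as.integer(names(tab)), y = as.integer(tab))
    data.table::setorder(h, x)
  }
  data.table::setattr(h, "individual_id", individual_id)
  data.table::setattr(h, "class", c("fragment_histogram", class(h)))
  h[]
}

#' Scale factor from trough/peak positions
#'
#' `SF_i = (min_m/min_i + max_m/max_i)/2`, where `min` is the x-position of
#' the trough between the error peak and the main peak of the
#' fragment-count histogram, `max` the x-position of the main peak, `m` the
#' reference individual (the mother, scale factor exactly 1), and `i` the
#' individual being normalized.
#'
#' @param min_m,max_m reference trough and peak positions.
#' @param min_i,max_i individual trough and peak positions.
#' @return scale factor (positive real).
#' @export
sf_from_extrema <- function(min_m, max_m, min_i, max_i) {
  stopifnot(min_i > 0, max_i > 0)
  (min_m / min_i + max_m / max_i) / 2
}

#' Estimate a per-individual scale factor from fragment histograms
#'
#' Automates the trough/peak reading: the y-values over the histogram's
#' support are smoothed with a centred moving average (window 3); the
#' trough `min_i` is the first local minimum at `x >= min_x` (default 2,
#' skipping the error peak); the peak `max_i` is the global maximum of the
#' smoothed curve at `x > min_i` (which also ignores the long repeat tail,
#' whose y-values are far below the main peak). The scale factor is then
#' computed with [sf_from_extrema()]. Passing the reference histogram as
#' both arguments returns exactly 1.
#'
#' @param h_i individual's [fragment_histogram()].
#' @param h_m reference (mother's) histogram.
#' @param min_x smallest x eligible as trough.
#' @param window moving-average window (odd).
#' @return list: `min_i`, `max_i`, `min_m`, `max_m`, `sf`.
#' @export
estimate_scale_factor <- function(h_i, h_m, min_x = 2, window = 3L) {
  e_i <- histogram_extrema(h_i, min_x, window)
  e_m <- histogram_extrema(h_m, min_x, window)
  list(min_i = e_i$trough, max_i = e_i$peak,
       min_m = e_m$trough, max_m = e_m$peak,
       sf = sf_from_extrema(e_m$trough, e_m$peak, e_i$trough, e_i$peak))
}

## Trough/peak detection on a histogram's support.
histogram_extrema <- function(h, min_x = 2, window = 3L) {
  if (nrow(h) < 3L)
    stop("histogram too sparse for trough/peak detection; ",
         "supply a manual scale-factor override")
  ys <- smooth_ma(h$y, window)
  n <- length(ys)
  trough_at <- NA_integer_
  for (t in 2:(n - 1L)) {
    if (h$x[t] < min_x) next
    ## a genuine trough lies in the descent from the low-count error peak,
    ## so (a) it sits strictly below the curve's starting value and (b)
    ## nothing before it exceeds that start -- otherwise the dip separates
    ## two interior modes (e.g. one-copy vs two-copy alleles), not the
    ## error peak from the main peak
    if (ys[t] <= ys[t - 1L] && ys[t] < ys[t + 1L] && ys[t] < ys[1L] &&
        max(ys[1:(t - 1L)]) <= ys[1L]) {
      trough_at <- t
      break
    }
  }
  if (is.na(trough_at))
    stop("no trough found in fragment-count histogram; ",
         "supply a manual scale-factor override")
  after <- which(seq_len(n) > trough_at)
  peak_at <- after[which.max(ys[after])]
  list(trough = h$x[trough_at], peak = h$x[peak_at])
}

smooth_ma <- function(y, window = 3L) {
  stopifnot(window %% 2L == 1L)
  half <- window %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(t) {
    lo <- max(1L, t - half); hi <- min(n, t + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' Scale factors for all individuals in a catalog
#'
#' Tries trough/peak estimation ([estimate_scale_factor()]) against the
#' reference individual. When a histogram has no detectable trough (as for
#' data without a low-count error peak, e.g. clean simulations), the
#' estimator falls back to the ratio of median fragment counts,
#' `SF_i = median_m / median_i`, with a warning; this preserves the
#' reference identity `SF_m = 1` and the inverse-depth behaviour of the
#' scale factor. Explicit overrides take precedence over both.
#'
#' @param catalog a `rad_catalog`.
#' @param reference_id reference individual (the mother).
#' @param overrides named numeric vector of manual scale factors.
#' @param min_x,window see [estimate_scale_factor()].
#' @return `data.table`: `individual_id`, `min_i`, `max_i`, `sf`, `method`
#'   (`trough-peak`, `median-ratio` or `override`).
#' @export
scale_factors <- function(catalog, reference_id, overrides = NULL,
                          min_x = 2, window = 3L) {
  cn <- catalog$counts
  inds <- unique(cn$individual_id)
  if (!reference_id %in% inds)
    stop("reference individual ", reference_id, " absent from catalog")
  hists <- lapply(inds, function(id)
    fragment_histogram(cn$fragment_raw[cn$individual_id == id], id))
  names(hists) <- inds
  h_m <- hists[[reference_id]]
  ref_extrema <- tryCatch(histogram_extrema(h_m, min_x, window),
                          error = function(e) NULL)
  fallback_used <- FALSE
  med_m <- stats::median(cn$fragment_raw[cn$individual_id == reference_id])
  res <- lapply(inds, function(id) {
    if (!is.null(overrides) && id %in% names(overrides)) {
      return(list(min_i = NA_real_, max_i = NA_real_,
                  sf = unname(overrides[[id]]), method = "override"))
    }
    if (!is.null(ref_extrema)) {
      est <- tryCatch(histogram_extrema(hists[[id]], min_x, window),
                      error = function(e) NULL)
      if (!is.null(est)) {
        return(list(min_i = est$trough, max_i = est$peak,
                    sf = sf_from_extrema(ref_extrema$trough, ref_extrema$peak,
                                         est$trough, est$peak),
                    method = "trough-peak"))
      }
    }
    fallback_used <<- TRUE
    med_i <- stats::median(cn$fragment_raw[cn$individual_id == id])
    list(min_i = NA_real_, max_i = NA_real_, sf = med_m / med_i,
         method = "median-ratio")
  })
  if (fallback_used)
    warning("no trough/peak detected for some individuals; ",
            "median-ratio scale factors used (see ?scale_factors)")
  out <- data.table::data.table(
    individual_id = inds,
    min_i = vapply(res, `[[`, numeric(1), "min_i"),
    max_i = vapply(res, `[[`, numeric(1), "max_i"),
    sf = vapply(res, `[[`, numeric(1), "sf"),
    method = vapply(res, `[[`, character(1), "method")
  )
  out[]
}

#' Normalize fragment counts and apply presence thresholds
#'
#' Each individual's raw fragment counts are multiplied by its scale
#' factor *before* thresholds are applied. An allele is called present in
#' an individual when its normalized count is at least `min_fragments`
#' (default 3); alleles present in fewer than `min_individuals` (default
#' 2) are discarded entirely, and loci left without alleles disappear.
#' Lowering `min_fragments` never removes an allele that was previously
#' retained.
#'
#' @param catalog a `rad_catalog` from [merge_loci()].
#' @param sf [scale_factors()] table (or named numeric vector).
#' @param min_fragments minimum normalized fragment count for a presence
#'   call.
#' @param min_individuals minimum number of individuals (counted after the
#'   fragment threshold) in which an allele must be present.
#' @return filtered `rad_catalog`; `counts` gains `fragment_norm` and
#'   `present`, and only rows of retained alleles remain.
#' @export
normalize_and_filter <- function(catalog, sf, min_fragments = 3,
                                 min_individuals = 2L) {
  sfv <- if (is.data.frame(sf)) stats::setNames(sf$sf, sf$individual_id) else sf
  cn <- data.table::copy(catalog$counts)
  missing_sf <- setdiff(unique(cn$individual_id), names(sfv))
  if (length(missing_sf))
    stop("no scale factor for: ", paste(missing_sf, collapse = ", "))
  cn[, fragment_norm := fragment_raw * sfv[individual_id]]
  cn[, present := fragment_norm >= min_fragments]
  keep <- cn[, .(n_present = sum(present)), by = allele_id][n_present >= min_individuals]
  cn <- cn[allele_id %in% keep$allele_id]
  alleles <- catalog$alleles[allele_id %in% keep$allele_id]
  structure(list(alleles = alleles[], counts = cn[]), class = "rad_catalog")
}

#' Presence matrix of a catalog
#'
#' @param catalog a normalized `rad_catalog` (after
#'   [normalize_and_filter()]).
#' @param individuals column order (default: all individuals present).
#' @return logical matrix, alleles (rownames `allele_id`) x individuals.
#' @export
presence_matrix <- function(catalog, individuals = NULL) {
  cn <- catalog$counts
  if (!"present" %in% names(cn))
    stop("catalog has no presence calls; run normalize_and_filter() first")
  if (is.null(individuals)) individuals <- sort(unique(cn$individual_id))
  ids <- catalog$alleles$allele_id
  m <- matrix(FALSE, nrow = length(ids), ncol = length(individuals),
              dimnames = list(ids, individuals))
  sub <- cn[present == TRUE & individual_id %in% individuals]
  m[cbind(match(sub$allele_id, ids), match(sub$individual_id, individuals))] <- TRUE
  m
}

#' Write catalog tables
#'
#' @param catalog a `rad_catalog`.
#' @param dir output directory; writes `catalog.tsv` (one row per allele,
#'   one normalized-count column per individual) and returns its path.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cn <- catalog$counts
  val <- if ("fragment_norm" %in% names(cn)) "fragment_norm" else "fragment_raw"
  wide <- data.table::dcast(cn, allele_id ~ individual_id,
                            value.var = val, fill = 0)
  out <- merge(catalog$alleles, wide, by = "allele_id")
  data.table::setorder(out, locus_id, allele_id)
  path <- file.path(dir, "catalog.tsv")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
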