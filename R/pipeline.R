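## cli_report: run configuration, pipeline orchestration and run summary.

## Recognized configuration keys and their defaults.
default_config <- function() {
  list(
    fastq_fwd = NULL, fastq_rev = NULL, manifest = NULL, out_dir = NULL,
    footprint = "TGCAGG", phred_offset = 33L,
    locus_threshold = 7, allele_qual = 20, max_error_frac = 0.1,
    allele_mismatches = 3L, min_fragments = 3, min_individuals = 2L,
    expected_chromosomes = NULL, lod_group = 2, max_link_diffs = 5L,
    cm_per_event = NULL, genome_mb = NULL,
    sf_override = NULL, exclude = NULL, seed = 1L
  )
}

#' Build or load a run configuration
#'
#' Unknown keys are rejected (a typo in a parameter name should never be
#' silently ignored). `exclude` may be a vector of individual ids or
#' `"auto"` to apply [flag_low_coverage()] to the demultiplexed read
#' counts.
#'
#' @param ... configuration values overriding the defaults, or a single
#'   named list.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args))) {
    args <- args[[1L]]
  }
  cfg <- default_config()
  unknown <- setdiff(names(args), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(args)] <- args
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `write_config` then `read_config` is a fixed point.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Summarize per-individual read counts
#'
#' Totals and rounded means in the layout of the run-accounting table:
#' the mean over all individuals and the mean over retained (non-excluded)
#' individuals. Means are rounded to the nearest integer, ties to even.
#'
#' @param counts named integer vector of per-individual read counts.
#' @param excluded ids excluded from the retained mean.
#' @return list: `total`, `mean_all`, `mean_retained` (`NA` if every
#'   individual is excluded), `n_all`, `n_retained`.
#' @export
summarize_reads <- function(counts, excluded = character(0)) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  keep <- !(names(counts) %in% excluded)
  list(
    total = sum(counts),
    mean_all = round(mean(counts)),
    mean_retained = if (any(keep)) round(mean(counts[keep])) else NA_real_,
    n_all = length(counts),
    n_retained = sum(keep)
  )
}

#' Run the full pipeline
#'
#' demultiplex -> per-individual allele calling -> cross-individual
#' catalog with normalization -> maternal chromosome prints (and sex
#' chromosome, when progeny sexes are known) -> paternal marker linkage
#' map. All stage outputs are written under `out_dir`; on stage failure a
#' `STATE` file records the last completed stage and partial outputs are
#' retained.
#'
#' @param cfg a `run_config` (or arguments accepted by [run_config()]).
#' @param quiet suppress progress messages.
#' @return (invisibly) list of class `rad_report`: `read_summary`,
#'   `demux_report`, `scale_factors`, `prints`, `sex`, `map`, `stats`,
#'   and the objects needed to recompute them.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  for (f in c("fastq_fwd", "fastq_rev", "manifest")) {
    if (is.null(cfg[[f]])) stop("configuration lacks required input: ", f)
    if (!file.exists(cfg[[f]])) stop("input not found: ", cfg[[f]])
  }
  out <- cfg$out_dir
  if (is.null(out)) stop("configuration lacks out_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out, "STATE")
  note <- function(...) if (!quiet) message("[radprint] ", ...)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(paste("failed at stage:", name),
                   conditionMessage(e)), state_path)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    writeLines(paste("completed stage:", name), state_path)
    res
  }

  manifest <- stage("manifest", load_manifest(cfg$manifest))

  note("demultiplexing")
  dm <- stage("demux", {
    pairs <- read_fastq_pairs(cfg$fastq_fwd, cfg$fastq_rev, cfg$phred_offset)
    d <- demultiplex(pairs, manifest, cfg$footprint)
    rm(pairs)
    write_demux(d, out)
    d
  })
  counts <- stats::setNames(dm$report$reads_assigned, dm$report$individual_id)

  ## exclusions ----------------------------------------------------------
  excluded <- character(0)
  if (!is.null(cfg$exclude)) {
    excluded <- if (identical(cfg$exclude, "auto")) {
      names(counts)[flag_low_coverage(counts)]
    } else {
      as.character(cfg$exclude)
    }
    if (length(intersect(excluded, c(mother_id(manifest), father_id(manifest)))))
      stop("cannot exclude a parent")
    manifest[individual_id %in% excluded, status := "excluded"]
  }
  excluded <- union(excluded, manifest$individual_id[manifest$status == "excluded"])
  read_summary <- summarize_reads(counts, excluded)

  note("calling alleles per individual")
  retained <- manifest$individual_id[manifest$status == "retained"]
  per_ind <- stage("tags", call_all_individuals(
    dm, retained,
    locus_threshold = cfg$locus_threshold,
    qual_threshold = cfg$allele_qual,
    max_error_frac = cfg$max_error_frac))

  note("building catalog")
  catalog <- stage("catalog", {
    cat0 <- merge_loci(per_ind, cfg$allele_mismatches)
    sf <- scale_factors(cat0, mother_id(manifest),
                        overrides = cfg$sf_override)
    cat1 <- normalize_and_filter(cat0, sf, cfg$min_fragments,
                                 cfg$min_individuals)
    write_catalog(cat1, out)
    data.table::fwrite(sf, file.path(out, "scale_factors.tsv"), sep = "\t")
    list(catalog = cat1, sf = sf)
  })

  note("deriving chromosome prints")
  prints_res <- stage("chromprint", {
    cand <- maternal_candidates(catalog$catalog, manifest)
    groups <- group_patterns(cand)
    prints <- pair_complements(groups$segregating, cfg$expected_chromosomes)
    homo <- classify_homozygous_maternal(cand)
    prog <- progeny_ids(manifest)
    sexes <- stats::setNames(manifest$sex[match(prog, manifest$individual_id)], prog)
    sex <- if (all(sexes %in% c("M", "F")))
      identify_sex_chromosome(prints, sexes) else NULL
    write_prints(prints, out)
    data.table::fwrite(homo[, .(allele_id, allele_seq, pattern)],
                       file.path(out, "homozygous_maternal.tsv"), sep = "\t")
    list(candidates = cand, groups = groups, prints = prints,
         homozygous = homo, sex = sex)
  })

  note("building paternal linkage map")
  map_res <- stage("map", {
    pat <- paternal_candidates(catalog$catalog, manifest)
    mat <- maternal_assignments(prints_res$prints, prints_res$candidates)
    asg <- assign_by_allelism(pat, mat, cfg$allele_mismatches)
    asg <- propagate_patterns(asg)
    mk <- collapse_markers(asg)
    if (nrow(mk)) {
      mp <- build_groups(mk, cfg$lod_group, cfg$max_link_diffs, cfg$cm_per_event)
      write_map(mp, out)
    } else {
      mp <- NULL
    }
    list(paternal = pat, assignments = asg, markers = mk, map = mp)
  })
  gsize <- if (is.null(cfg$genome_mb)) NULL else cfg$genome_mb * 1e6
  stats <- if (is.null(map_res$map)) {
    list(total_cm = 0, n_markers = 0L, n_groups = 0L, kb_per_cm = NA_real_)
  } else {
    map_stats(map_res$map, gsize)
  }

  report <- structure(list(
    config = cfg, manifest = manifest,
    read_summary = read_summary, demux_report = dm$report,
    discarded = dm$discarded, excluded = excluded,
    catalog = catalog$catalog, scale_factors = catalog$sf,
    candidates = prints_res$candidates, prints = prints_res$prints,
    homozygous = prints_res$homozygous, sex = prints_res$sex,
    assignments = map_res$assignments, markers = map_res$markers,
    map = map_res$map, stats = stats
  ), class = "rad_report")
  write_report_text(report, file.path(out, "report.txt"))
  writeLines("completed stage: report", state_path)
  note("done")
  invisible(report)
}

write_prints <- function(prints, dir) {
  pr <- prints$prints
  flat <- pr[, .(chrom_id, pattern_1, n_alleles_1, pattern_2, n_alleles_2, total)]
  data.table::fwrite(flat, file.path(dir, "prints.tsv"), sep = "\t")
  res <- prints$residuals[, .(pattern, n_alleles)]
  data.table::fwrite(res, file.path(dir, "residual_patterns.tsv"), sep = "\t")
  invisible(NULL)
}

write_report_text <- function(report, path) {
  rs <- report$read_summary
  lines <- c(
    "radprint run summary",
    "====================",
    sprintf("reads: total %.0f, mean %.0f over %d individuals, mean %s over %d retained",
            as.numeric(rs$total), as.numeric(rs$mean_all), rs$n_all,
            ifelse(is.na(rs$mean_retained), "NA", format(rs$mean_retained)),
            rs$n_retained),
    sprintf("discarded: %s",
            paste(names(report$discarded), report$discarded,
                  sep = "=", collapse = ", ")),
    if (length(report$excluded))
      sprintf("excluded individuals: %s", paste(report$excluded, collapse = ", "))
    else "excluded individuals: none",
    sprintf("catalog: %d loci, %d alleles",
            data.table::uniqueN(report$catalog$alleles$locus_id),
            nrow(report$catalog$alleles)),
    sprintf("maternal candidates: %d (%d homozygous-maternal)",
            nrow(report$candidates), nrow(report$homozygous)),
    sprintf("chromosome prints: %d (residual patterns: %d)",
            nrow(report$prints$prints), nrow(report$prints$residuals)),
    if (!is.null(report$sex))
      sprintf("sex chromosome: print %d (W side %d alleles, Z side %d alleles)",
              report$sex$chrom_id, report$sex$n_w, report$sex$n_z)
    else "sex chromosome: not identified",
    sprintf("markers: %d; linkage groups: %d; total map length: %.1f cM",
            report$stats$n_markers, report$stats$n_groups,
            report$stats$total_cm),
    if (!is.na(report$stats$kb_per_cm))
      sprintf("map density: %.1f kb/cM", report$stats$kb_per_cm)
    else NULL
  )
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  invisible(path)
}

#' @export
print.rad_report <- function(x, ...) {
  tmp <- tempfile()
  write_report_text(x, tmp)
  cat(readLines(tmp), sep = "\n")
  unlink(tmp)
  invisible(x)
}
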