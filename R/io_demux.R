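## io_demux: paired FASTQ input, manifest handling, and MID demultiplexing.
##
## Read layout (51-base forward reads): 5-base inline MID identifying the
## individual, 6 bases of SbfI restriction footprint (TGCAGG), then 40
## locus-specific bases -- the RAD tag. The paired-end mate comes from a
## sheared fragment 300-700 bp downstream and is carried along for
## fragment counting.

#' Load and validate a barcode/pedigree manifest
#'
#' The manifest maps 5-base inline MIDs to individuals and records the
#' pedigree role of each individual. Tab- or comma-separated with a header;
#' required columns `individual_id`, `role`, `sex`, `mid`; optional column
#' `status` (`retained`/`excluded`) marking individuals dropped from
#' segregation analysis (e.g. for low coverage).
#'
#' @param path path to the manifest file.
#' @return a `data.table` of class `rad_manifest` with columns
#'   `individual_id`, `role` (`mother`/`father`/`progeny`), `sex`
#'   (`M`/`F`/`U`), `mid`, `status`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character")
  as_manifest(dt)
}

#' Validate a manifest table
#'
#' @param dt data.frame with columns `individual_id`, `role`, `sex`, `mid`
#'   and optionally `status`.
#' @return validated `rad_manifest` data.table.
#' @export
as_manifest <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) == 0L) stop("manifest has no entries")
  need <- c("individual_id", "role", "sex", "mid")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (!"status" %in% names(dt)) dt[, status := "retained"]
  dt[, role := tolower(role)]
  dt[, sex := toupper(substr(sex, 1L, 1L))]
  dt[sex %in% c("", "U", "N"), sex := "U"]
  if (!all(dt$role %in% c("mother", "father", "progeny")))
    stop("manifest roles must be mother, father or progeny")
  if (!all(dt$sex %in% c("M", "F", "U")))
    stop("manifest sex must be M, F or unknown")
  if (anyDuplicated(dt$individual_id))
    stop("duplicate individual_id in manifest")
  dup <- dt$mid[duplicated(dt$mid)]
  if (length(dup))
    stop("duplicate MID in manifest: ", paste(unique(dup), collapse = ", "))
  if (!all(grepl("^[ACGT]{5}$", dt$mid)))
    stop("MIDs must be 5-base DNA strings")
  if (sum(dt$role == "mother") != 1L) stop("manifest must contain exactly one mother")
  if (sum(dt$role == "father") != 1L) stop("manifest must contain exactly one father")
  if (!all(dt$status %in% c("retained", "excluded")))
    stop("manifest status must be retained or excluded")
  data.table::setattr(dt, "class", c("rad_manifest", class(dt)))
  dt[]
}

#' Mother/father/progeny accessors
#' @param manifest a `rad_manifest`.
#' @return individual id(s).
#' @export
mother_id <- function(manifest) manifest$individual_id[manifest$role == "mother"]

#' @rdname mother_id
#' @export
father_id <- function(manifest) manifest$individual_id[manifest$role == "father"]

#' @rdname mother_id
#' @param retained_only drop individuals with `status == "excluded"`.
#' @export
progeny_ids <- function(manifest, retained_only = TRUE) {
  keep <- manifest$role == "progeny"
  if (retained_only) keep <- keep & manifest$status == "retained"
  manifest$individual_id[keep]
}

#' Read paired FASTQ files
#'
#' Loads forward and reverse reads (gzip-transparent) in matching record
#' order. Qualities are re-encoded to Phred+33 and capped at 41, so
#' downstream code never needs to know the original offset.
#'
#' @param fwd_path,rev_path FASTQ file paths.
#' @param phred_offset 33 (default) or 64 for older Illumina encodings.
#' @return list of class `rad_read_pairs` holding the reads as Biostrings
#'   sets: `fwd`, `rev` (`DNAStringSet`), `fwd_qual`, `rev_qual`
#'   (`BStringSet` of Phred+33 quality strings, capped at Q41) and
#'   `read_id`. Use [as.data.frame()] for a plain-character view.
#' @export
read_fastq_pairs <- function(fwd_path, rev_path, phred_offset = 33L) {
  fwd <- read_fastq_checked(fwd_path, phred_offset)
  rev <- read_fastq_checked(rev_path, phred_offset)
  if (length(fwd$seq) != length(rev$seq))
    stop("forward and reverse FASTQ files differ in record count (",
         length(fwd$seq), " vs ", length(rev$seq), "); first mismatch at record ",
         min(length(fwd$seq), length(rev$seq)) + 1L)
  structure(list(read_id = fwd$id, fwd = fwd$seq, fwd_qual = fwd$qual,
                 rev = rev$seq, rev_qual = rev$qual),
            class = "rad_read_pairs")
}

#' @export
as.data.frame.rad_read_pairs <- function(x, ...) {
  data.frame(read_id = x$read_id,
             fwd_seq = as.character(x$fwd),
             fwd_qual = as.character(x$fwd_qual),
             rev_seq = as.character(x$rev),
             rev_qual = as.character(x$rev_qual))
}

#' @export
length.rad_read_pairs <- function(x) length(x$fwd)

read_fastq_checked <- function(path, phred_offset) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      ## the reader warns that it drops its quality metadata column during
      ## internal coercion; we keep qualities ourselves, so muffle it
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }
    ),
    error = function(e) stop("malformed FASTQ in ", path, ": ", conditionMessage(e))
  )
  qual <- methods::as(Biostrings::quality(x), "BStringSet")
  ## byte-level range check via the alphabet table (C-level, no per-read R
  ## work); recode only when something is actually out of range
  if (length(qual)) {
    tab <- Biostrings::alphabetFrequency(qual, collapse = TRUE)
    bytes <- which(tab > 0)  # ascii codes present
    lo <- as.integer(phred_offset)
    hi <- lo + 41L
    if (length(bytes) && min(bytes) < lo)
      stop("quality character below offset ", phred_offset, " in ", path,
           "; wrong phred offset?")
    if (phred_offset != 33L || (length(bytes) && max(bytes) > hi)) {
      q <- vapply(as.character(qual), function(s) {
        v <- utf8ToInt(s) - lo
        intToUtf8(pmin(v, 41L) + 33L)
      }, character(1), USE.NAMES = FALSE)
      qual <- Biostrings::BStringSet(q)
    }
  }
  ## the coercion warns that the quality metadata column is dropped; we
  ## keep qualities separately, so silence it
  seqs <- suppressWarnings(methods::as(x, "DNAStringSet"))
  S4Vectors::mcols(seqs) <- NULL
  list(id = sub(" .*", "", names(x)), seq = seqs, qual = qual)
}

#' Demultiplex read pairs by inline MID and restriction footprint
#'
#' Assigns each read pair to an individual by exact match of the first 5
#' forward bases against the manifest MIDs, requires the next 6 bases to
#' equal the restriction footprint exactly, and extracts bases 12-51 as the
#' 40-base RAD tag. Reads failing either check, or whose tag contains an N,
#' are counted in per-reason discard bins (never an error). MID matching is
#' exact: the published MIDs are not error-correcting codes and a
#' one-mismatch rescue would risk cross-individual contamination.
#'
#' @param pairs a `rad_read_pairs` object from [read_fastq_pairs()].
#' @param manifest a `rad_manifest`.
#' @param footprint expected restriction footprint (SbfI leaves `TGCAGG`).
#' @return list of class `rad_demux` with elements
#'   \describe{
#'     \item{tags}{environment mapping individual id to a `data.table`
#'       with columns `tag`, `tag_qual`, `mate_seq`, `mate_qual`.}
#'     \item{report}{`data.table`: `individual_id`, `reads_assigned`.}
#'     \item{discarded}{named integer vector: `no_mid`, `bad_footprint`,
#'       `n_in_tag`.}
#'     \item{total}{total input pairs; always `sum(assigned) + sum(discarded)`.}
#'   }
#' @export
demultiplex <- function(pairs, manifest, footprint = "TGCAGG") {
  stopifnot(inherits(pairs, "rad_read_pairs"))
  manifest <- as_manifest(manifest)
  n <- length(pairs$fwd)
  mid_len <- nchar(manifest$mid[1L])
  fp_len <- nchar(footprint)
  tag_start <- mid_len + fp_len + 1L
  tag_end <- tag_start + 39L

  widths <- Biostrings::width(pairs$fwd)
  long_enough <- widths >= tag_end
  ind_idx <- rep(NA_integer_, n)
  fp_ok <- logical(n)
  tag_clean <- logical(n)
  le <- which(long_enough)
  if (length(le)) {
    head11 <- as.character(Biostrings::subseq(pairs$fwd[le], 1L, mid_len + fp_len))
    ind_idx[le] <- match(substr(head11, 1L, mid_len), manifest$mid)
    fp_ok[le] <- substr(head11, mid_len + 1L, mid_len + fp_len) == footprint
    ## N check on the tag region without materializing all tags
    nfreq <- Biostrings::alphabetFrequency(
      Biostrings::subseq(pairs$fwd[le], tag_start, tag_end))[, "N"]
    tag_clean[le] <- nfreq == 0L
  }
  has_mid <- !is.na(ind_idx)

  keep <- has_mid & fp_ok & tag_clean
  discarded <- c(
    no_mid = sum(!has_mid),
    bad_footprint = sum(has_mid & !fp_ok),
    n_in_tag = sum(has_mid & fp_ok & !tag_clean)
  )

  out <- vector("list", nrow(manifest))
  names(out) <- manifest$individual_id
  assigned <- integer(nrow(manifest))
  kept_idx <- which(keep)
  if (length(kept_idx)) {
    by_ind <- split(kept_idx, ind_idx[kept_idx])
    for (nm in names(by_ind)) {
      ix <- by_ind[[nm]]
      k <- as.integer(nm)
      out[[k]] <- data.table::data.table(
        tag = as.character(Biostrings::subseq(pairs$fwd[ix], tag_start, tag_end)),
        tag_qual = as.character(Biostrings::subseq(pairs$fwd_qual[ix], tag_start, tag_end)),
        mate_seq = as.character(pairs$rev[ix]),
        mate_qual = as.character(pairs$rev_qual[ix])
      )
      assigned[k] <- length(ix)
    }
  }
  empty <- vapply(out, is.null, logical(1))
  out[empty] <- list(data.table::data.table(
    tag = character(), tag_qual = character(),
    mate_seq = character(), mate_qual = character()
  ))
  ## an environment, not a list: callers (call_all_individuals) can then
  ## release each individual's tags by reference once processed
  structure(list(
    tags = list2env(out, envir = new.env(parent = emptyenv())),
    report = data.table::data.table(individual_id = manifest$individual_id,
                                    reads_assigned = assigned),
    discarded = discarded,
    total = n
  ), class = "rad_demux")
}

#' Write per-individual tag reads as FASTQ
#'
#' @param demux a `rad_demux` object.
#' @param dir output directory; one `<individual>.tags.fastq` per individual
#'   plus `demux_report.tsv`.
#' @return invisibly, the report path.
#' @export
write_demux <- function(demux, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ind in ls(demux$tags)) {
    dt <- demux$tags[[ind]]
    path <- file.path(dir, paste0(ind, ".tags.fastq"))
    write_fastq(dt$tag, dt$tag_qual,
                sprintf("%s_%d", ind, seq_len(nrow(dt))), path)
  }
  rep_path <- file.path(dir, "demux_report.tsv")
  rep <- data.table::copy(demux$report)
  rep[, reads_discarded := NA_integer_]
  disc <- data.table::data.table(
    individual_id = paste0("discarded_", names(demux$discarded)),
    reads_assigned = NA_integer_,
    reads_discarded = as.integer(demux$discarded)
  )
  data.table::fwrite(rbind(rep, disc), rep_path, sep = "\t")
  invisible(rep_path)
}

## FASTQ writer on character vectors (phred-33 quality strings).
write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}
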