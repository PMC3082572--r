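## Shared test fixtures, all built in code.

library(data.table)

## A tag table (as produced by demultiplex for one individual) from bare
## sequences; constant quality by default.
make_tags <- function(seqs, qual = 30L, mates = NULL) {
  if (length(seqs) == 0L) {
    return(data.table(tag = character(), tag_qual = character(),
                      mate_seq = character(), mate_qual = character()))
  }
  L <- nchar(seqs[1L])
  qs <- if (length(qual) == 1L) {
    rep(strrep(intToUtf8(qual + 33L), L), length(seqs))
  } else {
    vapply(qual, function(v) intToUtf8(v + 33L), character(1))
  }
  if (is.null(mates)) mates <- sprintf("MATE%04d", seq_along(seqs))
  data.table(tag = seqs, tag_qual = qs, mate_seq = mates,
             mate_qual = rep(strrep("I", nchar(mates[1L])), length(seqs)))
}

## A rad_uniques row set from sequences + per-unique read counts and
## (constant) median qualities.
make_uniques <- function(seqs, read_count = 10L, qual = 40, mates = NULL) {
  n <- length(seqs)
  if (length(read_count) == 1L) read_count <- rep(read_count, n)
  L <- if (n) nchar(seqs[1L]) else 0L
  qlist <- if (is.list(qual)) qual else rep(list(rep(qual, L)), n)
  if (is.null(mates)) mates <- lapply(seq_len(n), function(i)
    sprintf("M%d_%d", i, seq_len(read_count[i])))
  out <- data.table(seq = seqs, read_count = as.integer(read_count),
                    med_qual = qlist, mates = mates)
  setattr(out, "class", c("rad_uniques", class(out)))
  out[]
}

## Random DNA of given length.
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## Flip a 0/1 pattern string at the given positions.
mutate_pattern <- function(p, pos) {
  v <- strsplit(p, "")[[1]]
  v[pos] <- ifelse(v[pos] == "1", "0", "1")
  paste(v, collapse = "")
}

## Mutate a sequence at given positions (cycling base).
mutate_at <- function(seq, pos) {
  for (p in pos) {
    b <- substr(seq, p, p)
    substr(seq, p, p) <- chartr("ACGT", "CGTA", b)
  }
  seq
}

## Build a normalized rad_catalog directly from a presence/count matrix:
## `counts` is an alleles x individuals numeric matrix of normalized
## fragment counts (0 = absent); sequences optional.
make_catalog <- function(counts, seqs = NULL, min_fragments = 3) {
  ids <- sprintf("A%06d", seq_len(nrow(counts)))
  if (is.null(seqs)) seqs <- rand_dna(nrow(counts), 40L)
  cn <- data.table(
    allele_id = rep(ids, ncol(counts)),
    individual_id = rep(colnames(counts), each = nrow(counts)),
    read_count = as.integer(round(as.vector(counts) * 1.4)),
    fragment_raw = as.integer(round(as.vector(counts))),
    fragment_norm = as.vector(counts)
  )[fragment_raw > 0]
  cn[, present := fragment_norm >= min_fragments]
  structure(list(
    alleles = data.table(allele_id = ids,
                         locus_id = sprintf("L%05d", seq_along(ids)),
                         allele_seq = seqs),
    counts = cn
  ), class = "rad_catalog")
}

## A minimal manifest for toy catalogs.
make_manifest <- function(n_progeny, sexes = NULL,
                          excluded = character(0)) {
  ids <- c("mother", "father", sprintf("p%02d", seq_len(n_progeny)))
  if (is.null(sexes)) sexes <- rep(c("F", "M"), length.out = n_progeny)
  mids <- unique_mids(length(ids))
  as_manifest(data.table(
    individual_id = ids,
    role = c("mother", "father", rep("progeny", n_progeny)),
    sex = c("F", "M", sexes),
    mid = mids,
    status = ifelse(ids %in% excluded, "excluded", "retained")
  ))
}

unique_mids <- function(n) {
  pool <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1L,
                function(r) paste0("AC", paste(r, collapse = "")))
  pool[seq_len(n)]
}

## Path to a bundled extdata fixture.
fixture <- function(name) {
  system.file("extdata", name, package = "radprint", mustWork = TRUE)
}

## Cached end-to-end clean run used by several acceptance checks: the
## full-size error-free backcross (uniform depth), run through the
## read-level pipeline once per session.
clean_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    inds <- c("mother", "father", sprintf("progeny_%02d", 1:20))
    cfg <- sim_config(per_base_error = 0, seed = 42,
                      depth_multipliers = stats::setNames(rep(1, 22), inds))
    truth <- simulate_pedigree(cfg)
    dir <- file.path(tempdir(), "radprint_clean_run")
    em <- emit_reads(truth, dir)
    manifest <- load_manifest(em$manifest)
    pairs <- read_fastq_pairs(em$fwd, em$rev)
    dm <- demultiplex(pairs, manifest)
    rm(pairs); gc()
    per_ind <- call_all_individuals(dm, manifest$individual_id)
    rm(dm); gc()
    cat0 <- merge_loci(per_ind)
    sf <- suppressWarnings(scale_factors(cat0, "mother"))
    catalog <- normalize_and_filter(cat0, sf)
    cand <- maternal_candidates(catalog, manifest)
    groups <- group_patterns(cand)
    prints <- pair_complements(groups$segregating)
    cache <<- list(cfg = cfg, truth = truth, manifest = manifest,
                   em = em, catalog = catalog, sf = sf, candidates = cand,
                   groups = groups, prints = prints)
    unlink(dir, recursive = TRUE)
    cache
  }
})
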