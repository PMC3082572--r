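## simgen: backcross RAD-seq read simulator with truth tables.
##
## Genetic model: the F1 mother is heterozygous at a fraction of loci and,
## lacking crossing over (achiasmatic female meiosis), transmits one intact
## homolog per chromosome to each progeny; the father recombines with a
## Poisson number of crossovers per chromosome. Chromosome 1 is sex-linked
## by default: the mother is WZ and daughters are exactly the progeny
## receiving her homolog 2 (the W).

## The 24 published 5-base inline MIDs used by default.
DEFAULT_MIDS <- c(
  "CGATA", "CGGCG", "CTAGG", "CTGAA", "GAAGC", "GAGAT", "GCATT", "GGAAG",
  "GTACA", "TAATG", "TAGCA", "TCAGA", "TCGAG", "TGACC", "TGGTT", "TTAAT",
  "AACCC", "ACTGC", "AAGGG", "ACGTA", "AGAGT", "ATGCT", "CAGTC", "CCAAC"
)

#' Simulation configuration
#'
#' Defaults reproduce the design of the motivating experiment: 31
#' chromosomes, ~100 RAD loci each, a backcross with 20 scored progeny,
#' per-allele sequencing depth of ~30 independent fragments read ~1.4
#' times each (PCR duplication), log-normal depth variation between
#' individuals, and a per-base substitution error rate of 0.001 (Phred
#' Q30). `male_crossovers` defaults to 0.42 crossovers per paternal
#' chromosome per meiosis, which under the 100/N cM-per-event convention
#' gives an expected total map length of about 31 x 42 = 1300 cM.
#'
#' @param n_chromosomes number of chromosome pairs.
#' @param loci_per_chromosome Poisson mean number of RAD loci per
#'   chromosome.
#' @param n_progeny backcross progeny scored.
#' @param maternal_het_rate probability the mother is heterozygous at a
#'   locus.
#' @param paternal_het_rate probability the father is heterozygous at a
#'   locus.
#' @param parent_shared_rate probability the father carries one of the
#'   mother's alleles at a locus (shared polymorphism).
#' @param male_crossovers Poisson mean crossovers per chromosome in
#'   spermatogenesis.
#' @param depth_multipliers named positive reals per individual, or `NULL`
#'   to sample log-normal (`sdlog = depth_sdlog`, unit mean).
#' @param depth_sdlog log-sd of sampled depth multipliers.
#' @param fragments_per_allele mean independent sheared fragments per
#'   allele copy.
#' @param reads_per_fragment mean reads per fragment (>= 1; the excess is
#'   PCR duplication).
#' @param per_base_error substitution error probability per base;
#'   qualities are emitted consistently (Q = -10 log10(error)).
#' @param min_maternal_informative minimum informative maternal alleles
#'   enforced per chromosome (heterozygosity is topped up to reach it);
#'   `NULL` to disable.
#' @param sex_linked_chromosome chromosome carrying the W/Z pair (`NULL`
#'   for no sex linkage; progeny sexes then assigned at random).
#' @param tag_length RAD tag length.
#' @param footprint restriction footprint on the forward read.
#' @param mids MIDs to assign (defaults to the 24 published 5-mers,
#'   extended randomly if more individuals are simulated).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 31L,
                       loci_per_chromosome = 100,
                       n_progeny = 20L,
                       maternal_het_rate = 0.4,
                       paternal_het_rate = 0.4,
                       parent_shared_rate = 0.2,
                       male_crossovers = 0.42,
                       depth_multipliers = NULL,
                       depth_sdlog = 0.35,
                       fragments_per_allele = 30,
                       reads_per_fragment = 1.4,
                       per_base_error = 0.001,
                       min_maternal_informative = 49L,
                       sex_linked_chromosome = 1L,
                       tag_length = 40L,
                       footprint = "TGCAGG",
                       mids = NULL,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = loci_per_chromosome,
    n_progeny = as.integer(n_progeny),
    maternal_het_rate = maternal_het_rate,
    paternal_het_rate = paternal_het_rate,
    parent_shared_rate = parent_shared_rate,
    male_crossovers = male_crossovers,
    depth_multipliers = depth_multipliers,
    depth_sdlog = depth_sdlog,
    fragments_per_allele = fragments_per_allele,
    reads_per_fragment = reads_per_fragment,
    per_base_error = per_base_error,
    min_maternal_informative = if (is.null(min_maternal_informative)) NULL
                               else as.integer(min_maternal_informative),
    sex_linked_chromosome = if (is.null(sex_linked_chromosome)) NULL
                            else as.integer(sex_linked_chromosome),
    tag_length = as.integer(tag_length),
    footprint = footprint,
    mids = mids,
    seed = as.integer(seed)
  )
  rates <- c(cfg$maternal_het_rate, cfg$paternal_het_rate,
             cfg$parent_shared_rate, cfg$per_base_error)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_chromosomes < 0L) stop("n_chromosomes must be >= 0")
  means <- c(cfg$loci_per_chromosome, cfg$fragments_per_allele,
             cfg$reads_per_fragment, cfg$depth_sdlog)
  if (any(means <= 0)) stop("means must be positive")
  if (cfg$male_crossovers < 0) stop("male_crossovers must be >= 0")
  if (cfg$reads_per_fragment < 1) stop("reads_per_fragment must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate the backcross pedigree and genotypes
#'
#' Generates the genome (well-separated random tag sequences plus a
#' downstream region per locus for paired-end mates), parental genotypes,
#' intact maternal homolog transmission, recombinant paternal gametes,
#' per-individual depth multipliers and progeny sexes. Everything is
#' recorded in truth tables for parameter-recovery testing.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_truth`: `cfg`, `manifest` (a
#'   `rad_manifest`), `loci`, `alleles` (true allele sequences with
#'   chromosome/locus/origin), `genotypes` (individual x locus allele
#'   pair), `maternal_homolog` (progeny x chromosome matrix),
#'   `paternal_crossovers`, `depth` (named multipliers),
#'   `maternal_patterns` (expected print pattern per chromosome/homolog).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nc <- cfg$n_chromosomes
  np <- cfg$n_progeny

  ## individuals ---------------------------------------------------------
  prog_ids <- sprintf("progeny_%02d", seq_len(np))
  inds <- c("mother", "father", prog_ids)
  mids <- cfg$mids
  if (is.null(mids)) mids <- DEFAULT_MIDS
  while (length(mids) < length(inds)) {
    extra <- random_dna(1L, 5L)
    if (!extra %in% mids) mids <- c(mids, extra)
  }
  mids <- mids[seq_along(inds)]
  names(mids) <- inds

  ## depth multipliers ---------------------------------------------------
  depth <- cfg$depth_multipliers
  if (is.null(depth)) {
    depth <- stats::rlnorm(length(inds), meanlog = -cfg$depth_sdlog^2 / 2,
                           sdlog = cfg$depth_sdlog)
    names(depth) <- inds
  } else {
    if (!all(inds %in% names(depth)))
      stop("depth_multipliers must name every individual: ",
           paste(inds, collapse = ", "))
    depth <- depth[inds]
  }

  if (nc == 0L) {
    return(empty_truth(cfg, inds, mids, depth))
  }

  ## genome --------------------------------------------------------------
  n_loci <- pmax(stats::rpois(nc, cfg$loci_per_chromosome), 20L)
  total <- sum(n_loci)
  anc <- random_dna(total, cfg$tag_length)
  ## enforce well-separated loci (tags never within clustering range)
  repeat {
    nb <- .hamming_neighbors(anc, 9L)
    if (nrow(nb) == 0L) break
    anc[unique(nb$j)] <- random_dna(length(unique(nb$j)), cfg$tag_length)
  }
  loci <- data.table::data.table(
    locus = seq_len(total),
    chrom = rep(seq_len(nc), n_loci),
    pos = unlist(lapply(n_loci, seq_len)),
    ancestral = anc,
    downstream = random_dna(total, 451L)
  )

  ## parental genotypes --------------------------------------------------
  m_het <- stats::rbinom(total, 1L, cfg$maternal_het_rate) == 1L
  f_het <- stats::rbinom(total, 1L, cfg$paternal_het_rate) == 1L
  shared <- stats::rbinom(total, 1L, cfg$parent_shared_rate) == 1L

  ## top up maternal informativeness per chromosome
  if (!is.null(cfg$min_maternal_informative)) {
    informative <- m_het * (2L - shared)
    for (ch in seq_len(nc)) {
      on_ch <- which(loci$chrom == ch)
      need <- cfg$min_maternal_informative - sum(informative[on_ch])
      while (need > 0L) {
        fixable <- on_ch[!(m_het[on_ch] & !shared[on_ch])]
        if (!length(fixable)) break
        pick <- fixable[sample.int(length(fixable), 1L)]
        m_het[pick] <- TRUE; shared[pick] <- FALSE
        informative[pick] <- 2L
        need <- cfg$min_maternal_informative - sum(m_het[on_ch] * (2L - shared[on_ch]))
      }
    }
  }

  ## variant sequences: v1 = ancestral; v2..v4 each mutate one distinct
  ## position, so any two variants of a locus differ at <= 2 bases
  variants <- make_variants(anc, cfg$tag_length)
  ## genotype in variant indices (1..4)
  mo <- cbind(1L, ifelse(m_het, 2L, 1L))
  fa <- cbind(ifelse(shared, 1L, 3L),
              ifelse(shared, ifelse(f_het, 3L, 1L), ifelse(f_het, 4L, 3L)))
  ## randomize which maternal homolog carries which allele
  swap <- stats::rbinom(total, 1L, 0.5) == 1L
  mo[swap, ] <- mo[swap, c(2L, 1L), drop = FALSE]

  ## allele table (variants actually carried by someone)
  used <- unique(data.table::data.table(
    locus = rep(loci$locus, 4L),
    variant = rep(1:4, each = total),
    used = c(mo[, 1L] == 1 | mo[, 2L] == 1 | fa[, 1L] == 1 | fa[, 2L] == 1,
             mo[, 1L] == 2 | mo[, 2L] == 2 | fa[, 1L] == 2 | fa[, 2L] == 2,
             mo[, 1L] == 3 | mo[, 2L] == 3 | fa[, 1L] == 3 | fa[, 2L] == 3,
             mo[, 1L] == 4 | mo[, 2L] == 4 | fa[, 1L] == 4 | fa[, 2L] == 4)
  ))[used == TRUE][, used := NULL]
  data.table::setorder(used, locus, variant)
  used[, seq := variants[cbind(locus, variant)]]
  used[, chrom := loci$chrom[locus]]
  in_mother <- used$variant == mo[used$locus, 1L] | used$variant == mo[used$locus, 2L]
  in_father <- used$variant == fa[used$locus, 1L] | used$variant == fa[used$locus, 2L]
  used[, origin := ifelse(in_mother & in_father, "shared",
                          ifelse(in_mother, "maternal", "paternal"))]

  ## transmission --------------------------------------------------------
  H <- matrix(sample(1:2, np * nc, replace = TRUE), nrow = np, ncol = nc)
  sexes <- if (!is.null(cfg$sex_linked_chromosome)) {
    ifelse(H[, cfg$sex_linked_chromosome] == 2L, "F", "M")
  } else {
    sample(c("M", "F"), np, replace = TRUE)
  }

  co_rows <- list()
  pat_variant <- matrix(0L, nrow = total, ncol = np) # father variant per progeny
  for (p in seq_len(np)) {
    for (ch in seq_len(nc)) {
      on_ch <- which(loci$chrom == ch)
      nl <- length(on_ch)
      nco <- stats::rpois(1L, cfg$male_crossovers)
      bp <- sort(stats::runif(nco, 0, nl))
      start <- sample(1:2, 1L)
      flips <- vapply(seq_len(nl), function(l) sum(bp < l - 0.5), integer(1))
      hvec <- 1L + (start - 1L + flips) %% 2L
      pat_variant[on_ch, p] <- fa[cbind(on_ch, hvec)]
      co_rows[[length(co_rows) + 1L]] <- data.table::data.table(
        individual_id = prog_ids[p], chrom = ch, n_crossovers = nco,
        breakpoints = paste(round(bp, 3L), collapse = ",")
      )
    }
  }

  ## genotype long table -------------------------------------------------
  geno <- data.table::rbindlist(c(
    list(
      data.table::data.table(individual_id = "mother", locus = loci$locus,
                             a1 = mo[, 1L], a2 = mo[, 2L]),
      data.table::data.table(individual_id = "father", locus = loci$locus,
                             a1 = fa[, 1L], a2 = fa[, 2L])
    ),
    lapply(seq_len(np), function(p) {
      hsel <- H[p, loci$chrom]
      mat_variant <- mo[cbind(seq_len(total), hsel)]
      data.table::data.table(individual_id = prog_ids[p], locus = loci$locus,
                             a1 = mat_variant, a2 = pat_variant[, p])
    })
  ))
  geno[, chrom := loci$chrom[locus]]

  ## expected chromosome-print patterns ----------------------------------
  pat1 <- apply(H == 1L, 2L, function(v) paste(as.integer(v), collapse = ""))
  maternal_patterns <- data.table::data.table(
    chrom = rep(seq_len(nc), each = 2L),
    homolog = rep(1:2, nc),
    pattern = as.vector(rbind(pat1, complement_pattern(pat1)))
  )

  manifest <- as_manifest(data.table::data.table(
    individual_id = inds,
    role = c("mother", "father", rep("progeny", np)),
    sex = c("F", "M", sexes),
    mid = unname(mids),
    status = "retained"
  ))

  structure(list(
    cfg = cfg, manifest = manifest, loci = loci, alleles = used[],
    genotypes = geno[], maternal_homolog = H,
    paternal_crossovers = data.table::rbindlist(co_rows),
    depth = depth, maternal_patterns = maternal_patterns, mids = mids
  ), class = "sim_truth")
}

## 4 variant sequences per locus: ancestral plus three single-base
## substitutions at distinct positions.
make_variants <- function(anc, tag_length) {
  total <- length(anc)
  variants <- matrix("", nrow = total, ncol = 4L)
  variants[, 1L] <- anc
  pos <- t(vapply(seq_len(total), function(i) sample.int(tag_length, 3L),
                  integer(3)))
  for (v in 2:4) {
    p <- pos[, v - 1L]
    orig <- substr(anc, p, p)
    ## substitute with the next base in a fixed cycle (deterministic,
    ## always different)
    subst <- chartr("ACGT", "CGTA", orig)
    variants[, v] <- paste0(substr(anc, 1L, p - 1L), subst,
                            substring(anc, p + 1L))
  }
  variants
}

empty_truth <- function(cfg, inds, mids, depth) {
  manifest <- as_manifest(data.table::data.table(
    individual_id = inds,
    role = c("mother", "father", rep("progeny", cfg$n_progeny)),
    sex = c("F", "M", rep("U", cfg$n_progeny)),
    mid = unname(mids), status = "retained"
  ))
  structure(list(
    cfg = cfg, manifest = manifest,
    loci = data.table::data.table(locus = integer(), chrom = integer(),
                                  pos = integer(), ancestral = character(),
                                  downstream = character()),
    alleles = data.table::data.table(locus = integer(), variant = integer(),
                                     seq = character(), chrom = integer(),
                                     origin = character()),
    genotypes = data.table::data.table(individual_id = character(),
                                       locus = integer(), a1 = integer(),
                                       a2 = integer(), chrom = integer()),
    maternal_homolog = matrix(integer(), nrow = cfg$n_progeny, ncol = 0L),
    paternal_crossovers = data.table::data.table(individual_id = character(),
                                                 chrom = integer(),
                                                 n_crossovers = integer(),
                                                 breakpoints = character()),
    depth = depth,
    maternal_patterns = data.table::data.table(chrom = integer(),
                                               homolog = integer(),
                                               pattern = character()),
    mids = mids
  ), class = "sim_truth")
}

#' Emit simulated paired-end FASTQ reads
#'
#' Per individual and allele copy, the number of independent sheared
#' fragments is Poisson with mean `fragments_per_allele x depth x dose`
#' (dose 2 for homozygous alleles); each fragment starts uniformly 300-700
#' bp downstream and is read `1 + Poisson(reads_per_fragment - 1)` times
#' (PCR duplicates share the identical mate). Forward reads are
#' `MID + footprint + tag`; substitution errors are injected at
#' `per_base_error` with matching constant qualities.
#'
#' @param truth a `sim_truth` from [simulate_pedigree()].
#' @param dir output directory.
#' @return list: `fwd`, `rev`, `manifest` (file paths), `read_counts`
#'   (named per-individual read counts).
#' @export
emit_reads <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$cfg
  set.seed(derive_seed(cfg$seed, 1L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  geno <- truth$genotypes
  loci <- truth$loci
  ## allele instance table: one row per (individual, locus, distinct allele)
  hom <- geno$a1 == geno$a2
  inst <- rbind(
    geno[hom == TRUE, .(individual_id, locus, variant = a1, dose = 2L)],
    geno[hom == FALSE, .(individual_id, locus, variant = a1, dose = 1L)],
    geno[hom == FALSE, .(individual_id, locus, variant = a2, dose = 1L)]
  )
  inst <- merge(inst, truth$alleles[, .(locus, variant, seq)],
                by = c("locus", "variant"), sort = FALSE)
  data.table::setorder(inst, individual_id, locus, variant)

  manifest_path <- file.path(dir, "manifest.tsv")
  data.table::fwrite(truth$manifest, manifest_path, sep = "\t")
  fwd_path <- file.path(dir, "fwd.fastq")
  rev_path <- file.path(dir, "rev.fastq")

  if (nrow(inst) == 0L) {
    write_fastq(character(0), character(0), character(0), fwd_path)
    write_fastq(character(0), character(0), character(0), rev_path)
    return(list(fwd = fwd_path, rev = rev_path, manifest = manifest_path,
                read_counts = stats::setNames(
                  integer(length(truth$manifest$individual_id)),
                  truth$manifest$individual_id)))
  }

  depth <- truth$depth
  lam <- cfg$fragments_per_allele * depth[inst$individual_id] * inst$dose
  nf <- stats::rpois(nrow(inst), lam)
  frag_inst <- rep(seq_len(nrow(inst)), nf)
  total_frags <- length(frag_inst)
  offsets <- sample(300:700, total_frags, replace = TRUE)
  ## mate = 51 bases starting at the sheared end inside the downstream
  ## region (index 1 corresponds to +300 bp from the cut site)
  down <- loci$downstream[inst$locus[frag_inst]]
  mate_frag <- substr(down, offsets - 299L, offsets - 249L)

  nreads <- 1L + stats::rpois(total_frags, cfg$reads_per_fragment - 1)
  read_frag <- rep(seq_len(total_frags), nreads)
  n_r <- length(read_frag)

  mid <- truth$mids[inst$individual_id]
  fwd_inst <- paste0(unname(mid), cfg$footprint, inst$seq)
  fwd_reads <- fwd_inst[frag_inst[read_frag]]
  rev_reads <- mate_frag[read_frag]

  ## sequencing errors ---------------------------------------------------
  e <- cfg$per_base_error
  if (e > 0) {
    fwd_reads <- inject_errors(fwd_reads, e)
    rev_reads <- inject_errors(rev_reads, e)
    q <- as.integer(round(-10 * log10(e)))
  } else {
    q <- 40L
  }
  fq <- strrep(intToUtf8(q + 33L), nchar(fwd_reads[1L]))
  rq <- strrep(intToUtf8(q + 33L), nchar(rev_reads[1L]))

  ids <- sprintf("sim_%07d", seq_len(n_r))
  write_fastq(fwd_reads, rep(fq, n_r), ids, fwd_path)
  write_fastq(rev_reads, rep(rq, n_r), ids, rev_path)

  rc_tab <- table(inst$individual_id[frag_inst[read_frag]])
  read_counts <- stats::setNames(
    integer(nrow(truth$manifest)), truth$manifest$individual_id)
  read_counts[names(rc_tab)] <- as.integer(rc_tab)

  list(fwd = fwd_path, rev = rev_path, manifest = manifest_path,
       read_counts = read_counts)
}

## Uniform substitution errors at rate e per base.
inject_errors <- function(seqs, e) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  k <- stats::rbinom(1L, n * L, e)
  if (k == 0L) return(seqs)
  rd <- sample.int(n, k, replace = TRUE)
  ps <- sample.int(L, k, replace = TRUE)
  orig <- substr(seqs[rd], ps, ps)
  ## shift each base by a random non-zero cycle amount -> always different
  shift <- sample.int(3L, k, replace = TRUE)
  maps <- c("CGTA", "GTAC", "TACG")
  newb <- vapply(1:3, function(s) chartr("ACGT", maps[s], orig), character(k))
  if (k == 1L) newb <- matrix(newb, nrow = 1L)
  base <- newb[cbind(seq_len(k), shift)]
  .mutate_bases(seqs, rd, ps, base)
}

#' Write truth tables as TSV
#'
#' @param truth a `sim_truth`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(truth$loci, file.path(dir, "truth_loci.tsv"), sep = "\t")
  data.table::fwrite(truth$alleles, file.path(dir, "truth_alleles.tsv"), sep = "\t")
  data.table::fwrite(truth$genotypes, file.path(dir, "truth_genotypes.tsv"), sep = "\t")
  data.table::fwrite(truth$paternal_crossovers,
                     file.path(dir, "truth_paternal_crossovers.tsv"), sep = "\t")
  data.table::fwrite(truth$maternal_patterns,
                     file.path(dir, "truth_maternal_patterns.tsv"), sep = "\t")
  prog <- progeny_ids(truth$manifest, retained_only = FALSE)
  if (ncol(truth$maternal_homolog) > 0L) {
    hm <- data.table::as.data.table(truth$maternal_homolog)
    data.table::setnames(hm, sprintf("chrom_%d", seq_len(ncol(hm))))
    hm[, individual_id := prog]
  } else {
    hm <- data.table::data.table(individual_id = prog)
  }
  data.table::fwrite(hm, file.path(dir, "truth_maternal_homolog.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(individual_id = names(truth$depth),
                           depth_multiplier = unname(truth$depth)),
    file.path(dir, "truth_depth.tsv"), sep = "\t")
  data.table::fwrite(truth$manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(dir)
}

#' Read truth tables back
#'
#' Round-trips the TSVs written by [write_truth()] into the same list
#' layout (matrices and key types restored).
#'
#' @param dir directory written by [write_truth()].
#' @return list with the table components of a `sim_truth`.
#' @export
read_truth <- function(dir) {
  hm <- data.table::fread(file.path(dir, "truth_maternal_homolog.tsv"))
  ids <- hm$individual_id
  hm[, individual_id := NULL]
  if (ncol(hm) > 0L) {
    H <- as.matrix(hm)
    rownames(H) <- ids
  } else {
    H <- matrix(integer(), nrow = length(ids), ncol = 0L,
                dimnames = list(ids, NULL))
  }
  depth_dt <- data.table::fread(file.path(dir, "truth_depth.tsv"))
  list(
    loci = data.table::fread(file.path(dir, "truth_loci.tsv"),
                             colClasses = list(character = c("ancestral", "downstream"))),
    alleles = data.table::fread(file.path(dir, "truth_alleles.tsv")),
    genotypes = data.table::fread(file.path(dir, "truth_genotypes.tsv")),
    paternal_crossovers = data.table::fread(
      file.path(dir, "truth_paternal_crossovers.tsv"),
      colClasses = list(character = "breakpoints")),
    maternal_patterns = data.table::fread(
      file.path(dir, "truth_maternal_patterns.tsv"),
      colClasses = list(character = "pattern")),
    maternal_homolog = H,
    depth = stats::setNames(depth_dt$depth_multiplier, depth_dt$individual_id),
    manifest = load_manifest(file.path(dir, "manifest.tsv"))
  )
}
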