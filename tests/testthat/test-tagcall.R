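test_that("collapse_uniques takes per-position medians and drops singletons", {
  tag <- strrep("AC", 20L)
  ## three identical reads with qualities 30, 30, 40 at every position
  tags <- make_tags(rep(tag, 3L),
                    qual = list(rep(30L, 40L), rep(30L, 40L), rep(40L, 40L)))
  uq <- collapse_uniques(tags)
  expect_equal(nrow(uq), 1L)
  expect_equal(uq$read_count, 3L)
  expect_equal(uq$med_qual[[1L]], rep(30, 40L))
  expect_length(uq$mates[[1L]], 3L)

  ## even count: median is the average of the central pair
  tags2 <- make_tags(rep(tag, 2L), qual = list(rep(30L, 40L), rep(41L, 40L)))
  expect_equal(collapse_uniques(tags2)$med_qual[[1L]], rep(35.5, 40L))

  ## singleton reads are discarded
  mix <- make_tags(c(rep(tag, 2L), strrep("GT", 20L)))
  uq2 <- collapse_uniques(mix)
  expect_equal(nrow(uq2), 1L)
  expect_identical(uq2$seq, tag)

  ## empty input
  expect_equal(nrow(collapse_uniques(make_tags(character(0)))), 0L)
})

test_that("weighted distance follows the correct-call probability product", {
  a <- strrep("A", 40L)
  b <- paste0("C", strrep("A", 39L))
  ## identical sequences
  expect_identical(weighted_distance(a, a, rep(40, 40L), rep(40, 40L)), 0)
  ## one mismatch, both Q40: (1 - 1e-4)^2
  expect_equal(weighted_distance(a, b, rep(40, 40L), rep(40, 40L)),
               0.99980001, tolerance = 1e-9)
  ## one mismatch at Q3 vs Q40
  expect_equal(weighted_distance(a, b, rep(3, 40L), rep(40, 40L)),
               (1 - 10^-0.3) * (1 - 10^-4), tolerance = 1e-9)
  expect_error(weighted_distance(a, "ACG", rep(40, 40L), rep(40, 3L)),
               "equal length")
})

test_that("weighted distance is bounded by Hamming and attains it at high Q", {
  set.seed(11)
  for (i in 1:25) {
    s1 <- rand_dna(1L, 40L)
    k <- sample(0:10, 1L)
    s2 <- if (k) mutate_at(s1, sample(40L, k)) else s1
    q1 <- sample(3:41, 40L, replace = TRUE)
    q2 <- sample(3:41, 40L, replace = TRUE)
    d <- weighted_distance(s1, s2, q1, q2)
    h <- sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
    expect_lte(d, h)
    expect_equal(weighted_distance(s1, s2, rep(41, 40L), rep(41, 40L)), h,
                 tolerance = 1e-3)
    ## symmetry
    expect_identical(d, weighted_distance(s2, s1, q2, q1))
  }
})

test_that("clustering separates uniques beyond the distance threshold", {
  base <- strrep("ACGT", 10L)
  ## 8 confident mismatches: weighted distance ~7.998 > 7 -> two loci
  far <- mutate_at(base, 1:8)
  cl <- cluster_uniques(make_uniques(c(base, far), qual = 40), 7)
  expect_equal(length(unique(cl$locus)), 2L)
  ## 7 confident mismatches: ~6.999 <= 7 -> one locus
  near <- mutate_at(base, 1:7)
  cl2 <- cluster_uniques(make_uniques(c(base, near), qual = 40), 7)
  expect_equal(length(unique(cl2$locus)), 1L)
  ## single-linkage chain: a-b and b-c close, a-c far -> one locus
  a <- base
  b <- mutate_at(base, 1:5)
  c3 <- mutate_at(base, 1:10)
  cl3 <- cluster_uniques(make_uniques(c(a, b, c3), qual = 40), 7)
  expect_equal(length(unique(cl3$locus)), 1L)
  ## singleton
  expect_equal(cluster_uniques(make_uniques(base))$locus, 1L)
})

test_that("clustering matches exhaustive connected components on small sets", {
  brute_components <- function(seqs, qlist, threshold) {
    n <- length(seqs)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- i == j ||
        weighted_distance(seqs[i], seqs[j], qlist[[i]], qlist[[j]]) <= threshold
    }
    ## transitive closure
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
    }
    comp <- integer(n)
    nc <- 0L
    for (i in seq_len(n)) {
      if (comp[i] == 0L) { nc <- nc + 1L; comp[which(adj[i, ])] <- nc }
    }
    comp
  }
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(2:12, 1L)
    base <- rand_dna(1L, 40L)
    seqs <- vapply(seq_len(n), function(i)
      mutate_at(base, sample(40L, sample(0:12, 1L))), character(1))
    qlist <- lapply(seq_len(n), function(i) sample(3:41, 40L, replace = TRUE))
    uq <- make_uniques(seqs, qual = qlist)
    ## distinct uniques only (cluster_uniques operates post-collapse)
    uq <- uq[!duplicated(seq)]
    got <- cluster_uniques(uq, 7)$locus
    want <- brute_components(uq$seq, uq$med_qual, 7)
    ## same partition (labels may differ)
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(want, levels = unique(want))))
  }
})

test_that("allele calling corrects weak single-unique bases and keeps real SNPs", {
  base <- strrep("GATC", 10L)
  snp <- mutate_at(base, 17L)
  err <- mutate_at(base, 5L)

  ## error derivative: 3 reads of a 40-read locus (< 10%), its private base
  ## is rejected and the unique merges into the major allele
  uq <- make_uniques(c(base, err), read_count = c(40L, 3L), qual = 35)
  al <- call_alleles(uq)
  expect_equal(nrow(al), 1L)
  expect_identical(al$seq, base)
  expect_equal(al$read_count, 43L)
  expect_length(al$mates[[1L]], 43L)

  ## balanced heterozygous locus: both haplotypes well supported -> 2 alleles
  uq2 <- make_uniques(c(base, snp), read_count = c(40L, 38L), qual = 35)
  al2 <- call_alleles(uq2)
  expect_equal(nrow(al2), 2L)
  expect_setequal(al2$seq, c(base, snp))

  ## difference at a position whose mean quality is below the threshold is
  ## ignored -> merge even for balanced uniques
  qlow <- rep(35, 40L); qlow[17L] <- 10
  uq3 <- make_uniques(c(base, snp), read_count = c(40L, 38L),
                      qual = list(qlow, qlow))
  al3 <- call_alleles(uq3, qual_threshold = 20)
  expect_equal(nrow(al3), 1L)
  expect_identical(al3$seq, base) # highest read count is the representative

  ## single-unique locus passes through
  al4 <- call_alleles(make_uniques(base, read_count = 7L))
  expect_equal(nrow(al4), 1L)
  expect_equal(al4$read_count, 7L)
})

test_that("allele read counts are conserved within each locus", {
  set.seed(31)
  for (rep in 1:10) {
    base <- rand_dna(1L, 40L)
    n <- sample(2:6, 1L)
    seqs <- unique(vapply(seq_len(n), function(i)
      mutate_at(base, sample(40L, sample(0:3, 1L))), character(1)))
    rc <- sample(2:60, length(seqs))
    uq <- make_uniques(seqs, read_count = rc,
                       qual = lapply(seq_along(seqs), function(i)
                         sample(15:41, 40L, replace = TRUE)))
    al <- call_alleles(uq)
    expect_equal(sum(al$read_count), sum(rc))
    ## every allele sequence is one of the input uniques (no chimeras)
    expect_true(all(al$seq %in% seqs))
  }
})

test_that("fragment counts are distinct mate sequences", {
  base <- strrep("AC", 20L)
  uq <- make_uniques(base, read_count = 3L, mates = list(c("X", "X", "Y")))
  al <- call_alleles(uq)
  expect_equal(al$fragment_count_raw, 2L)
  expect_equal(count_fragments(rep("Z", 5L)), 1L)
  expect_equal(count_fragments(sprintf("m%d", 1:10)), 10L)
  ## invariant: 1 <= fragments <= reads
  expect_true(al$fragment_count_raw >= 1L &&
                al$fragment_count_raw <= al$read_count)
})

test_that("error-free simulated reads yield exactly the true haplotypes", {
  cfg <- sim_config(n_chromosomes = 2L, loci_per_chromosome = 15,
                    n_progeny = 6L, min_maternal_informative = 5L,
                    per_base_error = 0, seed = 99)
  truth <- simulate_pedigree(cfg)
  dir <- withr::local_tempdir()
  em <- emit_reads(truth, dir)
  manifest <- load_manifest(em$manifest)
  pairs <- read_fastq_pairs(em$fwd, em$rev)
  dm <- demultiplex(pairs, manifest)
  al <- call_individual(dm$tags[["mother"]], "mother")
  mo_geno <- truth$genotypes[individual_id == "mother"]
  true_seqs <- truth$alleles[
    paste(locus, variant) %in% c(paste(mo_geno$locus, mo_geno$a1),
                                 paste(mo_geno$locus, mo_geno$a2)), seq]
  expect_setequal(al$allele_seq, true_seqs)
})
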