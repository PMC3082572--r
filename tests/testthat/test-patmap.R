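toy_paternal <- function(patterns, seqs = NULL) {
  data.table(allele_id = sprintf("P%04d", seq_along(patterns)),
             allele_seq = if (is.null(seqs)) rand_dna(length(patterns), 40L) else seqs,
             pattern = patterns,
             n_present = nchar(gsub("0", "", patterns, fixed = TRUE)))
}

test_that("paternal candidates are father-specific and segregating", {
  counts <- rbind(
    seg   = c(0, 9, rep(c(9, 0), 10)),   # father + 10 of 20 progeny
    full  = c(0, 9, rep(9, 20)),          # father + all progeny
    both  = c(9, 9, rep(9, 20)),          # both parents
    mom   = c(9, 0, rep(c(9, 0), 10))
  )
  colnames(counts) <- c("mother", "father", sprintf("p%02d", 1:20))
  catalog <- make_catalog(counts)
  manifest <- make_manifest(20)
  pat <- paternal_candidates(catalog, manifest)
  expect_equal(nrow(pat), 1L)
  expect_identical(pat$allele_seq, catalog$alleles$allele_seq[1L])
  expect_identical(pat$pattern, strrep("10", 10L))
})

test_that("allelic homology assigns only unambiguous chromosome matches", {
  m_seq <- rand_dna(3L, 40L)
  maternal <- data.table(allele_id = sprintf("M%d", 1:3),
                         allele_seq = m_seq,
                         chrom_id = c(5L, 3L, 7L), homolog = 1L)
  p_seqs <- c(mutate_at(m_seq[1L], c(2L, 8L)),   # 2 mismatches -> chrom 5
              rand_dna(1L, 40L),                  # no match
              mutate_at(m_seq[2L], 1L))           # 1 mismatch -> chrom 3
  pat <- toy_paternal(c("10101", "11100", "00111"), p_seqs)
  asg <- assign_by_allelism(pat, maternal)
  expect_identical(asg$chrom_id, c(5L, NA_integer_, 3L))
  expect_identical(asg$basis, c("allelism", "unassigned", "allelism"))

  ## a paternal allele matching two chromosomes stays unassigned
  maternal2 <- rbind(maternal,
                     data.table(allele_id = "M4",
                                allele_seq = mutate_at(m_seq[1L], 3L),
                                chrom_id = 9L, homolog = 2L))
  asg2 <- assign_by_allelism(pat, maternal2)
  expect_true(is.na(asg2$chrom_id[1L]))
  ## multiple matches on the SAME chromosome are fine
  maternal3 <- rbind(maternal,
                     data.table(allele_id = "M5",
                                allele_seq = mutate_at(m_seq[1L], 11L),
                                chrom_id = 5L, homolog = 2L))
  expect_identical(assign_by_allelism(pat, maternal3)$chrom_id[1L], 5L)
})

test_that("pattern propagation passes identical, inverse, then one-off", {
  anchor <- "11110000001111000000"
  pat <- toy_paternal(c(anchor,                         # seeds via allelism
                        anchor,                         # identical
                        chartr("01", "10", anchor),     # inverse
                        mutate_pattern(anchor, 3L),     # one-off
                        mutate_pattern(anchor, c(3L, 7L)))) # two-off: stays
  maternal <- data.table(allele_id = "M1", allele_seq = pat$allele_seq[1L],
                         chrom_id = 9L, homolog = 1L)
  asg <- propagate_patterns(assign_by_allelism(pat, maternal))
  expect_identical(asg$chrom_id, c(9L, 9L, 9L, 9L, NA))
  expect_identical(asg$basis,
                   c("allelism", "identical-pattern", "inverse-pattern",
                     "one-off-pattern", "unassigned"))
})

test_that("conflicting anchors leave alleles unassigned", {
  p <- "11001100110011001100"
  pat <- toy_paternal(c(p, p, p))
  ## the same pattern anchored on two chromosomes
  maternal <- data.table(allele_id = c("M1", "M2"),
                         allele_seq = pat$allele_seq[1:2],
                         chrom_id = c(1L, 2L), homolog = 1L)
  asg0 <- assign_by_allelism(pat, maternal)
  asg <- propagate_patterns(asg0)
  expect_true(is.na(asg$chrom_id[3L]))
  expect_true(p %in% attr(asg, "conflicts"))
})

test_that("markers collapse patterns with their complements in phase", {
  p <- "10101010101010101010"
  asg <- data.table(
    allele_id = sprintf("P%d", 1:10),
    allele_seq = rand_dna(10L, 40L),
    pattern = c(rep(p, 3L), rep(chartr("01", "10", p), 2L),
                rep("11111000001111100000", 2L),
                rep("00000111110000011111", 2L),
                "11011000001101100000"),
    chrom_id = c(rep(4L, 5L), rep(6L, 4L), 6L),
    basis = "allelism"
  )
  mk <- collapse_markers(asg)
  ## 3 + 2 complementary alleles on chrom 4 -> one marker of 5
  expect_equal(mk[chrom_id == 4L, allele_count], 5L)
  expect_identical(mk[chrom_id == 4L, pattern], p) # majority phase
  ## 2 + 2 on chrom 6 -> one marker of 4; the singleton pattern is dropped
  expect_equal(nrow(mk), 2L)
  expect_equal(mk[chrom_id == 6L, allele_count], 4L)
  ## groups below min_alleles are discarded entirely
  expect_equal(nrow(collapse_markers(asg[9:10], min_alleles = 3L)), 0L)
})

test_that("two-point statistics follow the backcross likelihood", {
  p0 <- strrep("10", 10L)
  same <- two_point_stats(p0, p0)
  expect_equal(same$R, 0L)
  expect_equal(same$lod, 20 * log10(2), tolerance = 1e-12)
  ## complements fold to R = 0
  comp <- two_point_stats(p0, chartr("01", "10", p0))
  expect_equal(comp$R, 0L)
  expect_equal(comp$lod, 20 * log10(2), tolerance = 1e-12)
  ## half the progeny differ: independence
  indep <- two_point_stats(p0, "10101010100101010101")
  expect_equal(indep$r, 0.5)
  expect_equal(indep$lod, 0)
  expect_error(two_point_stats("", ""), "non-empty")
})

test_that("the LOD closed form matches a brute-force likelihood grid", {
  set.seed(71)
  grid <- seq(1e-6, 0.5, length.out = 20001L)
  for (i in 1:20) {
    N <- sample(c(10L, 20L, 30L), 1L)
    p1 <- paste(sample(0:1, N, replace = TRUE), collapse = "")
    p2 <- paste(sample(0:1, N, replace = TRUE), collapse = "")
    tp <- two_point_stats(p1, p2)
    loglik <- function(r) (N - tp$R) * log10(1 - r) + tp$R * log10(r) -
      N * log10(0.5)
    best <- max(loglik(grid))
    expect_equal(tp$lod, max(best, 0), tolerance = 1e-4)
    ## and the maximizing r is R/N
    if (tp$R > 0L && tp$r < 0.5) {
      expect_equal(grid[which.max(loglik(grid))], tp$r, tolerance = 1e-3)
    }
  }
})

mk_table <- function(patterns, chrom = 1L) {
  out <- data.table(marker_id = seq_along(patterns), chrom_id = chrom,
                    pattern = patterns,
                    allele_count = 3L + seq_along(patterns),
                    allele_ids = lapply(seq_along(patterns), function(i) list()))
  setattr(out, "class", c("rad_markers", class(out)))
  out
}

test_that("linkage grouping applies the crossover-count distance convention", {
  base <- paste(rep(c("1", "0"), each = 10L), collapse = "")
  ## one recombinant out of 20 -> linked at 5 cM
  mk <- mk_table(c(base, mutate_pattern(base, 1L)))
  mp <- build_groups(mk)
  expect_equal(nrow(mp$groups), 1L)
  expect_equal(mp$groups$length_cm, 5)
  ## six recombinants -> separate components
  mk2 <- mk_table(c(base, mutate_pattern(base, 1:6)))
  mp2 <- build_groups(mk2)
  expect_equal(nrow(mp2$groups), 2L)
  expect_equal(sum(mp2$groups$length_cm), 0)
  ## single marker: one group of length 0
  mp3 <- build_groups(mk_table(base))
  expect_equal(mp3$groups$length_cm, 0)
  ## cm_per_event override
  mp4 <- build_groups(mk_table(c(base, mutate_pattern(base, 1L))),
                      cm_per_event = 2.5)
  expect_equal(mp4$groups$length_cm, 2.5)
})

test_that("marker order and totals are invariant to input order and phase", {
  set.seed(81)
  base <- paste(sample(0:1, 20L, replace = TRUE), collapse = "")
  pats <- c(base, mutate_pattern(base, 1L), mutate_pattern(base, 1:2),
            mutate_pattern(base, 1:3))
  mk <- mk_table(pats)
  mp <- build_groups(mk)
  perm <- c(3L, 1L, 4L, 2L)
  mk2 <- mk_table(pats[perm])
  mp2 <- build_groups(mk2)
  expect_equal(sum(mp$groups$length_cm), sum(mp2$groups$length_cm))
  expect_equal(nrow(mp$groups), nrow(mp2$groups))
  ## flipping one marker to its complement changes nothing
  pats3 <- pats
  pats3[2L] <- chartr("01", "10", pats3[2L])
  mp3 <- build_groups(mk_table(pats3))
  expect_equal(mp3$groups$length_cm, mp$groups$length_cm)
  expect_equal(mp3$map$cum_cm, mp$map$cum_cm)
})

test_that("greedy ordering with 2-opt matches exhaustive enumeration", {
  set.seed(91)
  for (i in 1:15) {
    n <- sample(5:8, 1L)
    pts <- sort(runif(n, 0, 10))
    D <- abs(outer(pts, pts, "-")) + matrix(runif(n * n, 0, 0.3), n, n)
    D <- round((D + t(D)) / 2, 2)
    diag(D) <- 0
    path_cost <- getFromNamespace("path_cost", "radprint")
    ex <- order_markers(D, method = "exhaustive")
    gr <- order_markers(D, method = "greedy")
    expect_equal(path_cost(D, gr), path_cost(D, ex), tolerance = 1e-9)
  }
})

test_that("map statistics reproduce the kb/cM arithmetic", {
  fake_map <- structure(list(
    map = data.table(chrom_id = 1L, component = 1L, position = 1:2,
                     marker_id = 1:2, pattern = "", allele_count = 3L,
                     cum_cm = c(0, 1292)),
    groups = data.table(chrom_id = 1L, component = 1L, n_markers = 2L,
                        length_cm = 1292)
  ), class = "rad_map")
  st <- map_stats(fake_map, genome_size_bp = 339.4e6)
  expect_equal(st$kb_per_cm, 262.7)
  expect_equal(st$total_cm, 1292)
  ## no genome size, or zero-length map -> undefined density
  expect_true(is.na(map_stats(fake_map)$kb_per_cm))
  fake0 <- fake_map
  fake0$groups$length_cm <- 0
  expect_true(is.na(map_stats(fake0, 339.4e6)$kb_per_cm))
})
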