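## A toy catalog: 2 parents + 5 progeny, alleles placed by hand.
toy_setup <- function() {
  manifest <- make_manifest(5, sexes = c("F", "M", "F", "M", "M"))
  inds <- c("mother", "father", sprintf("p%02d", 1:5))
  counts <- rbind(
    mom_seg1  = c(9, 0, 9, 0, 9, 0, 0),  # mother + p01,p03 -> 10100
    mom_seg1b = c(8, 0, 7, 0, 8, 0, 0),  # same pattern
    mom_seg2  = c(9, 0, 0, 9, 0, 9, 9),  # complement 01011
    mom_hom   = c(9, 0, 9, 9, 9, 9, 9),  # all progeny -> homozygous class
    both_par  = c(9, 9, 9, 0, 0, 0, 0),  # in both parents -> excluded
    dad_seg   = c(0, 9, 9, 9, 0, 0, 0),  # paternal candidate 11000
    dad_all   = c(0, 9, 9, 9, 9, 9, 9),  # paternal, non-segregating
    orphan    = c(9, 0, 0, 0, 0, 0, 9)   # maternal 00001
  )
  colnames(counts) <- inds
  catalog <- make_catalog(counts)
  list(manifest = manifest, catalog = catalog,
       seqs = setNames(catalog$alleles$allele_seq, rownames(counts)))
}

test_that("maternal candidates are mother-present father-absent with patterns", {
  ts <- toy_setup()
  cand <- maternal_candidates(ts$catalog, ts$manifest)
  expect_setequal(
    cand$allele_seq,
    ts$seqs[c("mom_seg1", "mom_seg1b", "mom_seg2", "mom_hom", "orphan")])
  expect_identical(cand[allele_seq == ts$seqs["mom_seg1"], pattern], "10100")
  expect_identical(cand[allele_seq == ts$seqs["mom_hom"], pattern], "11111")
  ## both-parent allele excluded
  expect_false(ts$seqs["both_par"] %in% cand$allele_seq)
})

test_that("patterns of excluded progeny are omitted", {
  ts <- toy_setup()
  manifest2 <- make_manifest(5, sexes = c("F", "M", "F", "M", "M"),
                             excluded = "p02")
  cand <- maternal_candidates(ts$catalog, manifest2)
  expect_identical(nchar(cand$pattern[1]), 4L)
  expect_identical(cand[allele_seq == ts$seqs["mom_seg1"], pattern], "1100")
})

test_that("pattern grouping splits segregating / homozygous / null", {
  ts <- toy_setup()
  cand <- maternal_candidates(ts$catalog, ts$manifest)
  g <- group_patterns(cand)
  expect_equal(nrow(g$homozygous), 1L)
  expect_equal(g$homozygous$n_alleles, 1L)
  expect_equal(sum(g$segregating$n_alleles), 4L)
  expect_equal(g$segregating[pattern == "10100", n_alleles], 2L)
  ## grouping 5 + 3 alleles sharing complementary patterns
  cand2 <- data.table(allele_id = sprintf("A%d", 1:8),
                      allele_seq = rand_dna(8, 40),
                      pattern = c(rep("10110", 5), rep("01001", 3)),
                      n_present = 3L)
  g2 <- group_patterns(cand2)
  expect_equal(sort(g2$segregating$n_alleles), c(3L, 5L))
  ## empty input
  g3 <- group_patterns(cand2[0])
  expect_equal(nrow(g3$segregating), 0L)
})

test_that("complement pairing builds prints and leaves residuals", {
  groups <- data.table(
    pattern = c("10110", "01001", "11000"),
    n_alleles = c(4L, 2L, 7L),
    allele_ids = list(sprintf("a%d", 1:4), c("b1", "b2"), sprintf("c%d", 1:7))
  )
  pc <- pair_complements(groups)
  expect_equal(nrow(pc$prints), 1L)
  expect_equal(pc$prints$total, 6L)
  expect_identical(pc$prints$pattern_1, "10110") # better-supported side first
  expect_identical(pc$residuals$pattern, "11000")
  ## complement involution: no pattern appears in two prints
  expect_false(anyDuplicated(c(pc$prints$pattern_1, pc$prints$pattern_2)) > 0)
  ## expected_chromosomes larger than available -> warning
  expect_warning(pair_complements(groups, expected_chromosomes = 3), "fewer")
})

test_that("the 62 published segregation patterns pair into 31 prints with printed totals", {
  t2 <- fread(fixture("px_segregation_patterns.tsv"),
              colClasses = list(character = c("pattern_1", "pattern_2")))
  groups <- data.table(
    pattern = c(t2$pattern_1, t2$pattern_2),
    n_alleles = c(t2$alleles_1, t2$alleles_2)
  )
  groups[, allele_ids := lapply(n_alleles, function(n) sprintf("x%d", seq_len(n)))]
  ## shuffle rows: pairing must not depend on input order
  set.seed(1); groups <- groups[sample(.N)]
  pc <- pair_complements(groups, expected_chromosomes = 31)
  expect_equal(nrow(pc$prints), 31L)
  expect_equal(nrow(pc$residuals), 0L)
  expect_equal(sum(pc$prints$total), 3177L)
  ## the best-supported print is the published LG5 pair (108 + 82 = 190)
  expect_equal(pc$prints$total[1L], 190L)
  expect_setequal(
    c(pc$prints$n_alleles_1[1L], pc$prints$n_alleles_2[1L]), c(108L, 82L))
  ## per-pair totals match the published Totals column
  t2[, key := pmin(pattern_1, pattern_2)]
  pr <- pc$prints
  pr[, key := pmin(pattern_1, pattern_2)]
  m <- merge(pr[, .(key, total)],
             t2[, .(key, want = alleles_1 + alleles_2)], by = "key")
  expect_equal(nrow(m), 31L)
  expect_equal(m$total, m$want)
})

test_that("homozygous-maternal classification takes exactly the all-ones patterns", {
  ts <- toy_setup()
  cand <- maternal_candidates(ts$catalog, ts$manifest)
  hom <- classify_homozygous_maternal(cand)
  expect_identical(hom$allele_seq, unname(ts$seqs["mom_hom"]))
  expect_equal(nrow(classify_homozygous_maternal(cand[0])), 0L)
})

test_that("candidate alleles are conserved across prints, residuals and homozygous class", {
  ts <- toy_setup()
  cand <- maternal_candidates(ts$catalog, ts$manifest)
  g <- group_patterns(cand)
  pc <- pair_complements(g$segregating)
  n_prints <- sum(pc$prints$total)
  n_resid <- sum(pc$residuals$n_alleles)
  n_hom <- nrow(classify_homozygous_maternal(cand))
  n_null <- sum(g$null$n_alleles)
  expect_equal(n_prints + n_resid + n_hom + n_null, nrow(cand))
})

test_that("sex chromosome identification matches the female indicator", {
  ## toy: sexes FMFMM, print 10100/01011
  groups <- data.table(
    pattern = c("10100", "01011"),
    n_alleles = c(4L, 6L),
    allele_ids = list(sprintf("a%d", 1:4), sprintf("b%d", 1:6))
  )
  pc <- pair_complements(groups)
  sx <- identify_sex_chromosome(
    pc, c(p1 = "F", p2 = "M", p3 = "F", p4 = "M", p5 = "M"))
  expect_identical(sx$w_pattern, "10100")
  expect_identical(sx$z_pattern, "01011")
  ## no match -> NULL
  expect_null(identify_sex_chromosome(
    pc, c(p1 = "M", p2 = "M", p3 = "F", p4 = "M", p5 = "M")))
})

test_that("the published sexes pick out the sex-chromosome print with 39 W / 65 Z alleles", {
  t2 <- fread(fixture("px_segregation_patterns.tsv"),
              colClasses = list(character = c("pattern_1", "pattern_2")))
  groups <- data.table(
    pattern = c(t2$pattern_1, t2$pattern_2),
    n_alleles = c(t2$alleles_1, t2$alleles_2)
  )
  groups[, allele_ids := lapply(n_alleles, function(n) list())]
  pc <- pair_complements(groups)
  sexes <- strsplit("FMFMMMFFFMMMMMFFFMMM", "")[[1]]
  names(sexes) <- sprintf("p%02d", 1:20)
  sx <- identify_sex_chromosome(pc, sexes)
  expect_equal(sx$n_w, 39L)
  expect_equal(sx$n_z, 65L)
  ## W pattern is present exactly in the female progeny
  expect_identical(sx$w_pattern,
                   paste(as.integer(sexes == "F"), collapse = ""))
})

test_that("false-negative presence noise creates residuals one bit from prints", {
  set.seed(61)
  ## clean pedigree-level candidate set: 12 chromosomes, two complementary
  ## patterns each, 15 alleles per pattern
  n_prog <- 20L
  repeat {
    pats <- vapply(seq_len(12L), function(i)
      paste(sample(0:1, n_prog, replace = TRUE), collapse = ""), character(1))
    all_pats <- c(pats, chartr("01", "10", pats))
    w <- nchar(gsub("0", "", pats, fixed = TRUE))
    if (uniqueN(all_pats) == 24L && !any(w %in% c(0L, n_prog))) break
  }
  cand <- data.table(
    allele_id = sprintf("A%04d", seq_len(24L * 15L)),
    allele_seq = rand_dna(24L * 15L, 40L),
    pattern = rep(all_pats, each = 15L),
    n_present = 5L
  )
  ## inject false negatives: flip a present call to absent for 2% of alleles
  flip <- sample(nrow(cand), 24L)
  for (ix in flip) {
    p <- cand$pattern[ix]
    ones <- which(strsplit(p, "")[[1]] == "1")
    k <- sample(ones, 1L)
    substr(p, k, k) <- "0"
    cand$pattern[ix] <- p
  }
  g <- group_patterns(cand)
  pc <- pair_complements(g$segregating, expected_chromosomes = 12L)
  expect_equal(nrow(pc$prints), 12L)
  print_pats <- c(pc$prints$pattern_1, pc$prints$pattern_2)
  hd <- vapply(pc$residuals$pattern, function(p)
    min(vapply(print_pats, function(q)
      sum(strsplit(p, "")[[1]] != strsplit(q, "")[[1]]), numeric(1))),
    numeric(1))
  expect_equal(unname(stats::median(hd)), 1)
})

test_that("low-coverage exclusion rule flags the two dropped study individuals", {
  t1 <- fread(fixture("px_read_counts.tsv"))
  counts <- setNames(t1$reads, t1$individual_id)
  flagged <- names(counts)[flag_low_coverage(counts)]
  expect_setequal(flagged, c("Control_5", "Bioassay_12"))
})
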