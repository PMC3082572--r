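## Shared low-level helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Decode Phred quality strings
#'
#' Converts quality strings to an integer matrix (one row per read, one
#' column per base). Qualities are capped at 41, the ceiling of the
#' GAIIx-era Phred scale.
#'
#' @param qual character vector of quality strings (equal lengths).
#' @param offset Phred ASCII offset, 33 (Sanger/Illumina 1.8+) or 64
#'   (Illumina 1.3-1.7).
#' @return integer matrix of qualities.
#' @export
decode_qualities <- function(qual, offset = 33L) {
  if (!offset %in% c(33L, 64L)) stop("phred offset must be 33 or 64")
  .qual_to_matrix(qual, as.integer(offset), 41L)
}

## Encode an integer quality matrix/vector as phred-33 strings.
encode_qualities <- function(q) {
  if (is.matrix(q)) {
    apply(q, 1L, function(v) intToUtf8(pmin(v, 41L) + 33L))
  } else {
    intToUtf8(pmin(q, 41L) + 33L)
  }
}

## Connected components by single linkage over an edge list (1-based vertex
## indices). Returns an integer component id per vertex, components numbered
## in order of their smallest vertex.
single_linkage <- function(n, from, to) {
  if (n == 0L) return(integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  ## renumber by first appearance for reproducibility
  as.integer(factor(comp, levels = unique(comp)))
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  sum(x != y)
}

## Bitwise complement of a "0"/"1" pattern string.
complement_pattern <- function(p) chartr("01", "10", p)

## Canonical key identifying a pattern and its complement as one phase pair.
pattern_key <- function(p) {
  q <- complement_pattern(p)
  ifelse(p <= q, p, q)
}

## Number of 1s in a pattern string.
pattern_weight <- function(p) {
  nchar(p) - nchar(gsub("1", "", p, fixed = TRUE))
}

#' Size of the segregation-pattern space
#'
#' Number of distinct presence/absence patterns that `n_progeny` backcross
#' progeny admit (2^n). With 20 progeny this exceeds one million, which is
#' why the ~62 patterns actually observed in a lepidopteran backcross are
#' individually informative about chromosome identity.
#'
#' @param n_progeny number of scored progeny.
#' @return number of possible patterns (double).
#' @export
pattern_space_size <- function(n_progeny) 2^n_progeny

## Random DNA sequences.
random_dna <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

## Deterministic sub-seed derivation (kept < 2^31).
derive_seed <- function(seed, k) (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
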