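# Small programmatic fixtures shared across test files.

# Build a genotype_dataset from a call matrix with minimal metadata.
make_dataset <- function(calls, chrom = NULL, pos = NULL, breed = NULL,
                         a1 = NULL, a2 = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1e4
  if (is.null(breed)) breed <- rep("B1", n)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("C", m)
  genotype_dataset(
    samples = data.frame(sample_id = sprintf("s%03d", seq_len(n)), breed = breed),
    variants = data.frame(id = sprintf("v%04d", seq_len(m)), chrom = chrom,
                          pos_bp = pos, a1 = a1, a2 = a2),
    calls = calls
  )
}

# Random call matrix with optional missingness, for property-style loops.
random_calls <- function(n, m, miss = 0, maf = NULL) {
  p <- if (is.null(maf)) runif(m, 0.1, 0.9) else rep(maf, m)
  g <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (miss > 0) g[runif(n * m) < miss] <- NA_integer_
  g
}

# A two-breed dataset with a fixed allele-frequency contrast, for F_ST tests.
two_breed_dataset <- function(n1, n2, m, p1, p2, chrom = NULL, pos = NULL) {
  g1 <- matrix(rbinom(n1 * m, 2L, rep_len(p1, m)[col(matrix(0, n1, m))]), n1, m)
  g2 <- matrix(rbinom(n2 * m, 2L, rep_len(p2, m)[col(matrix(0, n2, m))]), n2, m)
  make_dataset(rbind(g1, g2), chrom = chrom, pos = pos,
               breed = rep(c("B1", "B2"), c(n1, n2)))
}
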