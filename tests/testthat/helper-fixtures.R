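## Shared fixtures, all generated in code.

## small genotype matrix with known content
toy_genotypes <- function() {
  d <- matrix(c(0, 1, 2,
                2, 1, 0), nrow = 3)
  rownames(d) <- c("s1", "s2", "s3")
  map <- data.frame(id = c("snpA", "snpB"), chrom = c("1", "2"),
                    pos = c(100L, 200L), ref = c("A", "C"),
                    alt = c("G", "T"), stringsAsFactors = FALSE)
  genotype_matrix(d, map)
}

## random genotype matrix (no missing) for property tests
rand_genotypes <- function(n, q, seed = 1, maf = c(0.1, 0.5)) {
  sim_genotypes(sim_config(n = n, q = q, p = 2L, maf_range = maf, seed = seed))
}

## random PSD matrix A A' / k with unit-ish diagonal
rand_psd <- function(n, k = 2 * n, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n * k), n, k) / sqrt(k)
  m <- tcrossprod(a)
  rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
  m
}

## uniform OTU table (every entry 1/p)
uniform_otus <- function(n = 4, p = 5) {
  m <- matrix(1 / p, n, p,
              dimnames = list(paste0("s", 1:n), paste0("o", 1:p)))
  otu_table_rel(m)
}

## three-gene GFF3 fixture written to a temp file
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    paste("1", "src", "gene", "1000", "2000", ".", "+", ".",
          "ID=gene:G1;Name=ALPHA;biotype=protein_coding", sep = "\t"),
    paste("1", "src", "gene", "5000", "8000", ".", "-", ".",
          "ID=gene:G2;Name=BETA;biotype=protein_coding", sep = "\t"),
    paste("2", "src", "gene", "100", "900", ".", "+", ".",
          "ID=gene:G3;Name=GAMMA;biotype=lncRNA", sep = "\t")),
    path)
  path
}

## explicit-inverse GLS: the independent oracle for the whitened scan
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  C <- solve(t(X) %*% Vi %*% X)
  beta <- C %*% t(X) %*% Vi %*% y
  list(beta = as.numeric(beta), se = unname(sqrt(diag(C))))
}
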