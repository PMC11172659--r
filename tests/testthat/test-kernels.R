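test_that("genotype standardization matches the closed form and centers", {
  d <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("s", 1:3), "snp1"))
  map <- data.frame(id = "snp1", chrom = "1", pos = 1L, ref = "A", alt = "B")
  g <- genotype_matrix(d, map)
  xs <- standardize_genotypes(g)
  expect_equal(unname(xs[, 1]), c(-1, 0, 1) / sqrt(0.5), tolerance = 1e-12)

  ## all-heterozygote column standardizes to zero
  d2 <- matrix(1, 4, 1, dimnames = list(paste0("s", 1:4), "snp1"))
  g2 <- genotype_matrix(d2, map)
  expect_equal(max(abs(standardize_genotypes(g2))), 0)

  ## column means zero, also with missing entries (mean imputation)
  g3 <- rand_genotypes(40, 30, seed = 3)
  g3$dosages[cbind(sample(40, 10), sample(30, 10, replace = TRUE))] <- NA
  g3 <- genotype_matrix(g3$dosages, g3$snps)
  expect_lt(max(abs(colMeans(standardize_genotypes(g3)))), 1e-12)

  ## monomorphic SNP is an error naming the SNP
  d4 <- cbind(mono = rep(2, 3), ok = c(0, 1, 2))
  rownames(d4) <- paste0("s", 1:3)
  map4 <- data.frame(id = colnames(d4), chrom = "1", pos = 1:2,
                     ref = "A", alt = "B")
  expect_error(standardize_genotypes(genotype_matrix(d4, map4)), "mono")
})

test_that("GRM matches hand products and a brute-force double loop", {
  xs <- matrix(c(1, -1, -1, 1), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  G <- compute_grm(xs, q = 2)
  expect_equal(unname(G$values), matrix(c(2, -2, -2, 2), 2, 2))
  expect_s3_class(G, "rel_matrix")
  expect_equal(G$kind, "GRM")
  expect_error(compute_grm(xs[, 1, drop = FALSE], q = 1), "q >= 2")

  ## duplicate individuals give identical rows/columns
  xs2 <- rbind(xs, xs[1, ])
  rownames(xs2) <- c("a", "b", "a2")
  G2 <- compute_grm(xs2, q = 2)
  expect_equal(G2$values["a", ], G2$values["a2", ], ignore_attr = TRUE)
  expect_equal(G2$values["a", "a"], G2$values["a2", "a2"])

  ## brute-force oracle on a random 20 x 50 matrix
  set.seed(11)
  xr <- matrix(rnorm(20 * 50), 20, 50,
               dimnames = list(paste0("s", 1:20), NULL))
  Gr <- compute_grm(xr)$values
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (k in 1:20)
    brute[i, k] <- sum(xr[i, ] * xr[k, ]) / 49
  expect_lt(max(abs(Gr - brute)), 1e-10)
})

test_that("MRM matches brute force, handles rank-1 and degenerate inputs", {
  n <- 15; p <- 30
  set.seed(12)
  r <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n), NULL))
  M <- compute_mrm(r)$values
  brute <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n)
    brute[i, k] <- sum(r[i, ] * r[k, ]) / p
  expect_lt(max(abs(M - brute)), 1e-10)
  expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  ## zero matrix in, zero kernel out
  z <- matrix(0, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(max(abs(compute_mrm(z)$values)), 0)

  ## single OTU: M = r r'
  r1 <- matrix(c(1, 2, -1), 3, 1, dimnames = list(paste0("s", 1:3), NULL))
  expect_equal(unname(compute_mrm(r1)$values), tcrossprod(c(1, 2, -1)))

  expect_error(compute_mrm(r, p = 10), "does not match")
})

test_that("Cholesky cross-covariance kernel matches a closed-form 2x2 oracle", {
  n <- 4
  I4 <- diag(1, n)
  rownames(I4) <- colnames(I4) <- paste0("s", 1:n)
  Gi <- rel_matrix(I4, kind = "GRM")
  Mi <- rel_matrix(I4, kind = "MRM")
  expect_equal(unname(compute_hrm_cg(Gi, Mi)$values), 2 * diag(1, n))

  ## explicit 2x2 Cholesky formulas as an independent oracle:
  ## chol([[1,a],[a,1]]) lower = [[1,0],[a,sqrt(1-a^2)]]
  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  M <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  lg <- matrix(c(1, 0.5, 0, sqrt(1 - 0.25)), 2, 2)
  lm_ <- matrix(c(1, 0.2, 0, sqrt(1 - 0.04)), 2, 2)
  cross <- lm_ %*% t(lg)
  oracle <- cross + t(cross)
  h <- compute_hrm_cg(rel_matrix(G, kind = "GRM"),
                      rel_matrix(M, kind = "MRM"))
  expect_lt(max(abs(h$values - oracle)), 1e-12)
  ## symmetric exactly
  expect_identical(h$values, t(h$values))
})

test_that("h_c(G, G) equals 2 G for positive-definite G", {
  G <- rand_psd(10, seed = 21) + diag(0.1, 10)
  rg <- rel_matrix(G, kind = "GRM")
  mg <- rel_matrix(G, kind = "MRM")
  h <- compute_hrm_cg(rg, mg)
  expect_lt(max(abs(h$values - 2 * G)), 1e-8)
})

test_that("Hadamard kernel is entrywise, commutative and PSD for PSD inputs", {
  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  M <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h <- compute_hrm_h(rel_matrix(G, kind = "GRM"), rel_matrix(M, kind = "MRM"))
  expect_equal(unname(h$values), matrix(c(1, 0.1, 0.1, 1), 2, 2))

  ## G o I is the diagonal of G
  n <- 6
  Gp <- rand_psd(n, seed = 22)
  I_ <- diag(1, n); dimnames(I_) <- dimnames(Gp)
  hd <- compute_hrm_h(rel_matrix(Gp, kind = "GRM"), rel_matrix(I_, kind = "MRM"))
  expect_equal(unname(hd$values), diag(diag(Gp)))

  ## commutative exactly; PSD for random PSD inputs
  for (s in 1:5) {
    A <- rand_psd(8, seed = 30 + s); B <- rand_psd(8, seed = 60 + s)
    h1 <- compute_hrm_h(rel_matrix(A, kind = "GRM"), rel_matrix(B, kind = "MRM"))
    h2 <- compute_hrm_h(rel_matrix(B, kind = "GRM"), rel_matrix(A, kind = "MRM"))
    expect_identical(h1$values, h2$values)
    expect_gte(min(eigen(h1$values, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }

  ## dimension mismatch
  expect_error(compute_hrm_h(rel_matrix(Gp, kind = "GRM"),
                             rel_matrix(G, kind = "MRM")), "dimension")
})

test_that("kernel builders are permutation-equivariant", {
  g <- rand_genotypes(12, 40, seed = 5)
  xs <- standardize_genotypes(g)
  perm <- sample(12)
  G1 <- compute_grm(xs)$values
  G2 <- compute_grm(xs[perm, ])$values
  expect_equal(unname(G2), unname(G1[perm, perm]), tolerance = 1e-12)

  set.seed(6)
  r <- matrix(rnorm(12 * 20), 12, 20, dimnames = list(rownames(xs), NULL))
  M1 <- compute_mrm(r)$values
  M2 <- compute_mrm(r[perm, ])$values
  expect_equal(unname(M2), unname(M1[perm, perm]), tolerance = 1e-12)

  H1 <- compute_hrm_h(rel_matrix(G1, kind = "GRM"),
                      rel_matrix(M1, kind = "MRM"))$values
  expect_equal(unname(H1[perm, perm]),
               unname(compute_hrm_h(rel_matrix(G1[perm, perm], kind = "GRM"),
                                    rel_matrix(M1[perm, perm],
                                               kind = "MRM"))$values),
               tolerance = 1e-12)
})

test_that("GRM diagonal is near one on HWE-simulated genotypes", {
  g <- sim_genotypes(sim_config(n = 300, q = 2000, seed = 9))
  G <- compute_grm(standardize_genotypes(g))
  md <- mean(diag(G$values))
  expect_gt(md, 0.9)
  expect_lt(md, 1.1)
})

test_that("principal components match eigenstructure and a power-iteration oracle", {
  ## rank-1 kernel: first PC proportional to v, remaining eigenvalues 0
  v <- c(3, -1, 2, 0.5)
  K <- tcrossprod(v)
  dimnames(K) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pcs <- compute_pcs(rel_matrix(K, kind = "GRM"), k = 3)
  ev <- attr(pcs, "eigenvalues")
  expect_equal(ev[2:3], c(0, 0), tolerance = 1e-10)
  cors <- abs(sum(pcs[, 1] * v) / sqrt(sum(pcs[, 1]^2) * sum(v^2)))
  expect_equal(cors, 1, tolerance = 1e-10)

  ## power iteration as an independent oracle for the top eigenvalue
  K2 <- rand_psd(10, seed = 44)
  x <- rep(1, 10)
  for (i in 1:2000) { x <- K2 %*% x; x <- x / sqrt(sum(x^2)) }
  lam1 <- as.numeric(t(x) %*% K2 %*% x)
  pcs2 <- compute_pcs(rel_matrix(K2, kind = "GRM"), k = 4)
  expect_equal(attr(pcs2, "eigenvalues")[1], lam1, tolerance = 1e-8)

  ## score columns orthogonal; sign convention: top loading positive
  cross <- crossprod(pcs2)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)
  for (j in 1:4) expect_gte(pcs2[which.max(abs(pcs2[, j] /
                                                 sqrt(sum(pcs2[, j]^2)))), j], 0)

  expect_error(compute_pcs(rel_matrix(K2, kind = "GRM"), k = 11), "exceeds")
})

test_that("ensure_pd jitters or clips as requested", {
  K <- rand_psd(6, seed = 7) + diag(0.5, 6)
  out <- ensure_pd(K)
  expect_false(out$report$modified)
  expect_identical(out$matrix, (K + t(K)) / 2)

  ## rank-deficient v v' becomes choleskyable under jitter
  v <- rnorm(5)
  out2 <- ensure_pd(tcrossprod(v), policy = "jitter")
  expect_true(out2$report$modified)
  expect_silent(chol(out2$matrix))

  ## clip-eigen floors the spectrum at tol
  U <- qr.Q(qr(matrix(c(1, 1, 1, -1), 2, 2)))
  K3 <- U %*% diag(c(2, -0.5)) %*% t(U)
  out3 <- ensure_pd(K3, policy = "clip-eigen", tol = 1e-8)
  ev <- sort(eigen(out3$matrix, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(abs(ev - c(1e-8, 2))), 1e-10)
})

test_that("kernel TSV round-trips values, kind and metadata", {
  g <- rand_genotypes(8, 30, seed = 8)
  G <- compute_grm(standardize_genotypes(g))
  path <- tempfile(fileext = ".tsv")
  write_kernel_tsv(G, path)
  G2 <- read_kernel_tsv(path)
  expect_equal(G2$values, G$values, tolerance = 1e-14)
  expect_equal(G2$kind, "GRM")
  expect_equal(G2$meta$q, 30)
  expect_equal(G2$samples, G$samples)
})
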