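#' Relationship matrix (kernel) container
#'
#' An n x n symmetric kernel over samples, tagged by kind: `GRM` (genomic),
#' `MRM` (microbial), `HRM_CG` (hologenome, Cholesky cross-covariance) or
#' `HRM_H` (hologenome, Hadamard product). GRM, MRM and HRM_H are positive
#' semi-definite by construction; HRM_CG is a cross-covariance term and may
#' be indefinite.
#'
#' @param values n x n numeric matrix.
#' @param samples sample IDs (default rownames).
#' @param kind one of `"GRM"`, `"MRM"`, `"HRM_CG"`, `"HRM_H"`.
#' @param meta named list of provenance (divisor used, flags, jitter).
#' @return an object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, samples = rownames(values),
                       kind = c("GRM", "MRM", "HRM_CG", "HRM_H"),
                       meta = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(values)))
  if (nrow(values) != ncol(values)) stop_hw("kernel must be square")
  if (length(samples) != nrow(values)) stop_hw("sample IDs do not match kernel dimension")
  if (!all(is.finite(values))) stop_hw("kernel has non-finite entries")
  if (!is_symmetric_tol(values, 1e-10))
    stop_hw(kind, " kernel is not symmetric within 1e-10")
  values <- (values + t(values)) / 2  # exact symmetry for downstream chol/eigen
  dimnames(values) <- list(samples, samples)
  structure(list(samples = as.character(samples), values = values,
                 kind = kind, meta = meta),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix %s> %d x %d, mean diag %.3f\n",
              x$kind, nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

as_kernel_values <- function(k) if (inherits(k, "rel_matrix")) k$values else as.matrix(k)

#' Standardize genotype dosages
#'
#' Column j becomes `(dosage - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j`
#' the alt-allele frequency computed from non-missing dosages
#' (VanRaden-style, unit variance under Hardy-Weinberg equilibrium).
#' Missing dosages are mean-imputed (to `2 p_j`) before centering, so they
#' standardize to exactly zero.
#'
#' @param g a [genotype_matrix()].
#' @return n x q numeric matrix `X_S`.
#' @export
standardize_genotypes <- function(g) {
  p <- g$freqs
  mono <- which(!is.finite(p) | p <= 0 | p >= 1)
  if (length(mono))
    stop_hw("monomorphic SNP(s) present (frequency 0 or 1): ",
            paste(head(g$snps$id[mono], 5), collapse = ", "),
            " — remove them (qc_filter_genotypes) before standardization")
  d <- g$dosages
  if (anyNA(d)) {
    mu <- rep(2 * p, each = nrow(d))
    d[is.na(d)] <- mu[is.na(d)]
  }
  xs <- sweep(d, 2L, 2 * p, `-`)
  sweep(xs, 2L, sqrt(2 * p * (1 - p)), `/`)
}

#' Genomic relationship matrix
#'
#' `G = X_S X_S' / (q - 1)` from the standardized genotype matrix.
#'
#' @param x_s standardized genotypes from [standardize_genotypes()].
#' @param q SNP count (default `ncol(x_s)`); must be >= 2.
#' @return a [rel_matrix()] of kind `GRM`.
#' @export
compute_grm <- function(x_s, q = ncol(x_s)) {
  if (q < 2) stop_hw("GRM needs q >= 2 SNPs (divisor q - 1)")
  rel_matrix(tcrossprod(x_s) / (q - 1), samples = rownames(x_s),
             kind = "GRM", meta = list(q = q))
}

#' Microbial relationship matrix
#'
#' `M = R R' / p` from the log-transformed OTU abundance matrix, with p
#' the number of OTUs.
#'
#' @param r n x p log-abundance matrix from [log_transform_otus()].
#' @param p OTU count (default `ncol(r)`).
#' @return a [rel_matrix()] of kind `MRM`.
#' @export
compute_mrm <- function(r, p = ncol(r)) {
  if (p < 1) stop_hw("MRM needs p >= 1 OTUs")
  if (p != ncol(r))
    stop_hw(sprintf("p = %d does not match ncol(r) = %d", p, ncol(r)))
  rel_matrix(tcrossprod(r) / p, samples = rownames(r),
             kind = "MRM",
             meta = list(p = p,
                         pseudocount = attr(r, "pseudocount"),
                         centered = attr(r, "centered")))
}

#' Hologenome kernel: Cholesky cross-covariance
#'
#' `h_c = L_M L_G' + (L_M L_G')'` with `L_G`, `L_M` the lower Cholesky
#' factors of G and M. This kernel carries the covariance between genomic
#' and microbial effects; it is symmetric by construction but may be
#' indefinite, so its variance-component coefficient is treated as an
#' unconstrained covariance parameter downstream. Rank-deficient inputs
#' are jittered (see [ensure_pd()]) until their Cholesky succeeds; any
#' jitter applied is recorded in `meta`.
#'
#' @param G,M [rel_matrix()] objects (or plain matrices) on the same samples.
#' @param jitter_policy passed to [ensure_pd()] (`"jitter"` default).
#' @return a [rel_matrix()] of kind `HRM_CG`.
#' @export
compute_hrm_cg <- function(G, M, jitter_policy = "jitter") {
  g <- as_kernel_values(G); m <- as_kernel_values(M)
  check_same_samples(G, M)
  gp <- ensure_pd(g, policy = jitter_policy)
  mp <- ensure_pd(m, policy = jitter_policy)
  lg <- t(chol(gp$matrix))
  lm_ <- t(chol(mp$matrix))
  cross <- lm_ %*% t(lg)
  h <- cross + t(cross)
  rel_matrix(h, samples = kernel_samples(G, n = nrow(g)), kind = "HRM_CG",
             meta = list(jitter_G = gp$report$epsilon, jitter_M = mp$report$epsilon))
}

#' Hologenome kernel: Hadamard product
#'
#' Entrywise product `(h_hp)_ij = G_ij * M_ij`; positive semi-definite
#' whenever both inputs are (Schur product theorem).
#'
#' @inheritParams compute_hrm_cg
#' @return a [rel_matrix()] of kind `HRM_H`.
#' @export
compute_hrm_h <- function(G, M) {
  g <- as_kernel_values(G); m <- as_kernel_values(M)
  if (!all(dim(g) == dim(m))) stop_hw("G and M have different dimensions")
  check_same_samples(G, M)
  rel_matrix(g * m, samples = kernel_samples(G, n = nrow(g)), kind = "HRM_H")
}

kernel_samples <- function(k, n) {
  if (inherits(k, "rel_matrix")) k$samples
  else rownames(as.matrix(k)) %||% paste0("S", seq_len(n))
}

check_same_samples <- function(a, b) {
  if (inherits(a, "rel_matrix") && inherits(b, "rel_matrix") &&
      !identical(a$samples, b$samples))
    stop_hw("kernels are defined on different sample sets")
  invisible(TRUE)
}

#' Genotype principal components
#'
#' Top-k eigenvectors of the GRM scaled by the square root of their
#' eigenvalues, in descending eigenvalue order. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param G a [rel_matrix()] (typically the GRM) or symmetric matrix.
#' @param k number of components (<= n).
#' @return matrix of PC scores (n x k, columns `PC1..PCk`) with the
#'   eigenvalues in `attr(, "eigenvalues")`.
#' @export
compute_pcs <- function(G, k = 5L) {
  g <- as_kernel_values(G)
  n <- nrow(g)
  if (k > n) stop_hw(sprintf("k = %d exceeds n = %d", k, n))
  e <- eigen(g, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  sc <- sweep(vec, 2L, sqrt(pmax(e$values[seq_len(k)], 0)), `*`)
  dimnames(sc) <- list(kernel_samples(G, n), paste0("PC", seq_len(k)))
  attr(sc, "eigenvalues") <- e$values[seq_len(k)]
  sc
}

#' Force a symmetric matrix to be positive definite
#'
#' `policy = "jitter"` adds `eps * mean(diag(K))` to the diagonal, with
#' `eps` escalating tenfold from 1e-8 until the Cholesky succeeds (or
#' `eps > 1e-2`, an error). `policy = "clip-eigen"` floors the
#' eigenvalues at `tol` and reconstructs.
#'
#' @param K symmetric matrix (or [rel_matrix()]).
#' @param policy `"jitter"` or `"clip-eigen"`.
#' @param tol eigenvalue floor for `"clip-eigen"`.
#' @return list with `matrix` and a `report` (`modified`, `policy`,
#'   `epsilon` or `n_clipped`).
#' @export
ensure_pd <- function(K, policy = c("jitter", "clip-eigen"), tol = 1e-8) {
  policy <- match.arg(policy)
  k <- as_kernel_values(K)
  if (!is_symmetric_tol(k, 1e-8)) stop_hw("ensure_pd: input is not symmetric")
  k <- (k + t(k)) / 2
  ok <- !inherits(try(chol(k), silent = TRUE), "try-error")
  if (ok)
    return(list(matrix = k, report = list(modified = FALSE, policy = policy,
                                          epsilon = 0)))
  if (policy == "jitter") {
    md <- mean(diag(k))
    if (md <= 0) md <- 1
    eps <- 1e-8
    while (eps <= 1e-2) {
      kj <- k + diag(eps * md, nrow(k))
      if (!inherits(try(chol(kj), silent = TRUE), "try-error"))
        return(list(matrix = kj,
                    report = list(modified = TRUE, policy = "jitter",
                                  epsilon = eps)))
      eps <- eps * 10
    }
    ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    stop_hw(sprintf("Cholesky failed even at jitter 1e-2 (min eigenvalue %.3g)",
                    min(ev)))
  }
  e <- eigen(k, symmetric = TRUE)
  vals <- pmax(e$values, tol)
  kc <- e$vectors %*% (vals * t(e$vectors))
  kc <- (kc + t(kc)) / 2
  list(matrix = kc,
       report = list(modified = TRUE, policy = "clip-eigen",
                     n_clipped = sum(e$values < tol), floor = tol))
}

#' Serialize / read a kernel as TSV plus a metadata sidecar
#'
#' Values are written at 15 significant digits with sample IDs as header
#' and first column; `<path>.meta` records the kind and provenance.
#'
#' @param k a [rel_matrix()].
#' @param path output TSV path.
#' @export
write_kernel_tsv <- function(k, path) {
  m <- format(k$values, digits = 15, trim = TRUE, scientific = TRUE)
  df <- data.frame(sample_id = k$samples, m, check.names = FALSE)
  colnames(df) <- c("sample_id", k$samples)
  write_tsv_atomic(df, path)
  meta <- c(sprintf("kind\t%s", k$kind),
            vapply(names(k$meta), function(nm)
              sprintf("%s\t%s", nm, paste(format(k$meta[[nm]]), collapse = ",")),
              character(1)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  kind <- "GRM"; meta <- list()
  mp <- paste0(path, ".meta")
  if (file.exists(mp)) {
    kv <- strsplit(readLines(mp), "\t", fixed = TRUE)
    for (x in kv) {
      if (x[1] == "kind") kind <- x[2]
      else meta[[x[1]]] <- utils::type.convert(x[2], as.is = TRUE)
    }
  }
  rel_matrix(m, kind = kind, meta = meta)
}
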