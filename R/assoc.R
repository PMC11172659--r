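#' Model specification for an association scan
#'
#' The four models differ only by their random-effect kernels:
#' * `GWAS` — genomic kernel only (`GRM`);
#' * `M-GWAS` — microbial kernel only (`MRM`);
#' * `HWAS-CG` — `GRM`, `MRM` and the Cholesky cross-covariance hologenome
#'   kernel (`HRM_CG`);
#' * `HWAS-H` — `GRM`, `MRM` and the Hadamard-product hologenome kernel
#'   (`HRM_H`).
#'
#' @param name model name.
#' @param kernels named list of [rel_matrix()] objects whose kinds must
#'   match the model definition exactly (order as listed above).
#' @param trait trait column name in the phenotype table.
#' @param covariates character vector of covariate column names (an
#'   intercept is always added).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name = c("GWAS", "M-GWAS", "HWAS-CG", "HWAS-H"),
                       kernels, trait, covariates = character()) {
  name <- match.arg(name)
  required <- switch(name,
                     "GWAS" = "GRM",
                     "M-GWAS" = "MRM",
                     "HWAS-CG" = c("GRM", "MRM", "HRM_CG"),
                     "HWAS-H" = c("GRM", "MRM", "HRM_H"))
  kinds <- vapply(kernels, function(k) {
    if (!inherits(k, "rel_matrix")) stop_hw("kernels must be rel_matrix objects")
    k$kind
  }, character(1))
  if (!identical(unname(kinds), required))
    stop_hw(sprintf("model %s requires kernels [%s], got [%s]",
                    name, paste(required, collapse = ", "),
                    paste(kinds, collapse = ", ")))
  samp <- lapply(kernels, `[[`, "samples")
  if (length(kernels) > 1 && !all(vapply(samp[-1], identical, logical(1), samp[[1]])))
    stop_hw("all kernels must share the same sample set and order")
  structure(list(name = name, kernels = kernels, trait = trait,
                 covariates = covariates),
            class = "model_spec")
}

#' Whitening rotation from a fitted covariance matrix
#'
#' Eigendecomposes `V = U D U'` once and returns
#' `y* = D^{-1/2} U' y`, `X* = D^{-1/2} U' X` together with the rotation
#' matrix, so that generalized least squares under V becomes ordinary
#' least squares with unit error variance. This single decomposition is
#' what makes the per-SNP scan fast.
#'
#' @param V symmetric positive-definite covariance matrix (or a fitted
#'   `variance_components` object, whose `V` is used).
#' @param y trait vector; `X` covariate matrix.
#' @return list with `y_star`, `X_star`, `rotation` (the n x n whitening
#'   matrix) and `eigenvalues`.
#' @export
whiten <- function(V, y, X) {
  if (inherits(V, "variance_components")) V <- V$V
  V <- as.matrix(V)
  if (!is_symmetric_tol(V, 1e-8)) stop_hw("V must be symmetric")
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop_hw(sprintf("V is not positive definite (min eigenvalue %.3g)",
                    min(e$values)))
  rot <- t(e$vectors) / sqrt(e$values)   # D^{-1/2} U'
  list(y_star = as.numeric(rot %*% y),
       X_star = rot %*% as.matrix(X),
       rotation = rot,
       eigenvalues = e$values)
}

#' Per-SNP Wald association scan on whitened data
#'
#' Each (mean-imputed) dosage column is rotated by the whitening transform,
#' appended to the rotated covariates, and its effect estimated by least
#' squares. Because the fitted V already carries the full phenotypic
#' covariance, the whitened residual variance is 1 by construction and the
#' standard error comes directly from the design:
#' `se^2 = 1 / (s*' M s*)` with `M` the projection off `X*`. The Wald
#' statistic `W = (effect/se)^2` is referred to the upper tail of
#' chi-squared with 1 df. SNP columns that are constant after rotation are
#' flagged and reported with missing p-values.
#'
#' @param wh whitening object from [whiten()].
#' @param genotypes a [genotype_matrix()] on the same samples, same order.
#' @param model,trait labels stored with the result.
#' @param vc optional `variance_components` object stored with the result.
#' @return data.frame of class `assoc_result` with columns `snp_id`,
#'   `chrom`, `pos`, `effect`, `se`, `wald`, `p`, `flag`; attributes
#'   `model`, `trait`, `n`, `q_tested`, `lambda_gc`, `vc`.
#' @export
wald_scan <- function(wh, genotypes, model = "GWAS", trait = "y", vc = NULL) {
  n <- length(wh$y_star)
  if (length(genotypes$samples) != n)
    stop_hw("genotypes and whitening rotation have different sample counts")
  d <- genotypes$dosages
  if (anyNA(d)) {                         # mean-impute at test time
    mu <- rep(2 * genotypes$freqs, each = n)
    d[is.na(d)] <- mu[is.na(d)]
  }
  S <- wh$rotation %*% d
  qx <- qr(wh$X_star)
  ry <- qr.resid(qx, wh$y_star)
  RS <- qr.resid(qx, S)
  ss <- colSums(RS^2)
  degenerate <- ss <= 1e-12 * pmax(colSums(S^2), .Machine$double.xmin)
  ss[degenerate] <- NA_real_
  effect <- colSums(RS * ry) / ss
  se <- 1 / sqrt(ss)
  wald <- (effect / se)^2
  p <- pchisq(wald, df = 1, lower.tail = FALSE)
  out <- data.frame(
    snp_id = genotypes$snps$id, chrom = genotypes$snps$chrom,
    pos = genotypes$snps$pos, effect = effect, se = se, wald = wald, p = p,
    flag = ifelse(degenerate, "constant_after_rotation", ""),
    stringsAsFactors = FALSE, row.names = NULL)
  lam <- if (sum(!is.na(wald)) >= 10) genomic_inflation(out) else NA_real_
  structure(out, class = c("assoc_result", "data.frame"),
            model = model, trait = trait, n = n,
            q_tested = nrow(out), lambda_gc = lam, vc = vc)
}

#' Run a full association model
#'
#' Orchestrates the scan: estimate variance components once under the
#' no-SNP null, whiten with the fitted V, then test every SNP with the
#' fixed rotation (EMMAX/P3D-style). With `exact_per_snp = TRUE` the
#' variance components are re-estimated for every SNP (slow; used to
#' verify the approximation).
#'
#' @param spec a [model_spec()].
#' @param data an aligned `hologenome_data` triple from [align_samples()],
#'   or any list with `genotypes` and `phenotypes`.
#' @param exact_per_snp re-fit the variance components per SNP.
#' @param ... passed to [fit_variance_components()].
#' @return an `assoc_result` (see [wald_scan()]) carrying the fitted
#'   `variance_components` in its attributes.
#' @export
run_model <- function(spec, data, exact_per_snp = FALSE, ...) {
  ph <- data$phenotypes
  g <- data$genotypes
  if (!spec$trait %in% names(ph)) stop_hw("trait not found: ", spec$trait)
  missing_cov <- setdiff(spec$covariates, names(ph))
  if (length(missing_cov))
    stop_hw("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
  ksamp <- spec$kernels[[1]]$samples
  if (!identical(ksamp, g$samples))
    stop_hw("kernel samples do not match genotype samples; align first")
  y <- as.numeric(ph[[spec$trait]])
  if (anyNA(y)) stop_hw("trait has missing values; subset samples first")
  X <- build_design(ph, spec$covariates)
  vc <- fit_variance_components(y, X, spec$kernels, ...)
  wh <- whiten(vc$V, y, X)
  res <- wald_scan(wh, g, model = spec$name, trait = spec$trait, vc = vc)
  if (exact_per_snp) {
    d <- g$dosages
    if (anyNA(d)) {
      mu <- rep(2 * g$freqs, each = nrow(d))
      d[is.na(d)] <- mu[is.na(d)]
    }
    for (j in seq_len(ncol(d))) {
      sj <- d[, j]
      if (sd(sj) < 1e-12) next
      Xj <- cbind(X, snp = sj)
      vj <- fit_variance_components(y, Xj, spec$kernels, ...)
      gls <- gls_fixed_effects(y, Xj, vj$V)
      k <- ncol(Xj)
      res$effect[j] <- gls$beta[k]
      res$se[j] <- gls$se[k]
      res$wald[j] <- (gls$beta[k] / gls$se[k])^2
      res$p[j] <- pchisq(res$wald[j], 1, lower.tail = FALSE)
    }
    attr(res, "lambda_gc") <- genomic_inflation(res)
  }
  res
}

## intercept + covariates; categorical covariates expand via model.matrix
build_design <- function(ph, covariates) {
  if (!length(covariates))
    return(matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)")))
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  stats::model.matrix(f, data = as.data.frame(ph))
}

## GLS with explicit inverse; also serves small-scale verification paths
gls_fixed_effects <- function(y, X, V) {
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(X, Vi %*% X)
  C <- chol2inv(chol(XtViX))
  beta <- C %*% crossprod(X, Vi %*% y)
  list(beta = as.numeric(beta), se = sqrt(diag(C)), cov = C)
}

#' Write an association result as TSV
#'
#' Header comment lines (prefixed `#`) carry the model name, trait,
#' variance-component estimates and the genomic-inflation factor.
#'
#' @param res an `assoc_result`.
#' @param path output file.
#' @export
write_assoc_tsv <- function(res, path) {
  vc <- attr(res, "vc")
  hdr <- c(sprintf("# model\t%s", attr(res, "model")),
           sprintf("# trait\t%s", attr(res, "trait")),
           sprintf("# n\t%d", attr(res, "n")),
           sprintf("# q_tested\t%d", attr(res, "q_tested")),
           sprintf("# lambda_gc\t%.6g", attr(res, "lambda_gc")))
  if (!is.null(vc))
    hdr <- c(hdr, sprintf("# vc_%s\t%.8g", names(vc$components), vc$components))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(hdr, tmp)
  suppressWarnings(
    data.table::fwrite(as.data.frame(res), tmp, sep = "\t", quote = FALSE,
                       na = "NA", append = TRUE, col.names = TRUE))
  file.rename(tmp, path)
  invisible(path)
}
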