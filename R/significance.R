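#' Bonferroni genome-wide threshold
#'
#' `alpha / n_tested`, the family-wise error controlling p-value cutoff.
#'
#' @param alpha significance level in (0, 1).
#' @param n_tested number of SNPs tested (>= 1).
#' @return list with `threshold` and `neg_log10`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tested) {
  if (length(n_tested) != 1L || is.na(n_tested) || n_tested < 1)
    stop_hw("n_tested must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop_hw("alpha must be in (0, 1)")
  thr <- alpha / n_tested
  list(threshold = thr, neg_log10 = -log10(thr))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via `stats::p.adjust`), with input
#' validation; original order is preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop_hw("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Permutation genome-wide significance threshold (GWST)
#'
#' Family-wise threshold from the null distribution of the minimum p-value:
#' the whitened trait residuals are permuted `T` times with a seeded
#' generator (Freedman-Lane style: permuted residuals are re-projected off
#' the covariates), the fast scan re-run per permutation, and the
#' empirical `alpha`-quantile of the per-permutation minimum p-values
#' returned.
#'
#' @param wh whitening object from [whiten()].
#' @param genotypes a [genotype_matrix()] aligned with `wh`.
#' @param T number of permutations (>= 20; `T * alpha >= 1` required).
#' @param alpha family-wise level.
#' @param seed RNG seed (required, for reproducibility).
#' @return list with `threshold`, `min_p` (the permutation distribution),
#'   `T`, `alpha`, `seed`.
#' @export
gwst_threshold <- function(wh, genotypes, T = 1000L, alpha = 0.05,
                           seed = 1L) {
  if (T < 20L) stop_hw("T must be >= 20 permutations")
  k <- floor(alpha * T)
  if (k < 1L)
    stop_hw(sprintf("T = %d too small for the alpha = %g quantile", T, alpha))
  n <- length(wh$y_star)
  d <- genotypes$dosages
  if (anyNA(d)) {
    mu <- rep(2 * genotypes$freqs, each = n)
    d[is.na(d)] <- mu[is.na(d)]
  }
  S <- wh$rotation %*% d
  qx <- qr(wh$X_star)
  ry <- qr.resid(qx, wh$y_star)
  RS <- qr.resid(qx, S)
  ss <- colSums(RS^2)
  usable <- ss > 1e-12 * pmax(colSums(S^2), .Machine$double.xmin)
  RS <- RS[, usable, drop = FALSE]
  ss <- ss[usable]
  min_p <- with_seed(seed, {
    vapply(seq_len(T), function(t_) {
      yp <- qr.resid(qx, ry[sample.int(n)])
      w <- (crossprod(RS, yp)[, 1])^2 / ss
      pchisq(max(w), df = 1, lower.tail = FALSE)
    }, numeric(1))
  })
  list(threshold = sort(min_p)[k], min_p = min_p, T = T, alpha = alpha,
       seed = seed)
}

#' Significant-SNP counts under the four significance regimes
#'
#' For each scan: the arbitrary threshold (p <= 0.05), Benjamini-Hochberg
#' FDR (adjusted p <= alpha), Bonferroni correction (p <= alpha/n_tested)
#' and, when supplied or requested, the permutation genome-wide threshold.
#'
#' @param results a single `assoc_result` or a named list of them
#'   (typically one per model).
#' @param alpha level for the FDR / Bonferroni / GWST regimes.
#' @param arbitrary fixed "arbitrary" cutoff (default 0.05).
#' @param gwst either `NULL` (regime reported as NA), a fixed numeric
#'   threshold, or a named list of [gwst_threshold()] results per model.
#' @return object of class `threshold_report`: list with `counts` (model x
#'   regime data.frame), `snps` (per model, per regime ID lists) and
#'   `provenance`.
#' @export
summarize_thresholds <- function(results, alpha = 0.05, arbitrary = 0.05,
                                 gwst = NULL) {
  if (inherits(results, "assoc_result")) results <- list(results)
  if (!length(results)) stop_hw("no scan results supplied")
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r)
      attr(r, "model") %||% "scan", character(1))
  rows <- list(); snps <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    p <- r$p
    bc <- bonferroni_threshold(alpha, sum(!is.na(p)))$threshold
    padj <- bh_adjust(p)
    thr_g <- if (is.numeric(gwst)) gwst
      else if (is.list(gwst) && !is.null(gwst[[nm]])) gwst[[nm]]$threshold
      else NA_real_
    pass <- list(
      arbitrary = r$snp_id[!is.na(p) & p <= arbitrary],
      fdr_bh = r$snp_id[!is.na(padj) & padj <= alpha],
      bc = r$snp_id[!is.na(p) & p <= bc],
      gwst = if (is.na(thr_g)) character(0)
             else r$snp_id[!is.na(p) & p <= thr_g])
    rows[[nm]] <- data.frame(
      model = nm, n_tested = sum(!is.na(p)),
      arbitrary = length(pass$arbitrary), fdr_bh = length(pass$fdr_bh),
      bc = length(pass$bc),
      gwst = if (is.na(thr_g)) NA_integer_ else length(pass$gwst),
      stringsAsFactors = FALSE)
    snps[[nm]] <- pass
  }
  structure(list(counts = do.call(rbind, c(rows, make.row.names = FALSE)),
                 snps = snps,
                 provenance = list(alpha = alpha, arbitrary = arbitrary,
                                   gwst = gwst)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write a threshold report (model x regime count matrix) as TSV
#' @param report a `threshold_report`.
#' @param path output TSV; per-regime SNP lists go to `<path>.snps.tsv`.
#' @export
write_threshold_report <- function(report, path) {
  write_tsv_atomic(report$counts, path)
  lists <- do.call(rbind, lapply(names(report$snps), function(nm) {
    do.call(rbind, lapply(names(report$snps[[nm]]), function(rg) {
      ids <- report$snps[[nm]][[rg]]
      if (!length(ids)) return(NULL)
      data.frame(model = nm, regime = rg, snp_id = ids,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(lists))
    lists <- data.frame(model = character(0), regime = character(0),
                        snp_id = character(0))
  write_tsv_atomic(lists, paste0(path, ".snps.tsv"))
  invisible(path)
}

#' Genomic inflation factor
#'
#' `lambda = median(W) / qchisq(0.5, 1)` — the median observed Wald
#' statistic over the null chi-squared(1) median (about 0.4549). Values
#' near 1 indicate a calibrated scan; values above 1 indicate inflation.
#'
#' @param results an `assoc_result`, or a numeric vector of Wald
#'   statistics.
#' @return lambda (single number).
#' @export
genomic_inflation <- function(results) {
  w <- if (is.numeric(results)) results else results$wald
  w <- w[!is.na(w)]
  if (length(w) < 10) stop_hw("need at least 10 non-missing test statistics")
  median(w) / qchisq(0.5, df = 1)
}
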