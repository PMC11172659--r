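#' OTU relative-abundance table
#'
#' Samples x OTUs matrix of relative abundances; each row sums to one.
#'
#' @param rel_abund numeric matrix, samples in rows, OTUs in columns.
#' @param samples sample IDs (default rownames).
#' @param otus OTU IDs (default colnames).
#' @return an object of class `otu_table_rel`.
#' @export
otu_table_rel <- function(rel_abund, samples = rownames(rel_abund),
                          otus = colnames(rel_abund)) {
  rel_abund <- as.matrix(rel_abund)
  storage.mode(rel_abund) <- "double"
  if (is.null(samples) || is.null(otus))
    stop_hw("sample and OTU IDs are required (dimnames or arguments)")
  check_no_duplicates(samples, "sample")
  check_no_duplicates(otus, "OTU")
  if (any(rel_abund < 0)) stop_hw("relative abundances must be >= 0")
  rs <- rowSums(rel_abund)
  if (any(abs(rs - 1) > 1e-6))
    stop_hw("OTU table rows must sum to 1 (max deviation ",
            format(max(abs(rs - 1))), ")")
  dimnames(rel_abund) <- list(samples, otus)
  structure(list(samples = as.character(samples), otus = as.character(otus),
                 rel_abund = rel_abund),
            class = "otu_table_rel")
}

#' @export
print.otu_table_rel <- function(x, ...) {
  cat(sprintf("<otu_table_rel> %d samples x %d OTUs\n",
              length(x$samples), length(x$otus)))
  invisible(x)
}

#' Read an OTU relative-abundance TSV (header = OTU IDs, first column = sample ID)
#' @param path TSV file.
#' @param normalize if `TRUE` (default), rows are rescaled to sum to one,
#'   so count tables are accepted too.
#' @return an [otu_table_rel()].
#' @export
read_otu_tsv <- function(path, normalize = TRUE) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (normalize) {
    rs <- rowSums(m)
    if (any(rs <= 0)) stop_hw("OTU table has all-zero sample row(s)")
    m <- m / rs
  }
  otu_table_rel(m)
}

#' @rdname read_otu_tsv
#' @param t an [otu_table_rel()].
#' @export
write_otu_tsv <- function(t, path) {
  df <- data.frame(sample_id = t$samples, t$rel_abund, check.names = FALSE)
  write_tsv_atomic(df, path)
}

#' Prevalence / abundance filter for OTUs
#'
#' Drops OTUs present (nonzero) in fewer than `prevalence_min` of samples
#' (boundary inclusive: exactly the threshold is kept), or — with
#' `mode = "abundance"` — OTUs whose mean relative abundance falls below
#' the threshold. Remaining rows are re-normalized to sum to one.
#'
#' @param t an [otu_table_rel()].
#' @param prevalence_min fraction in \[0, 1\].
#' @param mode `"prevalence"` (default) or `"abundance"`.
#' @return filtered `otu_table_rel` with removal report in
#'   `attr(, "removed")`.
#' @export
qc_filter_otus <- function(t, prevalence_min = 0.2,
                           mode = c("prevalence", "abundance")) {
  mode <- match.arg(mode)
  check_fraction(prevalence_min, "prevalence_min")
  stat <- if (mode == "prevalence") colMeans(t$rel_abund > 0)
          else colMeans(t$rel_abund)
  keep <- stat >= prevalence_min
  if (!any(keep))
    stop_hw("OTU filter removed every OTU; relax the threshold")
  removed <- data.frame(id = t$otus[!keep], reason = rep(mode, sum(!keep)),
                        value = unname(stat[!keep]), stringsAsFactors = FALSE)
  m <- t$rel_abund[, keep, drop = FALSE]
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop_hw("OTU filter left sample(s) with zero total abundance")
  out <- otu_table_rel(m / rs)
  attr(out, "removed") <- removed
  out
}

#' Log-transform OTU relative abundances
#'
#' Returns `R = log(rel_abund + pseudocount)`, optionally column
#' (OTU-wise) mean-centered. Centering is the default because the
#' microbial relationship matrix built from `R` plays a covariance-like
#' role; uncentered cross-products are dominated by the compositional
#' mean. A pseudocount is required because zero abundances are common and
#' `log(0)` is undefined; `"auto"` uses half the smallest nonzero relative
#' abundance in the table.
#'
#' @param t an [otu_table_rel()].
#' @param pseudocount positive number or `"auto"`.
#' @param center center each OTU column to mean zero (default `TRUE`).
#' @return n x p numeric matrix with the pseudocount used in
#'   `attr(, "pseudocount")`.
#' @export
log_transform_otus <- function(t, pseudocount = "auto", center = TRUE) {
  m <- t$rel_abund
  if (identical(pseudocount, "auto")) {
    nz <- m[m > 0]
    if (!length(nz)) stop_hw("OTU table is all zero; cannot pick pseudocount")
    pseudocount <- min(nz) / 2
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop_hw("pseudocount must be a single positive number or \"auto\"")
  r <- log(m + pseudocount)
  if (center) r <- scale(r, center = TRUE, scale = FALSE)
  r <- r[, , drop = FALSE]
  attr(r, "scaled:center") <- NULL
  attr(r, "pseudocount") <- pseudocount
  attr(r, "centered") <- isTRUE(center)
  r
}
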