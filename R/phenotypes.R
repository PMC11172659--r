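#' Read a phenotype/covariate TSV (first column = sample ID)
#'
#' All remaining columns are kept as-is; which are traits and which are
#' covariates is decided at model time via [model_spec()].
#'
#' @param path TSV file.
#' @return data.frame with a `sample_id` column, class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  check_no_duplicates(df$sample_id, "sample")
  empty <- vapply(df[-1], function(x) all(is.na(x)), logical(1))
  if (any(empty))
    warning("phenotype column(s) entirely missing: ",
            paste(names(df)[-1][empty], collapse = ", "))
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param p a phenotype table.
#' @export
write_phenotypes <- function(p, path) {
  write_tsv_atomic(as.data.frame(p), path)
}

#' Derived feed-performance traits
#'
#' Daily gain `DG = (final_wt - initial_wt) / days` (kg/day) and feed
#' conversion `FC = feed_intake / DG` (ratio of feed intake to daily gain).
#' Vectorized over animals.
#'
#' @param initial_wt,final_wt body weights (kg) at test start / end.
#' @param days days on test (> 0).
#' @param feed_intake total feed intake (kg).
#' @return data.frame with columns `DG` and `FC`.
#' @export
derive_performance_traits <- function(initial_wt, final_wt, days, feed_intake) {
  if (any(days <= 0)) stop_hw("`days` must be > 0")
  dg <- (final_wt - initial_wt) / days
  if (any(dg == 0, na.rm = TRUE))
    stop_hw("daily gain is zero for some animal(s); FC = FI/DG is undefined")
  data.frame(DG = dg, FC = feed_intake / dg)
}

#' Align genotype, OTU and phenotype data to a common sample set
#'
#' Restricts all three inputs to the intersection of their sample IDs, in
#' the genotype table's order. Dropped samples are reported via `message()`.
#'
#' @param g a [genotype_matrix()].
#' @param t an [otu_table_rel()].
#' @param p a phenotype table (data.frame with `sample_id`).
#' @return list with elements `genotypes`, `otus`, `phenotypes`, class
#'   `hologenome_data`.
#' @export
align_samples <- function(g, t, p) {
  common <- intersect(intersect(g$samples, t$samples), p$sample_id)
  if (!length(common)) {
    stop_hw(sprintf(
      "no samples shared across inputs (genotypes e.g. %s; otus e.g. %s; phenotypes e.g. %s)",
      paste(head(g$samples, 3), collapse = ","),
      paste(head(t$samples, 3), collapse = ","),
      paste(head(p$sample_id, 3), collapse = ",")))
  }
  ids <- g$samples[g$samples %in% common]
  dropped <- setdiff(unique(c(g$samples, t$samples, p$sample_id)), ids)
  if (length(dropped))
    message(length(dropped), " sample(s) not shared by all inputs were dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  p2 <- as.data.frame(p)[match(ids, p$sample_id), , drop = FALSE]
  rownames(p2) <- NULL
  structure(list(
    genotypes = subset_genotypes(g, samples = ids),
    otus = otu_table_rel(t$rel_abund[match(ids, t$samples), , drop = FALSE]),
    phenotypes = p2),
    class = "hologenome_data")
}
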