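#' Manhattan and QQ plots with data sidecars
#'
#' Writes a Manhattan plot (chromosome-alternating colors, dashed line at
#' the Bonferroni threshold) and a QQ plot of observed vs expected
#' -log10 p with the genomic-inflation factor printed in the corner. Each
#' plot also writes a TSV "sidecar" of its plotted coordinates so that
#' graphical claims can be tested without pixel comparison. Output is
#' deterministic given the input.
#'
#' @param results an `assoc_result`.
#' @param thresholds optional named list / numeric: `bc` (dashed line) and
#'   `gwst`; default draws the Bonferroni line at alpha = 0.05.
#' @param out_prefix path prefix; writes `<prefix>_manhattan.png`,
#'   `<prefix>_manhattan.sidecar.tsv`, `<prefix>_qq.png`,
#'   `<prefix>_qq.sidecar.tsv`.
#' @param width,height,dpi device settings.
#' @return invisible character vector of the files written.
#' @export
plot_manhattan_qq <- function(results, thresholds = NULL, out_prefix,
                              width = 9, height = 4, dpi = 120) {
  df <- as.data.frame(results)
  df <- df[!is.na(df$p), , drop = FALSE]
  if (!nrow(df)) stop_hw("no usable p-values to plot")
  bc <- if (!is.null(thresholds$bc)) thresholds$bc
        else bonferroni_threshold(0.05, nrow(df))$threshold

  ## cumulative genome coordinate
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  off <- 0; df$cumpos <- NA_real_
  for (ch in levels(df$chrom)) {
    i <- df$chrom == ch
    df$cumpos[i] <- df$pos[i] + off
    off <- off + max(df$pos[i]) + 1
  }
  df$neglog10p <- -log10(pmax(df$p, .Machine$double.xmin))
  df$color_band <- (as.integer(df$chrom) %% 2L) == 0L

  man_side <- df[, c("snp_id", "chrom", "pos", "cumpos", "neglog10p")]
  write_tsv_atomic(man_side, paste0(out_prefix, "_manhattan.sidecar.tsv"))

  lam <- attr(results, "lambda_gc")
  obs <- sort(df$neglog10p, decreasing = TRUE)
  q <- length(obs)
  expc <- -log10((seq_len(q) - 0.5) / q)
  qq_side <- data.frame(expected = expc, observed = obs)
  write_tsv_atomic(qq_side, paste0(out_prefix, "_qq.sidecar.tsv"))

  files <- paste0(out_prefix, c("_manhattan.png", "_qq.png"))
  centers <- tapply(df$cumpos, df$chrom, mean)
  p_man <- ggplot2::ggplot(df, ggplot2::aes(.data$cumpos, .data$neglog10p,
                                            color = .data$color_band)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c("grey25", "steelblue")) +
    ggplot2::geom_hline(yintercept = -log10(bc), linetype = "dashed",
                        color = "red") +
    ggplot2::scale_x_continuous(breaks = centers, labels = names(centers)) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p)),
                  title = sprintf("%s / %s", attr(results, "model"),
                                  attr(results, "trait"))) +
    ggplot2::theme_classic()
  if (!is.null(thresholds$gwst))
    p_man <- p_man + ggplot2::geom_hline(yintercept = -log10(thresholds$gwst),
                                         linetype = "dotted", color = "darkred")
  ggplot2::ggsave(files[1], p_man, width = width, height = height, dpi = dpi)

  p_qq <- ggplot2::ggplot(qq_side, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "red",
                         linetype = "dashed") +
    ggplot2::annotate("text", x = 0.12 * max(expc), y = 0.95 * max(obs, 1),
                      label = sprintf("lambda == %.3f",
                                      lam %||% NA_real_), parse = TRUE) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_classic()
  ggplot2::ggsave(files[2], p_qq, width = height, height = height, dpi = dpi)

  invisible(c(files, paste0(out_prefix,
                            c("_manhattan.sidecar.tsv", "_qq.sidecar.tsv"))))
}

#' @importFrom ggplot2 .data
NULL
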