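#' Load gene models from a GFF3 file
#'
#' Keeps `gene`-type features only (1-based inclusive coordinates, as in
#' GFF3). Parsing goes through `rtracklayer::import`.
#'
#' @param path GFF3 file.
#' @return data.frame of class `gene_models` with columns `gene_id`,
#'   `name`, `chrom`, `start`, `end`, `strand`, `biotype`.
#' @export
load_gff <- function(path) {
  if (!file.exists(path)) stop_hw("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_hw("GFF3 parse error in ", path,
                                             ": ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  is_gene <- !is.na(md$type) & md$type == "gene"
  if (!any(is_gene)) {
    warning("no gene-type features in ", path)
    return(empty_gene_models())
  }
  gr <- gr[is_gene]
  md <- S4Vectors::mcols(gr)
  get_col <- function(nm) if (nm %in% names(md)) as.character(md[[nm]])
                          else rep(NA_character_, length(gr))
  gene_id <- get_col("ID")
  gid2 <- get_col("gene_id")
  gene_id[is.na(gene_id)] <- gid2[is.na(gene_id)]
  if (anyNA(gene_id))
    gene_id[is.na(gene_id)] <- paste0("gene_", which(is.na(gene_id)))
  gene_id <- sub("^gene:", "", gene_id)
  biotype <- get_col("biotype")
  bt2 <- get_col("gene_biotype")
  biotype[is.na(biotype)] <- bt2[is.na(biotype)]
  out <- data.frame(
    gene_id = gene_id,
    name = get_col("Name"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop_hw("gene with end < start in ", path)
  class(out) <- c("gene_models", "data.frame")
  out
}

empty_gene_models <- function() {
  out <- data.frame(gene_id = character(0), name = character(0),
                    chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    biotype = character(0), stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Annotate SNPs with candidate genes in a window
#'
#' For each SNP (a point at `pos`), every gene intersecting the interval
#' `[pos - window, pos + window]` is reported (boundaries inclusive; a gap
#' of exactly `window` base pairs still counts), classified as:
#' * `within_gene` — the SNP lies inside `[start, end]` (distance 0);
#' * `within_window` — the gene lies entirely inside the window;
#' * `overlaps_window` — the gene partially overlaps the window.
#'
#' Distance is the base-pair gap between the SNP and the nearest gene
#' edge. Strand is ignored (upstream and downstream are symmetric).
#' SNPs on chromosomes absent from the gene set simply produce no hits.
#'
#' @param snps data.frame with columns `snp_id` (or `id`), `chrom`, `pos`;
#'   an `assoc_result` works directly.
#' @param genes a `gene_models` data.frame from [load_gff()].
#' @param window half-width in bp (default 100000).
#' @return data.frame of hits: `snp_id`, `gene_id`, `name`, `relation`,
#'   `distance`.
#' @export
annotate_snps <- function(snps, genes, window = 100000) {
  if (window < 0) stop_hw("window must be >= 0")
  snps <- as.data.frame(snps)
  if (!"snp_id" %in% names(snps) && "id" %in% names(snps))
    names(snps)[names(snps) == "id"] <- "snp_id"
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snps)))
    stop_hw("snps needs columns: ", paste(need, collapse = ", "))
  if (!nrow(snps) || !nrow(genes)) return(empty_hits())

  win <- GenomicRanges::GRanges(
    snps$chrom,
    IRanges::IRanges(pmax(1L, snps$pos - window), snps$pos + window))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(win, gg))
  if (!length(ov)) return(empty_hits())
  si <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  pos <- snps$pos[si]
  gs <- genes$start[gi]; ge <- genes$end[gi]
  inside <- pos >= gs & pos <= ge
  contained <- gs >= (pos - window) & ge <= (pos + window)
  relation <- ifelse(inside, "within_gene",
                     ifelse(contained, "within_window", "overlaps_window"))
  distance <- ifelse(inside, 0L,
                     ifelse(pos < gs, gs - pos, pos - ge))
  out <- data.frame(snp_id = snps$snp_id[si], gene_id = genes$gene_id[gi],
                    name = genes$name[gi], relation = relation,
                    distance = as.integer(distance),
                    stringsAsFactors = FALSE)
  ## deterministic output order regardless of gene-file order
  out[order(out$snp_id, out$distance, genes$start[gi], out$gene_id), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(snp_id = character(0), gene_id = character(0),
             name = character(0), relation = character(0),
             distance = integer(0), stringsAsFactors = FALSE)
}

#' Nearest gene to a single SNP
#'
#' Minimal-distance gene on the SNP's chromosome; ties broken by smaller
#' start coordinate, then lexicographic gene ID. Returns `NULL` when the
#' chromosome holds no genes.
#'
#' @param snp one-row data.frame (or list) with `snp_id`, `chrom`, `pos`.
#' @param genes a `gene_models` data.frame.
#' @return one-row hit data.frame (as [annotate_snps()]) or `NULL`.
#' @export
nearest_gene <- function(snp, genes) {
  snp <- as.list(as.data.frame(snp, stringsAsFactors = FALSE))
  if (is.null(snp$snp_id)) snp$snp_id <- snp$id
  g <- genes[genes$chrom == snp$chrom, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  pos <- as.integer(snp$pos)
  dist <- ifelse(pos >= g$start & pos <= g$end, 0L,
                 ifelse(pos < g$start, g$start - pos, pos - g$end))
  ord <- order(dist, g$start, g$gene_id)
  i <- ord[1]
  data.frame(snp_id = snp$snp_id, gene_id = g$gene_id[i], name = g$name[i],
             relation = if (dist[i] == 0L) "within_gene" else "within_window",
             distance = as.integer(dist[i]), stringsAsFactors = FALSE)
}
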