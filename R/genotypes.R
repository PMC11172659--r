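#' Genotype matrix container
#'
#' Holds additive allele dosages for n samples at q SNPs together with the
#' SNP map and alt-allele frequencies. Dosages count copies of the alt
#' allele (0, 1, 2); missing genotypes are stored as `NA` and are only
#' mean-imputed downstream, at standardization time.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   in {0, 1, 2} or `NA`.
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per SNP column.
#' @param samples character vector of sample IDs; defaults to
#'   `rownames(dosages)`.
#' @return an object of class `genotype_matrix` with elements `samples`,
#'   `snps`, `dosages` and `freqs` (per-SNP alt-allele frequency computed
#'   from non-missing dosages).
#' @export
genotype_matrix <- function(dosages, map, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(samples)) stop_hw("sample IDs are required (rownames or `samples`)")
  samples <- as.character(samples)
  if (length(samples) != nrow(dosages))
    stop_hw("length(samples) != nrow(dosages)")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop_hw("SNP map lacks column(s): ", paste(miss, collapse = ", "))
  map <- map[need]
  map$id <- as.character(map$id); map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(dosages)) stop_hw("nrow(map) != ncol(dosages)")
  check_no_duplicates(samples, "sample")
  check_no_duplicates(map$id, "SNP")
  if (any(map$pos < 1L, na.rm = TRUE)) stop_hw("SNP positions must be >= 1")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop_hw("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(samples, map$id)
  structure(
    list(samples = samples, snps = map, dosages = dosages,
         freqs = alt_freqs(dosages)),
    class = "genotype_matrix")
}

## alt-allele frequency from non-missing dosages only
alt_freqs <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs; %.2f%% missing\n",
              length(x$samples), nrow(x$snps),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  d <- g$dosages
  map <- g$snps
  if (!is.null(snps)) {
    keep <- if (is.character(snps)) match(snps, map$id) else snps
    d <- d[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  if (!is.null(samples)) {
    keep <- if (is.character(samples)) match(samples, g$samples) else samples
    d <- d[keep, , drop = FALSE]
  }
  genotype_matrix(d, map, samples = rownames(d))
}

#' Read genotypes from PLINK1, VCF or dosage TSV
#'
#' Dispatches on the input: a PLINK1 fileset prefix (`.bed`/`.bim`/`.fam`),
#' a VCF(.gz) path, or a TSV of dosages (header row of SNP IDs, first
#' column sample IDs). Dosages follow the alt-allele counting convention;
#' for PLINK filesets the bim A1 allele is taken as alt, matching
#' `plink --recode A`.
#'
#' @param path file path or PLINK prefix.
#' @param format one of `"auto"`, `"plink"`, `"vcf"`, `"tsv"`.
#' @param map optional SNP map (data.frame or TSV path with columns
#'   id/chrom/pos/ref/alt) for the dosage-TSV input, which carries no
#'   coordinates of its own.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "plink", "vcf", "tsv"),
                           map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(path, ".bed"))) "plink"
      else if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
      else if (grepl("\\.(tsv|txt)$", path)) "tsv"
      else stop_hw("cannot infer genotype format for: ", path)
  }
  switch(format,
         plink = read_plink(path),
         vcf = read_vcf_genotypes(path),
         tsv = read_dosage_tsv(path, map = map))
}

## ---- PLINK1 bed/bim/fam -----------------------------------------------
## SNP-major .bed: 3 magic bytes 0x6c 0x1b 0x01 then ceil(n/4) bytes per
## SNP, 2 bits per genotype: 00 = hom A1, 01 = missing, 10 = het,
## 11 = hom A2. We count A1 (alt) copies. No installed package reads this
## format, so the decoder lives here.
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop_hw("missing PLINK file: ", p)

  fam <- data.table::fread(paths[3], header = FALSE, data.table = FALSE)
  if (ncol(fam) < 2) stop_hw("malformed .fam (need >= 2 columns): ", paths[3])
  samples <- as.character(fam[[2]])

  bim <- data.table::fread(paths[2], header = FALSE, data.table = FALSE)
  if (ncol(bim) < 6) stop_hw("malformed .bim (need 6 columns): ", paths[2])
  map <- data.frame(id = as.character(bim[[2]]), chrom = as.character(bim[[1]]),
                    pos = as.integer(bim[[4]]), ref = as.character(bim[[6]]),
                    alt = as.character(bim[[5]]), stringsAsFactors = FALSE)

  n <- length(samples); q <- nrow(map)
  bpv <- ceiling(n / 4)                      # bytes per variant
  raw <- readBin(paths[1], what = "raw", n = 3 + bpv * q)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_hw("not a PLINK1 .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop_hw("only SNP-major .bed supported: ", paths[1])
  body <- raw[-(1:3)]
  if (length(body) != bpv * q)
    stop_hw(sprintf(".bed size mismatch: expected %d data bytes, found %d",
                    bpv * q, length(body)))

  idx <- rep(as.integer(body), each = 4L) * 4L + rep_len(1:4, 4L * length(body))
  dos <- matrix(plink_decode_table()[idx], nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  genotype_matrix(dos, map, samples = samples)
}

## 256 x 4 lookup: byte value -> 4 decoded dosages (A1 copies), low bits first
plink_decode_table <- local({
  vec <- NULL
  function() {
    if (is.null(vec)) {
      code <- c(2, NA, 1, 0)  # 2-bit codes 00/01/10/11 -> A1 copies
      m <- vapply(0:255, function(b) {
        code[1L + c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
                    bitwAnd(bitwShiftR(b, 4L), 3L),
                    bitwAnd(bitwShiftR(b, 6L), 3L))]
      }, numeric(4))
      ## flattened so that vec[byte*4 + k] decodes genotype k of `byte`
      vec <<- as.numeric(m)
    }
    vec
  }
})

#' Write a genotype matrix as a PLINK1 fileset
#'
#' @param g a [genotype_matrix()].
#' @param prefix output prefix; writes `prefix.bed`, `.bim`, `.fam`.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- length(g$samples); q <- nrow(g$snps)
  fam <- data.frame(g$samples, g$samples, 0L, 0L, 0L, -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  bim <- data.frame(g$snps$chrom, g$snps$id, 0L, g$snps$pos, g$snps$alt, g$snps$ref)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)

  code <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # dosage -> 2-bit code; NA -> 1
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bpv - n
  for (j in seq_len(q)) {
    d <- g$dosages[, j]
    cc <- ifelse(is.na(d), 1L, code[as.character(d)])
    cc <- c(cc, rep(0L, pad))
    byte <- cc[c(TRUE, FALSE, FALSE, FALSE)] +
      bitwShiftL(cc[c(FALSE, TRUE, FALSE, FALSE)], 2L) +
      bitwShiftL(cc[c(FALSE, FALSE, TRUE, FALSE)], 4L) +
      bitwShiftL(cc[c(FALSE, FALSE, FALSE, TRUE)], 6L)
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

## ---- VCF ---------------------------------------------------------------
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_hw("VCF has no GT field: ", path)
  ## count alt alleles; any missing allele -> NA
  count_alt <- function(s) {
    s[s %in% c(".", "./.", ".|.")] <- NA
    a <- strsplit(gsub("\\|", "/", s), "/", fixed = TRUE)
    vapply(a, function(x) {
      if (anyNA(x) || any(x == ".")) return(NA_real_)
      sum(x != "0")
    }, numeric(1))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  map <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(dos), map, samples = colnames(gt))
}

## ---- dosage TSV --------------------------------------------------------
read_dosage_tsv <- function(path, map = NULL) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  samples <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- samples
  if (is.character(map) && length(map) == 1L)
    map <- data.table::fread(map, sep = "\t", header = TRUE, data.table = FALSE)
  if (is.null(map))
    map <- data.frame(id = colnames(dos), chrom = "un",
                      pos = seq_len(ncol(dos)), ref = "A", alt = "B",
                      stringsAsFactors = FALSE)
  else
    map <- map[match(colnames(dos), map$id), , drop = FALSE]
  genotype_matrix(dos, map, samples = samples)
}

#' Write dosages as TSV (header = SNP IDs, first column = sample ID)
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(sample_id = g$samples, g$dosages, check.names = FALSE)
  write_tsv_atomic(df, path)
}

#' Quality-control filter for SNPs
#'
#' Retains SNPs with minor allele frequency and call rate at or above the
#' thresholds (comparisons inclusive on the keep side). The removal report
#' names each dropped SNP and the reason(s).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param cr_min minimum call rate (default 0.95).
#' @return the filtered `genotype_matrix`, with the removal report as a
#'   data.frame in `attr(, "removed")`.
#' @export
qc_filter_genotypes <- function(g, maf_min = 0.05, cr_min = 0.95) {
  check_fraction(maf_min, "maf_min"); check_fraction(cr_min, "cr_min")
  maf <- pmin(g$freqs, 1 - g$freqs)
  maf[is.nan(maf)] <- 0  # all-missing column
  cr <- colMeans(!is.na(g$dosages))
  fail_maf <- maf < maf_min
  fail_cr <- cr < cr_min
  drop <- fail_maf | fail_cr
  reason <- character(sum(drop))
  reason[] <- ""
  reason[fail_maf[drop]] <- "MAF"
  both <- fail_maf[drop] & fail_cr[drop]
  reason[fail_cr[drop] & !fail_maf[drop]] <- "call_rate"
  reason[both] <- "MAF;call_rate"
  removed <- data.frame(id = g$snps$id[drop], reason = reason,
                        maf = maf[drop], call_rate = cr[drop],
                        stringsAsFactors = FALSE)
  if (all(drop))
    stop_hw("QC removed every SNP; relax maf_min/cr_min")
  out <- subset_genotypes(g, snps = which(!drop))
  attr(out, "removed") <- removed
  out
}
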