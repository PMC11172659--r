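test_that("PLINK bed/bim/fam fixture with known genotypes reads back correctly", {
  prefix <- tempfile()
  ## hand-written fileset: 3 samples, 2 SNPs
  writeLines(c("f1\ts1\t0\t0\t0\t-9", "f2\ts2\t0\t0\t0\t-9",
               "f3\ts3\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  writeLines(c("1\tsnpA\t0\t100\tG\tA", "2\tsnpB\t0\t200\tT\tC"),
             paste0(prefix, ".bim"))
  ## SNP-major 2-bit codes, low bits first: snpA = (0,1,2) alt copies ->
  ## codes (11,10,00) -> byte 00 00 10 11 = 0x0b; snpB = (2,NA,0) ->
  ## codes (00,01,11) -> byte 00 11 01 00 = 0x34
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x0b, 0x34)), con)
  close(con)

  g <- read_genotypes(prefix)
  expect_equal(g$samples, c("s1", "s2", "s3"))
  expect_equal(unname(g$dosages[, "snpA"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "snpB"]), c(2, NA, 0))
  expect_equal(g$snps$alt, c("G", "T"))
  ## freqs from non-missing only
  expect_equal(unname(g$freqs), c(0.5, 0.5))
})

test_that("PLINK writer round-trips through the reader, missing preserved", {
  g <- toy_genotypes()
  g$dosages[2, 2] <- NA
  g <- genotype_matrix(g$dosages, g$snps)
  prefix <- tempfile()
  write_plink(g, prefix)
  g2 <- read_genotypes(prefix, format = "plink")
  expect_identical(g2$dosages, g$dosages)
  expect_equal(g2$snps$pos, g$snps$pos)
})

test_that("VCF input: './.' becomes missing; dosages count alt alleles", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1|1"), vcf)
  g <- read_genotypes(vcf)
  expect_equal(unname(g$dosages[, "rs1"]), c(0, 1, 2))
  expect_true(is.na(g$dosages["s1", "rs2"]))
  expect_equal(unname(g$dosages[c("s2", "s3"), "rs2"]), c(1, 2))
})

test_that("duplicate SNP IDs are rejected", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  map <- data.frame(id = c("dup", "dup"), chrom = "1", pos = c(1L, 2L),
                    ref = "A", alt = "B")
  expect_error(genotype_matrix(d, map), "duplicate SNP")
})

test_that("dosage TSV round-trip is exact", {
  g <- toy_genotypes()
  path <- tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  g2 <- read_genotypes(path, format = "tsv", map = g$snps)
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$snps, g$snps)
})

test_that("phenotype TSV round-trip is exact and flags empty columns", {
  p <- data.frame(sample_id = c("s1", "s2"), y = c(1.25, -0.5),
                  age = c(3L, 4L))
  path <- tempfile(fileext = ".tsv")
  write_phenotypes(p, path)
  p2 <- read_phenotypes(path)
  expect_equal(p2$y, p$y)
  expect_equal(p2$age, p$age)

  p$bad <- NA_real_
  write_phenotypes(p, path)
  expect_warning(read_phenotypes(path), "entirely missing")
})

test_that("genotype QC drops by MAF and call rate with inclusive boundaries", {
  ## 50 samples; snp1 freq 0.04 (MAF fail), snp2 call rate 96% (pass at
  ## 0.95), snp3 monomorphic, snp4 clean
  n <- 50
  d <- cbind(snp1 = c(rep(1, 4), rep(0, 46)),
             snp2 = c(rep(NA, 2), rep(1, 48)),
             snp3 = rep(0, n),
             snp4 = rep(c(0, 1, 2), length.out = n))
  rownames(d) <- paste0("s", 1:n)
  map <- data.frame(id = colnames(d), chrom = "1", pos = 1:4,
                    ref = "A", alt = "B")
  g <- genotype_matrix(d, map)
  out <- qc_filter_genotypes(g, maf_min = 0.05, cr_min = 0.95)
  removed <- attr(out, "removed")
  expect_setequal(out$snps$id, c("snp2", "snp4"))
  expect_equal(removed$reason[removed$id == "snp1"], "MAF")
  expect_equal(removed$reason[removed$id == "snp3"], "MAF")

  ## idempotent
  out2 <- qc_filter_genotypes(out, maf_min = 0.05, cr_min = 0.95)
  expect_identical(out2$dosages, out$dosages)

  ## removing everything is an error
  expect_error(qc_filter_genotypes(g, maf_min = 0.499, cr_min = 1),
               "relax")
})

test_that("OTU prevalence filter is boundary-inclusive and renormalizes", {
  n <- 100
  m <- matrix(0.5, n, 2)                 # two always-present OTUs
  o19 <- c(rep(0.2, 19), rep(0, n - 19)) # present in 19% -> removed
  o20 <- c(rep(0, n - 20), rep(0.2, 20)) # present in 20% -> retained
  m <- cbind(m, o19, o20)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", 1:n), c("oA", "oB", "o19", "o20"))
  t <- otu_table_rel(m)
  out <- qc_filter_otus(t, prevalence_min = 0.20)
  expect_setequal(out$otus, c("oA", "oB", "o20"))
  expect_equal(attr(out, "removed")$id, "o19")
  expect_equal(rowSums(out$rel_abund), rep(1, n), ignore_attr = TRUE)

  ## abundance mode filters on mean relative abundance
  out2 <- qc_filter_otus(t, prevalence_min = 0.1, mode = "abundance")
  expect_false("o19" %in% out2$otus)
})

test_that("log transform: centering, explicit pseudocount and auto rule", {
  ## uniform composition + centering -> zero matrix
  r0 <- log_transform_otus(uniform_otus(), center = TRUE)
  expect_equal(max(abs(r0)), 0)

  m <- matrix(c(0.6, 0.2, 0.4, 0.8), 2, 2,
              dimnames = list(c("a", "b"), c("o1", "o2")))
  t <- otu_table_rel(m)
  r <- log_transform_otus(t, pseudocount = 1e-6, center = FALSE)
  expect_equal(unname(r), log(unname(m) + 1e-6), ignore_attr = TRUE)

  ## auto pseudocount = half the smallest nonzero entry
  m2 <- matrix(c(0.99, 0.5, 0.01, 0.5), 2, 2,
               dimnames = list(c("a", "b"), c("o1", "o2")))
  r2 <- log_transform_otus(otu_table_rel(m2), pseudocount = "auto")
  expect_equal(attr(r2, "pseudocount"), 0.005)

  expect_error(log_transform_otus(t, pseudocount = -1), "positive")
  ## centered columns have mean zero
  r3 <- log_transform_otus(t, center = TRUE)
  expect_lt(max(abs(colMeans(r3))), 1e-12)
})

test_that("derived performance traits follow DG and FC definitions", {
  out <- derive_performance_traits(30, 100, 70, 175)
  expect_equal(out$DG, 1.0)
  expect_equal(out$FC, 175)
  expect_equal(derive_performance_traits(30, 100, 70, 140)$FC, 140)
  expect_error(derive_performance_traits(30, 30, 70, 140), "undefined")
  expect_error(derive_performance_traits(30, 100, 0, 140), "days")
})

test_that("sample alignment restricts and reorders consistently", {
  g <- toy_genotypes()
  m <- matrix(1 / 3, 3, 3,
              dimnames = list(c("s3", "s1", "s2"), paste0("o", 1:3)))
  t <- otu_table_rel(m)
  p <- data.frame(sample_id = c("s2", "s3", "s1", "s9"), y = c(2, 3, 1, 9))
  out <- suppressMessages(align_samples(g, t, p))
  expect_equal(out$genotypes$samples, c("s1", "s2", "s3"))
  expect_equal(out$otus$samples, c("s1", "s2", "s3"))
  expect_equal(out$phenotypes$y, c(1, 2, 3))
  expect_message(align_samples(g, t, p), "dropped")

  p2 <- data.frame(sample_id = c("x1", "x2"), y = 1:2)
  expect_error(align_samples(g, t, p2), "no samples shared")
})
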