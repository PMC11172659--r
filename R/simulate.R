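#' Simulation configuration for synthetic hologenome data
#'
#' Defines the study conditions for the generator: cohort size, marker and
#' OTU panel sizes, the variance architecture of the trait, and how much
#' of the microbiome is genotype-driven (which induces covariance between
#' the genomic and microbial kernels).
#'
#' The default variance fractions — additive genetic 0.3, microbial 0.2,
#' hologenome interaction 0.1, residual 0.4 — reflect a moderately
#' heritable production trait with a substantial microbiability, the
#' regime the hologenome models are designed for.
#'
#' @param n samples; `q` SNPs; `p` OTUs.
#' @param maf_range range for per-SNP minor allele frequencies,
#'   within (0, 0.5].
#' @param var_fractions named numeric `(g, m, holo, e)` summing to 1.
#' @param rho_gm optional genome-microbiome covariance coefficient placed
#'   on the Cholesky cross-covariance kernel when simulating under the
#'   HWAS-CG architecture (clamped if it breaks positive definiteness).
#' @param n_causal number of causal SNPs with fixed effects.
#' @param causal_effect per-SNP fixed effect size (standardized dosage
#'   scale); recycled to `n_causal`.
#' @param otu_heritable_frac share of OTU log-abundance variance driven by
#'   genotype, in \[0, 1\].
#' @param seed master RNG seed; every downstream draw derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n = 300L, q = 2000L, p = 200L,
                       maf_range = c(0.05, 0.5),
                       var_fractions = c(g = 0.3, m = 0.2, holo = 0.1, e = 0.4),
                       rho_gm = 0, n_causal = 0L, causal_effect = 0.5,
                       otu_heritable_frac = 0.3, seed = 1L) {
  var_fractions <- unlist(var_fractions)  # accept YAML-style lists
  maf_range <- unlist(maf_range)
  if (length(var_fractions) != 4L)
    stop_hw("var_fractions must have 4 entries (g, m, holo, e)")
  names(var_fractions) <- c("g", "m", "holo", "e")
  if (any(var_fractions < 0)) stop_hw("variance fractions must be nonnegative")
  if (abs(sum(var_fractions) - 1) > 1e-9)
    stop_hw("variance fractions must sum to 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_hw("maf_range must lie within (0, 0.5]")
  check_fraction(otu_heritable_frac, "otu_heritable_frac")
  structure(list(n = as.integer(n), q = as.integer(q), p = as.integer(p),
                 maf_range = maf_range, var_fractions = var_fractions,
                 rho_gm = rho_gm, n_causal = as.integer(n_causal),
                 causal_effect = rep_len(causal_effect, max(1L, n_causal)),
                 otu_heritable_frac = otu_heritable_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, a MAF is drawn uniformly on `maf_range` and dosages are
#' Binomial(2, MAF), i.i.d. across samples. SNPs that come out
#' monomorphic in the finite sample are redrawn so the standardization
#' step is always defined. SNPs are spread over 10 chromosomes with
#' sorted positions.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with no missing values.
#' @export
sim_genotypes <- function(cfg) {
  with_seed(child_seed(cfg$seed, 1), {
    n <- cfg$n; q <- cfg$q
    maf <- runif(q, cfg$maf_range[1], cfg$maf_range[2])
    d <- matrix(rbinom(n * q, 2L, rep(maf, each = n)), n, q)
    for (r in 1:20) {
      mono <- which(colSums(d) %in% c(0L, 2L * n))
      if (!length(mono)) break
      d[, mono] <- rbinom(n * length(mono), 2L,
                          rep(maf[mono], each = n))
    }
    chrom <- rep(as.character(1:10), length.out = q)
    pos <- integer(q)
    for (ch in unique(chrom))
      pos[chrom == ch] <- sort(sample.int(1e8, sum(chrom == ch)))
    map <- data.frame(id = sprintf("snp%05d", seq_len(q)), chrom = chrom,
                      pos = pos, ref = "A", alt = "B",
                      stringsAsFactors = FALSE)
    ord <- order(as.integer(map$chrom), map$pos)
    genotype_matrix(d[, ord, drop = FALSE], map[ord, ],
                    samples = sprintf("ind%04d", seq_len(n)))
  })
}

#' Simulate a compositional OTU table, partly genotype-driven
#'
#' Latent log-abundances are
#' `L = sqrt(f) * scale(X_S B) + sqrt(1 - f) * E` with `f =
#' otu_heritable_frac`, `B` and `E` standard normal, and both terms scaled
#' to unit column variance; a per-row softmax converts `L` to relative
#' abundances summing to one (logistic-normal composition). With `f > 0`
#' the genomic and microbial kernels share structure, emulating a
#' heritable microbiome.
#'
#' @param cfg a [sim_config()].
#' @param genotypes the matching [sim_genotypes()] output.
#' @return an [otu_table_rel()].
#' @export
sim_microbiome <- function(cfg, genotypes) {
  with_seed(child_seed(cfg$seed, 2), {
    n <- cfg$n; p <- cfg$p; f <- cfg$otu_heritable_frac
    E <- matrix(rnorm(n * p), n, p)
    L <- if (f > 0) {
      xs <- standardize_genotypes(genotypes)
      B <- matrix(rnorm(cfg$q * p), cfg$q, p)
      H <- xs %*% B
      H <- scale(H)             # unit column variance
      sqrt(f) * H + sqrt(1 - f) * scale(E)
    } else E
    rel <- exp(L)
    rel <- rel / rowSums(rel)
    rownames(rel) <- genotypes$samples
    colnames(rel) <- sprintf("otu%04d", seq_len(p))
    otu_table_rel(rel)
  })
}

## rescale a kernel to mean diagonal 1 so variance fractions are shares
scale_kernel_diag <- function(k) {
  v <- as_kernel_values(k)
  v / mean(diag(v))
}

#' Simulate phenotypes with a given variance architecture
#'
#' `y = X beta + Z_causal gamma + u`, `u ~ N(0, V_true)` with
#' `V_true = f_g G + f_m M + f_holo H + rho_gm h_c + f_e I`. Kernels are
#' rescaled to mean diagonal one inside the generator so the fractions are
#' interpretable as variance shares; `u` is drawn through the Cholesky
#' factor of `V_true` with seeded normals. If `rho_gm` makes `V_true`
#' indefinite it is halved until positive definite (logged via message).
#'
#' @param cfg a [sim_config()].
#' @param kernels named list; recognized names `G`, `M`, `H` (Hadamard
#'   kernel, weight `holo`) and `hc` (cross-covariance kernel, weight
#'   `rho_gm`). Any may be omitted; its fraction is then folded into the
#'   residual.
#' @param genotypes optional [genotype_matrix()]; required when
#'   `cfg$n_causal > 0` (causal SNPs are drawn from it).
#' @param X optional fixed-effect design (defaults to intercept only,
#'   beta = 0).
#' @return a `phenotype_table` data.frame with columns `sample_id`, `y`;
#'   causal SNP ids/effects in `attr(, "causal")`.
#' @export
sim_phenotype <- function(cfg, kernels = list(), genotypes = NULL, X = NULL) {
  with_seed(child_seed(cfg$seed, 3), {
    n <- cfg$n
    fr <- cfg$var_fractions
    used <- 0
    V <- matrix(0, n, n)
    add <- function(V, nm, w) {
      if (!is.null(kernels[[nm]]) && w != 0) {
        V <- V + w * scale_kernel_diag(kernels[[nm]])
        used <<- used + w
      }
      V
    }
    V <- add(V, "G", fr["g"])
    V <- add(V, "M", fr["m"])
    V <- add(V, "H", fr["holo"])
    rho <- cfg$rho_gm
    if (!is.null(kernels$hc) && rho != 0) {
      hc <- as_kernel_values(kernels$hc)
      hc <- hc / mean(abs(diag(hc)))
      Vb <- V + diag(1 - used, n)
      for (tries in 1:30) {
        ev <- min(eigen(Vb + rho * hc, symmetric = TRUE,
                        only.values = TRUE)$values)
        if (ev > 1e-8) break
        rho <- rho / 2
      }
      if (rho != cfg$rho_gm)
        message("rho_gm clamped from ", cfg$rho_gm, " to ", rho,
                " to keep V positive definite")
      V <- V + rho * hc
    }
    V <- V + diag(max(1 - used, 0), n)  # residual absorbs unused fractions
    ch <- tryCatch(chol(V), error = function(e)
      stop_hw("simulated covariance matrix is not positive definite"))
    u <- as.numeric(crossprod(ch, rnorm(n)))
    y <- u
    if (!is.null(X)) y <- y + as.matrix(X) %*% rep(0, ncol(X))
    causal <- NULL
    if (cfg$n_causal > 0) {
      if (is.null(genotypes))
        stop_hw("genotypes required to place causal SNPs")
      j <- sort(sample.int(ncol(genotypes$dosages), cfg$n_causal))
      xs <- standardize_genotypes(subset_genotypes(genotypes, snps = j))
      eff <- cfg$causal_effect[seq_len(cfg$n_causal)]
      y <- y + as.numeric(xs %*% eff)
      causal <- data.frame(snp_id = genotypes$snps$id[j], effect = eff,
                           stringsAsFactors = FALSE)
    }
    samples <- if (!is.null(genotypes)) genotypes$samples
               else sprintf("ind%04d", seq_len(n))
    ph <- data.frame(sample_id = samples, y = as.numeric(y),
                     stringsAsFactors = FALSE)
    class(ph) <- c("phenotype_table", "data.frame")
    attr(ph, "causal") <- causal
    ph
  })
}

#' Simulate a complete hologenome dataset
#'
#' Convenience wrapper: genotypes, microbiome, all four kernels, and a
#' phenotype drawn under the requested architecture.
#'
#' @param cfg a [sim_config()].
#' @param architecture which kernels receive variance: `"HWAS-H"`
#'   (default; G, M and the Hadamard kernel), `"HWAS-CG"` (G, M and the
#'   cross-covariance kernel via `rho_gm`), `"GWAS"` (G only; microbial and
#'   hologenome fractions fold into the residual), `"M-GWAS"` (M only).
#' @return list with `genotypes`, `otus`, `phenotypes`, `kernels`
#'   (named list G, M, hc, hh) and `causal`.
#' @export
sim_dataset <- function(cfg, architecture = c("HWAS-H", "HWAS-CG",
                                              "GWAS", "M-GWAS")) {
  architecture <- match.arg(architecture)
  g <- sim_genotypes(cfg)
  t <- sim_microbiome(cfg, g)
  xs <- standardize_genotypes(g)
  G <- compute_grm(xs)
  r <- log_transform_otus(t)
  M <- compute_mrm(r)
  hc <- compute_hrm_cg(G, M)
  hh <- compute_hrm_h(G, M)
  sim_k <- switch(architecture,
                  "HWAS-H" = list(G = G, M = M, H = hh),
                  "HWAS-CG" = list(G = G, M = M, hc = hc),
                  "GWAS" = list(G = G),
                  "M-GWAS" = list(M = M))
  ph <- sim_phenotype(cfg, sim_k, genotypes = g)
  list(genotypes = g, otus = t, phenotypes = ph,
       kernels = list(G = G, M = M, hc = hc, hh = hh),
       causal = attr(ph, "causal"))
}

#' Type-I error / power / recovery experiments
#'
#' Runs `replicates` independent datasets per scenario, fits the requested
#' models, scans all SNPs, and aggregates empirical type-I error (null
#' SNPs), power (causal SNPs), variance-component estimates and genomic
#' inflation. Fully deterministic given the config seeds.
#'
#' @param cfgs a single [sim_config()] or list of them (scenarios).
#' @param models character subset of
#'   `c("GWAS", "M-GWAS", "HWAS-CG", "HWAS-H")`.
#' @param replicates number of replicate datasets per scenario (>= 1).
#' @param alpha_levels nominal levels for the type-I error / power rates.
#' @param architecture generating architecture passed to [sim_dataset()].
#' @return object of class `experiment_result`: list with `summary`
#'   (one row per scenario x model), `rates` (per alpha level) and
#'   `replicates`.
#' @export
run_experiment <- function(cfgs, models = "GWAS", replicates = 10L,
                           alpha_levels = c(0.05, 0.01),
                           architecture = "HWAS-H") {
  if (replicates < 1L) stop_hw("need at least 1 replicate")
  if (inherits(cfgs, "sim_config")) cfgs <- list(cfgs)
  rows <- list(); rate_rows <- list()
  for (sc in seq_along(cfgs)) {
    cfg0 <- cfgs[[sc]]
    for (m in models) {
      lam <- numeric(replicates)
      vc_list <- vector("list", replicates)
      null_p <- list(); causal_p <- list()
      for (rep_i in seq_len(replicates)) {
        cfg <- cfg0
        cfg$seed <- as.integer(child_seed(cfg0$seed, 1000 + rep_i))
        ds <- sim_dataset(cfg, architecture = architecture)
        kn <- switch(m,
                     "GWAS" = list(GRM = ds$kernels$G),
                     "M-GWAS" = list(MRM = ds$kernels$M),
                     "HWAS-CG" = list(GRM = ds$kernels$G, MRM = ds$kernels$M,
                                      HRM_CG = ds$kernels$hc),
                     "HWAS-H" = list(GRM = ds$kernels$G, MRM = ds$kernels$M,
                                     HRM_H = ds$kernels$hh),
                     stop_hw("unknown model: ", m))
        spec <- model_spec(m, kn, trait = "y")
        res <- run_model(spec, list(genotypes = ds$genotypes,
                                    phenotypes = ds$phenotypes))
        lam[rep_i] <- attr(res, "lambda_gc")
        vc_list[[rep_i]] <- attr(res, "vc")$components
        is_causal <- res$snp_id %in% ds$causal$snp_id
        null_p[[rep_i]] <- res$p[!is_causal & !is.na(res$p)]
        causal_p[[rep_i]] <- res$p[is_causal & !is.na(res$p)]
      }
      vc_mat <- do.call(rbind, vc_list)
      rows[[paste(sc, m)]] <- data.frame(
        scenario = sc, model = m, replicates = replicates,
        lambda_mean = mean(lam), lambda_sd = sd(lam),
        stringsAsFactors = FALSE)
      rows[[paste(sc, m)]]$vc_mean <- I(list(colMeans(vc_mat)))
      rows[[paste(sc, m)]]$vc_sd <- I(list(apply(vc_mat, 2, sd)))
      np <- unlist(null_p); cp <- unlist(causal_p)
      for (a in alpha_levels) {
        rate_rows[[paste(sc, m, a)]] <- data.frame(
          scenario = sc, model = m, alpha = a,
          type1 = if (length(np)) mean(np <= a) else NA_real_,
          n_null = length(np),
          power = if (length(cp)) mean(cp <= a) else NA_real_,
          n_causal = length(cp), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 rates = do.call(rbind, c(rate_rows, make.row.names = FALSE)),
                 replicates = replicates),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
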