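# Generator for unrelated-individual biallelic SNP panels with a known
# SNP heritability, realising the additive model that GREML assumes.

#' Specification for a simulated SNP panel
#'
#' @param n_individuals,n_snps Panel dimensions.
#' @param maf_range Minor-allele-frequency interval, a subset of (0, 0.5].
#' @param h2_snp Generative SNP heritability in `[0,1]`.
#' @param n_causal Number of causal variants (`<= n_snps`); must be 0 when
#'   `h2_snp` is 0 only if you want a literally effect-free panel — any
#'   `n_causal` works since effects are scaled to the target variance.
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `snp_sim_spec`.
#' @export
snp_sim_spec <- function(n_individuals, n_snps, maf_range = c(0.05, 0.5),
                         h2_snp = 0, n_causal = n_snps, seed = NULL) {
  if (n_individuals < 1) stop_field("n_individuals", "must be >= 1")
  if (n_snps < 1) stop_field("n_snps", "must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_field("maf_range", "must satisfy 0 < low <= high <= 0.5")
  }
  if (h2_snp < 0 || h2_snp > 1) stop_field("h2_snp", "must lie in [0,1]")
  if (n_causal > n_snps || n_causal < 0) {
    stop_field("n_causal", "must lie in [0, n_snps]")
  }
  if (h2_snp > 0 && n_causal == 0) {
    stop_field("n_causal", "must be positive when h2_snp > 0")
  }
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = maf_range, h2_snp = h2_snp,
                 n_causal = n_causal, seed = seed),
            class = "snp_sim_spec")
}

#' Construct a genotype matrix object
#'
#' @param dosages N x M integer matrix of minor-allele counts (0/1/2, `NA`
#'   for missing).
#' @param ids Individual identifiers (default `I00001`, ...).
#' @param snp_ids Marker identifiers (default `snp1`, ...).
#' @return Object of class `genotype_matrix` with sample allele
#'   frequencies attached.
#' @export
genotype_matrix <- function(dosages,
                            ids = sprintf("I%05d", seq_len(nrow(dosages))),
                            snp_ids = paste0("snp", seq_len(ncol(dosages)))) {
  stopifnot(is.matrix(dosages), length(ids) == nrow(dosages),
            length(snp_ids) == ncol(dosages))
  if (any(!(dosages %in% c(0, 1, 2, NA)))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  structure(list(dosages = dosages, ids = ids, snp_ids = snp_ids,
                 freq = colMeans(dosages, na.rm = TRUE) / 2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Simulate a SNP panel and an additively heritable phenotype
#'
#' Genotypes are independent binomial(2, p) draws with allele frequencies
#' uniform on `maf_range` (no linkage disequilibrium). Effects beta are
#' standard-normal at `n_causal` randomly chosen SNPs and act on
#' sample-standardised dosages; the genetic value is rescaled so that its
#' sample variance is exactly `h2_snp` and residual noise brings the
#' total phenotypic variance to 1.
#'
#' @param spec A [snp_sim_spec()].
#' @return List with `genotypes` (a [genotype_matrix()]), `phenotype`
#'   (length-N numeric), `genetic_value`, `effects` (length-M, zero at
#'   non-causal SNPs) and `causal` (indices).
#' @export
simulate_snp_panel <- function(spec) {
  stopifnot(inherits(spec, "snp_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_individuals; m <- spec$n_snps
    p <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    x <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
    geno <- genotype_matrix(x)
    beta <- numeric(m)
    causal <- sort(sample.int(m, spec$n_causal))
    g <- numeric(n)
    if (spec$n_causal > 0) {
      beta[causal] <- stats::rnorm(spec$n_causal)
      xc <- x[, causal, drop = FALSE]
      sds <- apply(xc, 2, stats::sd)
      ok <- sds > 0
      if (any(ok)) {
        zc <- scale(xc[, ok, drop = FALSE])
        g <- drop(zc %*% beta[causal][ok])
      }
    }
    sg <- stats::sd(g)
    scale_g <- if (sg > 0) sqrt(spec$h2_snp) / sg else 0
    g <- g * scale_g
    beta <- beta * scale_g
    noise <- stats::rnorm(n) * sqrt(1 - spec$h2_snp)
    list(genotypes = geno, phenotype = g + noise, genetic_value = g,
         effects = beta, causal = causal)
  })
}
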