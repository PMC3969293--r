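# Phenotype preparation: normalising transforms, standardisation with
# age/sex residualisation, +/- 3 SD outlier screening, and descriptive
# tables with a two-way sex-by-zygosity ANOVA.

#' Normalising transforms for the two task phenotypes
#'
#' Accuracy scores are squared (they are negatively skewed) and Weber
#' fractions are square-root transformed (they are positively skewed).
#'
#' @param accuracy Accuracy score(s).
#' @param weber Weber fraction(s), non-negative.
#' @return List with `accuracy` (squared) and `weber` (square root).
#' @examples
#' transform_scores(116, 0.25)
#' @export
transform_scores <- function(accuracy, weber) {
  if (any(weber < 0, na.rm = TRUE)) stop("`weber` must be non-negative")
  list(accuracy = accuracy^2, weber = sqrt(weber))
}

#' Standardise a phenotype and residualise for age and sex
#'
#' Z-scores the input, regresses the z-scores on age (linear, in years)
#' and sex (binary) by ordinary least squares with intercept, and
#' re-standardises the residuals to mean 0 and SD 1. Twin pairs share
#' their age exactly and half of the pairs share sex, so uncorrected age
#' and sex effects would inflate twin correlations and masquerade as
#' shared environment. Missing values propagate.
#'
#' @param values Numeric vector.
#' @param age Numeric vector of ages.
#' @param sex Character/factor vector (two levels).
#' @return Numeric vector of standardised residuals.
#' @export
standardize_and_residualize <- function(values, age, sex) {
  stopifnot(length(values) == length(age), length(values) == length(sex))
  if (sum(!is.na(values)) < 3) stop("need at least 3 non-missing values")
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("constant input: zero variance")
  z <- (values - mean(values, na.rm = TRUE)) / s
  sexf <- factor(sex)
  fit <- stats::lm(z ~ age + sexf, na.action = stats::na.exclude)
  r <- stats::residuals(fit)
  sr <- stats::sd(r, na.rm = TRUE)
  if (!is.finite(sr) || sr < 1e-10) {
    # perfect fit: residuals are all (numerically) zero
    return(ifelse(is.na(z), NA_real_, 0))
  }
  as.numeric((r - mean(r, na.rm = TRUE)) / sr)
}

#' Outlier mask for standardised scores
#'
#' Single-pass screen: an observation is kept iff `|value| <= k` (the
#' boundary itself is kept). No re-standardisation loop is applied.
#'
#' @param values Standardised numeric vector.
#' @param k SD bound (default 3).
#' @return Logical keep mask; `NA` values are kept (they carry no
#'   evidence of being outliers).
#' @export
exclude_outliers <- function(values, k = 3) {
  is.na(values) | abs(values) <= k
}

#' Prepare a twin phenotype column for genetic analysis
#'
#' Applies, in order: the normalising transform, standardisation,
#' age/sex residualisation, and the +/- 3 SD outlier screen (screened
#' values become `NA`). The screen is applied once, after
#' standardisation and residualisation.
#'
#' @param dataset Twin data frame with `age` and `sex` columns.
#' @param pheno Phenotype column name.
#' @param transform `"square"` (accuracy), `"sqrt"` (Weber fraction) or
#'   `"none"`.
#' @param k Outlier bound in SDs.
#' @return The dataset with an added column `<pheno>_resid`.
#' @export
prepare_phenotype <- function(dataset, pheno = "pheno",
                              transform = c("none", "square", "sqrt"),
                              k = 3) {
  transform <- match.arg(transform)
  v <- dataset[[pheno]]
  v <- switch(transform,
              none = v,
              square = v^2,
              sqrt = { if (any(v < 0, na.rm = TRUE))
                         stop("negative values under sqrt transform")
                       sqrt(v) })
  r <- standardize_and_residualize(v, dataset$age, dataset$sex)
  r[!exclude_outliers(r, k)] <- NA_real_
  dataset[[paste0(pheno, "_resid")]] <- r
  dataset
}

# type-II sums of squares for the two-way sex x zygosity layout
.anova2_type2 <- function(value, sex, zyg) {
  ok <- !is.na(value)
  value <- value[ok]; sex <- factor(sex[ok]); zyg <- factor(zyg[ok])
  rss <- function(form) sum(stats::residuals(stats::lm(form))^2)
  ss_tot <- sum((value - mean(value))^2)
  r_s <- rss(value ~ sex)
  r_z <- rss(value ~ zyg)
  r_sz <- rss(value ~ sex + zyg)
  r_full <- rss(value ~ sex * zyg)
  ss_sex <- r_z - r_sz
  ss_zyg <- r_s - r_sz
  ss_int <- r_sz - r_full
  df_int <- (nlevels(sex) - 1) * (nlevels(zyg) - 1)
  df_res <- length(value) - nlevels(sex) * nlevels(zyg)
  ms_res <- r_full / df_res
  f_p <- function(ss, df) {
    f <- (ss / df) / ms_res
    stats::pf(f, df, df_res, lower.tail = FALSE)
  }
  list(
    p_zyg = f_p(ss_zyg, nlevels(zyg) - 1),
    eta2_zyg = ss_zyg / ss_tot,
    p_sex = f_p(ss_sex, nlevels(sex) - 1),
    eta2_sex = ss_sex / ss_tot,
    p_int = f_p(ss_int, df_int),
    eta2_int = ss_int / ss_tot,
    r2 = 1 - r_sz / ss_tot
  )
}

#' Descriptive statistics table with a sex-by-zygosity ANOVA
#'
#' Reports, for one randomly chosen twin per family (to keep
#' observations independent) or for all individuals, the mean and SD per
#' group (All, MZ, DZ, Female, Male, MZm, DZm, MZf, DZf, DZo, DZss),
#' skewness and excess kurtosis with their large-sample standard errors
#' (`sqrt(6/N)` and `sqrt(24/N)`), and a two-way fixed-effects ANOVA of
#' sex, zygosity and their interaction with eta-squared effect sizes
#' (type-II sums of squares) plus the R-squared of the additive
#' sex + zygosity model.
#'
#' @param dataset Twin data frame.
#' @param pheno Phenotype column name.
#' @param one_per_pair Select one twin per family at random.
#' @param seed Seed for the per-family draw.
#' @return Object of class `descriptive_report`: `groups` (data frame of
#'   per-group N/mean/SD), `skewness`, `kurtosis`, `se_skew`, `se_kurt`,
#'   `anova` (list), `n`.
#' @export
descriptives <- function(dataset, pheno = "pheno", one_per_pair = TRUE,
                         seed = 1L) {
  stopifnot(nrow(dataset) > 0)
  d <- dataset
  if (one_per_pair) {
    d <- with_seed(seed, {
      picks <- lapply(split(seq_len(nrow(d)), d$family_id), function(i) {
        i[sample.int(length(i), 1)]
      })
      d[unlist(picks), , drop = FALSE]
    })
  }
  v <- d[[pheno]]
  grp <- d$group
  dzss <- grp %in% c("DZm", "DZf")
  sel <- list(All = rep(TRUE, nrow(d)), MZ = d$zygosity == "MZ",
              DZ = d$zygosity == "DZ", Female = d$sex == "F",
              Male = d$sex == "M", MZm = grp == "MZm", DZm = grp == "DZm",
              MZf = grp == "MZf", DZf = grp == "DZf", DZo = grp == "DZos",
              DZss = dzss)
  groups <- do.call(rbind, lapply(names(sel), function(nm) {
    x <- v[sel[[nm]] & !is.na(v)]
    if (!length(x)) {
      return(data.frame(group = nm, n = 0L, mean = NA_real_, sd = NA_real_))
    }
    data.frame(group = nm, n = length(x), mean = mean(x), sd = stats::sd(x))
  }))
  x <- v[!is.na(v)]
  n <- length(x)
  const <- stats::sd(x) == 0
  an <- if (const) NULL else .anova2_type2(v, d$sex, d$zygosity)
  structure(list(groups = groups,
                 skewness = if (const) NA_real_ else sample_skewness(x),
                 kurtosis = if (const) NA_real_ else sample_kurtosis(x),
                 se_skew = sqrt(6 / n), se_kurt = sqrt(24 / n),
                 anova = an, n = n, degenerate = const),
            class = "descriptive_report")
}

#' @export
print.descriptive_report <- function(x, ...) {
  cat(sprintf("Descriptives (N = %d)\n", x$n))
  print(x$groups, row.names = FALSE, digits = 3)
  cat(sprintf("skewness %.2f (SE %.2f), kurtosis %.2f (SE %.2f)\n",
              x$skewness, x$se_skew, x$kurtosis, x$se_kurt))
  if (!is.null(x$anova)) {
    a <- x$anova
    cat(sprintf(
      "ANOVA: zyg p = %.2f (eta2 %.3f), sex p = %.2f (eta2 %.3f), ",
      a$p_zyg, a$eta2_zyg, a$p_sex, a$eta2_sex))
    cat(sprintf("int p = %.2f (eta2 %.3f), R2 = %.3f\n",
                a$p_int, a$eta2_int, a$r2))
  } else cat("ANOVA undefined (constant phenotype)\n")
  invisible(x)
}
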