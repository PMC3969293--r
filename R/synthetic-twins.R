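# Generator for ACE-structured twin phenotypes across the five
# zygosity-by-sex groups (MZm, MZf, DZm, DZf, DZos).

#' Specification for a simulated twin dataset
#'
#' Variance proportions are per sex and must sum to one: the phenotype of
#' each twin is `a*A + c*C + e*E` with standard-normal latent factors, so
#' every individual has unit variance. The additive factor A is fully
#' shared within MZ pairs, correlated 0.5 within same-sex DZ pairs and
#' `rg_os` within opposite-sex pairs; C is shared within a pair; E is
#' independent.
#'
#' Default group sizes mirror a large adolescent twin cohort (317 MZm,
#' 519 MZf, 281 DZm, 452 DZf, 689 DZos pairs); `missing_rate` drops one
#' random co-twin per affected pair to create singletons.
#'
#' @param a2_m,c2_m,e2_m,a2_f,c2_f,e2_f Variance proportions in `[0,1]`,
#'   summing to 1 within 1e-9 per sex.
#' @param rg_os Genetic correlation for opposite-sex DZ pairs, in `[0,1]`;
#'   0.5 means the same genetic factors operate in both sexes.
#' @param n_pairs_by_group Named counts for `MZm`, `MZf`, `DZm`, `DZf`,
#'   `DZos`.
#' @param missing_rate Fraction of pairs reduced to singletons.
#' @param age_range Ages (years) drawn uniformly per pair (identical within
#'   a pair).
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `twin_sim_spec`.
#' @export
twin_sim_spec <- function(a2_m = 0.32, c2_m = 0, e2_m = 0.68,
                          a2_f = 0.32, c2_f = 0, e2_f = 0.68,
                          rg_os = 0.5,
                          n_pairs_by_group = c(MZm = 317, MZf = 519,
                                               DZm = 281, DZf = 452,
                                               DZos = 689),
                          missing_rate = 0.13,
                          age_range = c(16.1, 17.1),
                          seed = NULL) {
  for (f in c("a2_m", "c2_m", "e2_m", "a2_f", "c2_f", "e2_f")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop_field(f, "must be a proportion in [0,1]")
    }
  }
  if (abs(a2_m + c2_m + e2_m - 1) > 1e-9) {
    stop_field("a2_m + c2_m + e2_m", "male proportions must sum to 1")
  }
  if (abs(a2_f + c2_f + e2_f - 1) > 1e-9) {
    stop_field("a2_f + c2_f + e2_f", "female proportions must sum to 1")
  }
  if (!is.numeric(rg_os) || rg_os < 0 || rg_os > 1) {
    stop_field("rg_os", "must lie in [0,1]")
  }
  gg <- c("MZm", "MZf", "DZm", "DZf", "DZos")
  if (!all(gg %in% names(n_pairs_by_group))) {
    stop_field("n_pairs_by_group", "needs counts for MZm, MZf, DZm, DZf, DZos")
  }
  n_pairs_by_group <- n_pairs_by_group[gg]
  if (any(n_pairs_by_group < 0)) stop_field("n_pairs_by_group", "counts must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_field("missing_rate", "must lie in [0,1)")
  }
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    stop_field("age_range", "must be an increasing length-2 range")
  }
  structure(list(a2_m = a2_m, c2_m = c2_m, e2_m = e2_m,
                 a2_f = a2_f, c2_f = c2_f, e2_f = e2_f,
                 rg_os = rg_os, n_pairs_by_group = n_pairs_by_group,
                 missing_rate = missing_rate, age_range = age_range,
                 seed = seed),
            class = "twin_sim_spec")
}

# one zygosity-by-sex group of pairs
.sim_twin_group <- function(n, group, rA, sex1, sex2, spec, id0) {
  if (n == 0) return(NULL)
  props <- function(s) {
    if (s == "M") c(spec$a2_m, spec$c2_m, spec$e2_m)
    else c(spec$a2_f, spec$c2_f, spec$e2_f)
  }
  p1 <- props(sex1); p2 <- props(sex2)
  A1 <- stats::rnorm(n)
  A2 <- rA * A1 + sqrt(1 - rA^2) * stats::rnorm(n)
  C <- stats::rnorm(n)
  y1 <- sqrt(p1[1]) * A1 + sqrt(p1[2]) * C + sqrt(p1[3]) * stats::rnorm(n)
  y2 <- sqrt(p2[1]) * A2 + sqrt(p2[2]) * C + sqrt(p2[3]) * stats::rnorm(n)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  fam <- as.integer(id0 + seq_len(n))
  data.frame(
    family_id = rep(fam, each = 2),
    twin = rep(1:2, times = n),
    zygosity = if (startsWith(group, "MZ")) "MZ" else "DZ",
    sex = rep(c(sex1, sex2), times = n),
    age = rep(round(age, 2), each = 2),
    group = group,
    pheno = as.vector(rbind(y1, y2)),
    stringsAsFactors = FALSE
  )
}

#' Simulate an ACE-structured twin phenotype dataset
#'
#' @param spec A [twin_sim_spec()].
#' @return Data frame with columns `family_id`, `twin` (1 or 2),
#'   `zygosity` (`MZ`/`DZ`), `sex` (`M`/`F`), `age`, `group` (five-group
#'   label) and `pheno` (possibly `NA` for dropped co-twins). In DZos
#'   pairs twin 1 is the male.
#' @export
simulate_twin_dataset <- function(spec) {
  stopifnot(inherits(spec, "twin_sim_spec"))
  with_seed(spec$seed, {
    ng <- spec$n_pairs_by_group
    parts <- list(
      .sim_twin_group(ng[["MZm"]], "MZm", 1.0, "M", "M", spec, 0L),
      .sim_twin_group(ng[["MZf"]], "MZf", 1.0, "F", "F", spec, ng[["MZm"]]),
      .sim_twin_group(ng[["DZm"]], "DZm", 0.5, "M", "M", spec,
                      sum(ng[c("MZm", "MZf")])),
      .sim_twin_group(ng[["DZf"]], "DZf", 0.5, "F", "F", spec,
                      sum(ng[c("MZm", "MZf", "DZm")])),
      .sim_twin_group(ng[["DZos"]], "DZos", spec$rg_os, "M", "F", spec,
                      sum(ng[c("MZm", "MZf", "DZm", "DZf")]))
    )
    out <- do.call(rbind, parts)
    if (is.null(out)) stop("all group counts are zero")
    if (spec$missing_rate > 0) {
      fams <- unique(out$family_id)
      drop <- fams[stats::runif(length(fams)) < spec$missing_rate]
      if (length(drop)) {
        which_twin <- sample(1:2, length(drop), replace = TRUE)
        key <- paste(out$family_id, out$twin)
        out$pheno[key %in% paste(drop, which_twin)] <- NA_real_
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Implied twin correlations for a simulation spec
#'
#' Expected within-pair phenotypic correlations under the generative model:
#' `rMZ = a2 + c2`, `rDZss = 0.5 a2 + c2`,
#' `rDZos = rg_os * am * af + cm * cf` (with unit variances).
#'
#' @param spec A [twin_sim_spec()].
#' @return Named vector of implied correlations per group.
#' @export
implied_twin_correlations <- function(spec) {
  stopifnot(inherits(spec, "twin_sim_spec"))
  c(MZm = spec$a2_m + spec$c2_m,
    MZf = spec$a2_f + spec$c2_f,
    DZm = 0.5 * spec$a2_m + spec$c2_m,
    DZf = 0.5 * spec$a2_f + spec$c2_f,
    DZos = spec$rg_os * sqrt(spec$a2_m * spec$a2_f) +
      sqrt(spec$c2_m * spec$c2_f))
}
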