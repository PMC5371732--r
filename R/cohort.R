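#' Default per-group clinical moments
#'
#' Group means and standard deviations of the clinical variables for the low
#' (liver fat < 5.5\%) and high (> 5.5\%) steatosis groups. Units: liver fat
#' \%, age years, weight kg, BMI kg/m^2, glucose mmol/l, insulin mU/l, HOMA-IR
#' unitless, plasma TG mmol/l, liver enzymes U/l, VLDL-TG secretion mmol TG/h,
#' apoB secretion mmol AA-equivalents/h. The VLDL secretion moments are a
#' package convention (molar secretion units are standardized internally to
#' mmol/h); all others are cohort-characteristic values.
#'
#' @return data.frame with columns \code{variable}, \code{low_mean},
#'   \code{low_sd}, \code{high_mean}, \code{high_sd}.
#' @export
default_group_params <- function() {
  d <- rbind(
    c("liver_fat_pct",       2.8,  1.7, 13.4,  6.4),
    c("age",                52.1,  8.4, 52.6,  8.0),
    c("weight",             92.4, 11.2, 102.2, 14.0),
    c("bmi",                29.7,  3.2, 32.9,  3.4),
    c("fasting_glucose",     5.5,  0.5,  5.85, 0.6),
    c("fasting_insulin",     7.6,  5.0, 14.0,  7.0),
    c("homa_ir",             1.9,  1.3,  3.7,  2.0),
    c("plasma_tg",           1.7,  0.6,  2.1,  0.8),
    c("alt",                23.5,  9.3, 38.9, 28.3),
    c("ast",                21.9,  5.1, 23.2,  5.8),
    c("alp",                63.2, 16.7, 70.5, 19.3),
    c("ggt",                27.6, 16.4, 31.2, 13.9),
    c("vldl_tg_secretion",   0.50, 0.20, 0.72, 0.25),
    c("vldl_apob_secretion", 0.55, 0.18, 0.66, 0.22)
  )
  out <- data.frame(variable = d[, 1], stringsAsFactors = FALSE)
  out[c("low_mean", "low_sd", "high_mean", "high_sd")] <-
    lapply(2:5, function(j) as.numeric(d[, j]))
  out
}

#' Default whole-cohort correlation targets
#'
#' Pairwise Pearson correlations the generated cohort reproduces on the whole
#' cohort (both steatosis groups pooled). The liver-fat/VLDL-TG target of
#' 0.581 mirrors the measured coupling between steatosis and VLDL secretion;
#' the remaining values are package conventions consistent with the observed
#' significant positive correlations of liver fat with weight, BMI, insulin,
#' HOMA-IR, plasma TG and ALT.
#'
#' @return data.frame with columns \code{var1}, \code{var2}, \code{r}.
#' @export
default_correlation_targets <- function() {
  d <- rbind(
    c("liver_fat_pct", "weight",              0.40),
    c("liver_fat_pct", "bmi",                 0.45),
    c("liver_fat_pct", "fasting_insulin",     0.50),
    c("liver_fat_pct", "homa_ir",             0.50),
    c("liver_fat_pct", "plasma_tg",           0.35),
    c("liver_fat_pct", "alt",                 0.40),
    c("liver_fat_pct", "vldl_tg_secretion",   0.581),
    c("liver_fat_pct", "vldl_apob_secretion", 0.50),
    c("weight",        "bmi",                 0.80),
    c("fasting_insulin", "homa_ir",           0.90),
    c("fasting_glucose", "homa_ir",           0.45),
    c("plasma_tg",     "vldl_tg_secretion",   0.40),
    c("vldl_tg_secretion", "vldl_apob_secretion", 0.60)
  )
  data.frame(var1 = d[, 1], var2 = d[, 2], r = as.numeric(d[, 3]),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic steatosis cohort
#'
#' @param n_subjects number of subjects (>= 2); split half/half between the
#'   low and high steatosis groups (the extra subject of an odd total goes to
#'   the low group).
#' @param seed integer RNG seed making the cohort reproducible.
#' @param group_params per-group moments, see [default_group_params()].
#' @param hs_threshold liver-fat percentage splitting low from high HS.
#' @param target_correlations whole-cohort Pearson targets, see
#'   [default_correlation_targets()].
#' @param male_fraction probability that a subject is male (default 75/86).
#' @param fat_mass_missing fraction of subjects whose measured fat mass is
#'   withheld (default 29/73, imputed downstream from BMI).
#' @param fat_mass_resid_sd residual SD (kg) of measured fat mass around the
#'   BMI regression line.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 86, seed = 1,
                        group_params = default_group_params(),
                        hs_threshold = 5.5,
                        target_correlations = default_correlation_targets(),
                        male_fraction = 75 / 86,
                        fat_mass_missing = 29 / 73,
                        fat_mass_resid_sd = 2.5) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (hs_threshold <= 0) stop("hs_threshold must be positive")
  if (any(group_params$low_sd < 0) || any(group_params$high_sd < 0))
    stop("group SDs must be nonnegative")
  if (any(abs(target_correlations$r) > 1))
    stop("target correlations must satisfy |r| <= 1")
  bad <- setdiff(unique(c(target_correlations$var1, target_correlations$var2)),
                 group_params$variable)
  if (length(bad))
    stop("correlation target references unknown variable(s): ",
         paste(bad, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 group_params = group_params, hs_threshold = hs_threshold,
                 target_correlations = target_correlations,
                 male_fraction = male_fraction,
                 fat_mass_missing = fat_mass_missing,
                 fat_mass_resid_sd = fat_mass_resid_sd),
            class = "cohort_spec")
}

## lognormal parameters matched to a given mean and sd
.lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

## latent Gaussian correlation that yields the requested whole-cohort Pearson
## correlation for a 50/50 two-group mixture of bivariate lognormals
.latent_r <- function(r_target, p1, p2, m1, s1, m2, s2) {
  # p*: .lnorm_pars for var i and j in group 1 / group 2 (lists of two)
  Vi <- 0.5 * (s1[1]^2 + s2[1]^2) + 0.25 * (m1[1] - m2[1])^2
  Vj <- 0.5 * (s1[2]^2 + s2[2]^2) + 0.25 * (m1[2] - m2[2])^2
  cov_t <- r_target * sqrt(Vi * Vj)
  between <- 0.25 * (m1[1] - m2[1]) * (m1[2] - m2[2])
  f <- function(r) {
    c1 <- m1[1] * m1[2] * (exp(r * p1[[1]]$sdlog * p1[[2]]$sdlog) - 1)
    c2 <- m2[1] * m2[2] * (exp(r * p2[[1]]$sdlog * p2[[2]]$sdlog) - 1)
    0.5 * (c1 + c2) + between - cov_t
  }
  lo <- f(-0.999); hi <- f(0.999)
  if (lo > 0 || hi < 0)
    stop("correlation target ", round(r_target, 3),
         " is unachievable for the given group moments")
  stats::uniroot(f, c(-0.999, 0.999), tol = 1e-10)$root
}

#' Generate a synthetic steatosis cohort
#'
#' Draws subjects from a two-group Gaussian copula: per clinical variable, a
#' lognormal marginal moment-matched to the group mean and SD (so group
#' moments are reproduced exactly in expectation and all values are strictly
#' positive); across variables, a shared latent correlation matrix whose
#' pairwise entries are solved numerically so the whole-cohort Pearson
#' correlations converge to the requested targets as n grows. A latent matrix
#' that is not positive semi-definite after construction is an explicit error.
#'
#' Fat mass is "measured" (BMI regression plus residual noise) for a subset of
#' subjects and withheld (\code{NA}) for the configured fraction, emulating
#' body-composition data available in only part of a cohort.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class \code{liver_cohort}, one row per subject.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gp <- spec$group_params
  vars <- gp$variable
  p <- length(vars)
  n <- spec$n_subjects
  n_low <- ceiling(n / 2); n_high <- n - n_low

  pars_low <- lapply(seq_len(p), function(i) .lnorm_pars(gp$low_mean[i], gp$low_sd[i]))
  pars_high <- lapply(seq_len(p), function(i) .lnorm_pars(gp$high_mean[i], gp$high_sd[i]))
  names(pars_low) <- names(pars_high) <- vars

  R <- diag(p); dimnames(R) <- list(vars, vars)
  tc <- spec$target_correlations
  for (k in seq_len(nrow(tc))) {
    i <- match(tc$var1[k], vars); j <- match(tc$var2[k], vars)
    r <- .latent_r(tc$r[k],
                   pars_low[c(i, j)], pars_high[c(i, j)],
                   c(gp$low_mean[i], gp$low_mean[j]),
                   c(gp$low_sd[i], gp$low_sd[j]),
                   c(gp$high_mean[i], gp$high_mean[j]),
                   c(gp$high_sd[i], gp$high_sd[j]))
    R[i, j] <- R[j, i] <- r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent correlation matrix is not positive semi-definite; ",
         "relax the correlation targets")
  L <- chol(R + diag(1e-10, p))

  set.seed(spec$seed)
  draw_group <- function(ng, pars) {
    Z <- matrix(stats::rnorm(ng * p), ng, p) %*% L
    X <- vapply(seq_len(p), function(i)
      stats::qlnorm(stats::pnorm(Z[, i]), pars[[i]]$meanlog, pars[[i]]$sdlog),
      numeric(ng))
    if (ng == 1L) X <- matrix(X, 1L, p)
    colnames(X) <- vars
    X
  }
  X <- rbind(draw_group(n_low, pars_low), draw_group(n_high, pars_high))
  X[, "liver_fat_pct"] <- pmin(X[, "liver_fat_pct"], 100)

  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  fat_meas <- 1.763 * X[, "bmi"] - 26.75 +
    stats::rnorm(n, 0, spec$fat_mass_resid_sd)
  fat_meas <- pmax(fat_meas, 1)
  withheld <- stats::runif(n) < spec$fat_mass_missing
  fat_meas[withheld] <- NA_real_

  cohort <- data.frame(id = sprintf("S%03d", seq_len(n)), sex = sex,
                       as.data.frame(X), fat_mass = fat_meas,
                       stringsAsFactors = FALSE)
  class(cohort) <- c("liver_cohort", "data.frame")
  cohort
}

#' Split a cohort at a liver-fat threshold
#'
#' Subjects with liver fat strictly below the threshold form the low-HS group;
#' subjects at or above it form the high-HS group (ties go to high, matching
#' the "low < threshold" group definition).
#'
#' @param cohort a \code{liver_cohort} data.frame.
#' @param threshold liver-fat percentage (> 0), default 5.5.
#' @return list with elements \code{low} and \code{high}.
#' @export
split_high_low <- function(cohort, threshold = 5.5) {
  if (threshold <= 0) stop("threshold must be positive")
  if (nrow(cohort) == 0) stop("cohort is empty")
  hi <- cohort$liver_fat_pct >= threshold
  list(low = cohort[!hi, , drop = FALSE], high = cohort[hi, , drop = FALSE])
}

#' Write / read a cohort as CSV
#'
#' Column header: id, sex, the clinical variables of
#' [default_group_params()] in order, fat_mass (empty when withheld).
#'
#' @param cohort a \code{liver_cohort} data.frame.
#' @param path CSV file path.
#' @return \code{read_cohort_csv} returns the \code{liver_cohort}.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "liver_fat_pct", "weight", "bmi",
            "vldl_tg_secretion", "vldl_apob_secretion")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  class(cohort) <- c("liver_cohort", "data.frame")
  cohort
}
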