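#' Log-transform a metabolite matrix
#'
#' Natural log of every observed abundance; missing entries stay missing.
#' There is deliberately no imputation pathway anywhere in the metabolomics
#' stage: non-detected values remain \code{NA} through every downstream
#' statistic, which all use pairwise-complete observations.
#'
#' @param mat a \code{metabolite_matrix} (positive where present).
#' @param base logarithm base (default e; results' signs and ordering do not
#'   depend on it).
#' @return the log-scale matrix.
#' @export
log_transform <- function(mat, base = exp(1)) {
  vals <- unclass(mat)
  if (any(vals[!is.na(vals)] <= 0))
    stop("non-positive abundance encountered; log transform undefined")
  out <- log(vals, base = base)
  class(out) <- class(mat)
  out
}

#' Welch two-sample tests per metabolite between steatosis groups
#'
#' Welch's unequal-variance t-test of every metabolite between the low and
#' high liver-fat groups, on log-transformed abundances, using only observed
#' values (missing entries excluded, never imputed). Metabolites with fewer
#' than 2 observed values in either group are skipped with a reason; a
#' metabolite with zero variance in both groups is flagged degenerate.
#'
#' @param mat log-scale \code{metabolite_matrix}.
#' @param grouping factor/character per subject: \code{"low"} or \code{"high"}.
#' @return data.frame of class \code{metabolite_association}: metabolite,
#'   mean_low, mean_high, log_diff (high - low), t, df, p, neg_log10_p,
#'   n_low, n_high, note. Volcano-plot ready.
#' @export
welch_tests <- function(mat, grouping) {
  if (length(grouping) != nrow(mat))
    stop("grouping length must equal number of subjects")
  grouping <- as.character(grouping)
  if (!all(grouping %in% c("low", "high")))
    stop("grouping must consist of 'low' / 'high'")
  res <- lapply(colnames(mat), function(j) {
    x <- mat[grouping == "low", j]; x <- x[!is.na(x)]
    y <- mat[grouping == "high", j]; y <- y[!is.na(y)]
    base <- data.frame(metabolite = j, mean_low = NA_real_,
                       mean_high = NA_real_, log_diff = NA_real_,
                       t = NA_real_, df = NA_real_, p = NA_real_,
                       neg_log10_p = NA_real_,
                       n_low = length(x), n_high = length(y), note = "",
                       stringsAsFactors = FALSE)
    if (length(x) < 2 || length(y) < 2) {
      base$note <- "skipped: fewer than 2 observed values in a group"
      return(base)
    }
    base$mean_low <- mean(x); base$mean_high <- mean(y)
    base$log_diff <- base$mean_high - base$mean_low
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
      base$note <- "degenerate: zero variance in both groups"
      if (abs(base$log_diff) < 1e-12) { base$t <- 0; base$p <- 1 }
      return(base)
    }
    tt <- stats::t.test(y, x, var.equal = FALSE)
    base$t <- unname(tt$statistic)
    base$df <- unname(tt$parameter)
    base$p <- tt$p.value
    base$neg_log10_p <- -log10(tt$p.value)
    base
  })
  out <- do.call(rbind, res)
  class(out) <- c("metabolite_association", "data.frame")
  out
}

#' Pairwise metabolite correlations under a detection threshold
#'
#' Pearson correlation between metabolite pairs using pairwise-complete
#' observations, computed only when both metabolites are jointly detected in
#' at least \code{min_detected} subjects (default 30); pairs below the
#' threshold are reported as excluded rather than dropped silently.
#'
#' @param mat log-scale \code{metabolite_matrix}.
#' @param min_detected minimum joint detections (>= 3).
#' @return data.frame: met1, met2, r, p, n_joint, excluded.
#' @export
pairwise_correlations <- function(mat, min_detected = 30) {
  if (min_detected < 3) stop("min_detected must be at least 3")
  mets <- colnames(mat)
  pairs <- utils::combn(length(mets), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- !is.na(mat[, i]) & !is.na(mat[, j])
    nj <- sum(ok)
    if (nj < min_detected)
      return(data.frame(met1 = mets[i], met2 = mets[j], r = NA_real_,
                        p = NA_real_, n_joint = nj, excluded = TRUE,
                        stringsAsFactors = FALSE))
    x <- mat[ok, i]; y <- mat[ok, j]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
      return(data.frame(met1 = mets[i], met2 = mets[j], r = NA_real_,
                        p = NA_real_, n_joint = nj, excluded = TRUE,
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y)
    data.frame(met1 = mets[i], met2 = mets[j], r = unname(ct$estimate),
               p = ct$p.value, n_joint = nj, excluded = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Correlate metabolites with hepatic steatosis
#'
#' Pearson correlation of each metabolite's log abundance with the liver-fat
#' percentage, over subjects in which the metabolite was detected; the same
#' detection threshold as [pairwise_correlations()] applies (metabolite vs
#' phenotype).
#'
#' @param mat log-scale \code{metabolite_matrix}.
#' @param hs liver-fat percentage per subject.
#' @param min_detected minimum detections required to report a correlation.
#' @return data.frame of class \code{metabolite_association}: metabolite, r,
#'   p, n, excluded.
#' @export
hs_correlations <- function(mat, hs, min_detected = 30) {
  if (length(hs) != nrow(mat)) stop("hs length must equal number of subjects")
  res <- lapply(colnames(mat), function(j) {
    ok <- !is.na(mat[, j]) & is.finite(hs)
    n <- sum(ok)
    if (n < min_detected || stats::sd(mat[ok, j]) < 1e-12)
      return(data.frame(metabolite = j, r = NA_real_, p = NA_real_, n = n,
                        excluded = TRUE, stringsAsFactors = FALSE))
    ct <- stats::cor.test(mat[ok, j], hs[ok])
    data.frame(metabolite = j, r = unname(ct$estimate), p = ct$p.value,
               n = n, excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("metabolite_association", "data.frame")
  out
}
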