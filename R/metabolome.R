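#' Default plasma-metabolome effect specification
#'
#' Defines how each synthetic plasma metabolite is coupled to hepatic
#' steatosis: \code{hs_loading} is the target Pearson correlation between the
#' log abundance and liver fat (negative for glycine, serine, betaine and
#' N-acetylglycine, emulating the depletion of glutathione precursors with
#' increasing steatosis), \code{detection_prob} the per-sample probability
#' that the metabolite is detected at all. Null metabolites (zero loading)
#' fill the panel. Serine and glycine additionally share a latent factor so
#' their mutual correlation reaches \code{serine_glycine_r} (default 0.77).
#'
#' @param serine_glycine_r target log-scale Pearson correlation between
#'   serine and glycine.
#' @param n_null number of uncoupled filler metabolites.
#' @return list of class \code{metabolome_effects} with elements
#'   \code{metabolites} (data.frame: metabolite, hs_loading, detection_prob,
#'   meanlog, sdlog) and \code{serine_glycine_r}.
#' @export
metabolome_effects <- function(serine_glycine_r = 0.77, n_null = 14) {
  d <- rbind(
    c("glycine",               -0.35, 1.00),
    c("serine",                -0.35, 1.00),
    c("betaine",               -0.30, 0.95),
    c("N-acetylglycine",       -0.30, 0.85),
    c("N-delta-acetylornithine", -0.25, 0.80),
    c("butyrylcarnitine",       0.30, 0.95),
    c("glycylphenylalanine",    0.25, 0.75),
    c("gamma-tocopherol",       0.25, 0.90),
    c("kynurenate",             0.25, 0.90),
    c("N-methylproline",        0.20, 0.70),
    c("diacylglycerol-34:2",    0.30, 0.85),
    c("triacylglycerol-52:3",   0.35, 0.95),
    c("palmitoylcarnitine",     0.25, 0.90),
    c("oleate",                 0.30, 0.95),
    c("cysteine",               0.00, 0.95),
    c("glutamine",              0.00, 1.00)
  )
  mets <- data.frame(metabolite = d[, 1],
                     hs_loading = as.numeric(d[, 2]),
                     detection_prob = as.numeric(d[, 3]),
                     stringsAsFactors = FALSE)
  if (n_null > 0) {
    mets <- rbind(mets, data.frame(
      metabolite = sprintf("metabolite-%02d", seq_len(n_null)),
      hs_loading = 0,
      detection_prob = rep(c(0.95, 0.85, 0.6), length.out = n_null),
      stringsAsFactors = FALSE))
  }
  mets$meanlog <- log(100)
  mets$sdlog <- 0.4
  structure(list(metabolites = mets, serine_glycine_r = serine_glycine_r),
            class = "metabolome_effects")
}

#' Generate a synthetic plasma metabolite matrix
#'
#' For each metabolite the log abundance is built as
#' \code{loading * z(HS) + coupling * F + residual}, where \code{z(HS)} is the
#' cohort-standardized liver fat, \code{F} a latent factor shared by serine
#' and glycine, and the residual scaled so the composite has unit variance.
#' Abundances are lognormal (strictly positive where present); missingness is
#' applied after generation as independent non-detection with the
#' per-metabolite detection probability. Missing entries are \code{NA};
#' nothing is ever imputed.
#'
#' @param cohort a \code{liver_cohort} data.frame.
#' @param seed integer RNG seed.
#' @param effects a [metabolome_effects()] specification.
#' @return numeric matrix (subjects x metabolites, rownames = subject ids) of
#'   class \code{metabolite_matrix} with \code{NA} for non-detected entries.
#' @export
generate_metabolome <- function(cohort, seed = 1,
                                effects = metabolome_effects()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 2)
  mets <- effects$metabolites
  if (any(mets$detection_prob < 0 | mets$detection_prob > 1))
    stop("detection probabilities must lie in [0, 1]")
  if (any(abs(mets$hs_loading) > 1))
    stop("|hs_loading| must not exceed 1")
  n <- nrow(cohort)
  hs <- cohort$liver_fat_pct
  z <- (hs - mean(hs)) / stats::sd(hs)

  set.seed(seed)
  Fc <- stats::rnorm(n)   # serine-glycine shared factor
  X <- matrix(NA_real_, n, nrow(mets),
              dimnames = list(cohort$id, mets$metabolite))
  sg <- mets$metabolite %in% c("serine", "glycine")
  r_sg <- effects$serine_glycine_r
  for (j in seq_len(nrow(mets))) {
    a <- mets$hs_loading[j]
    cshare <- 0
    if (sg[j]) {
      c2 <- r_sg - a^2      # shared-factor weight: a^2 + c^2 = r_sg
      if (c2 < 0)
        stop("serine_glycine_r must be at least hs_loading^2 for serine/glycine")
      cshare <- sqrt(c2)
    }
    resid_var <- 1 - a^2 - cshare^2
    if (resid_var < 0)
      stop("loadings of ", mets$metabolite[j], " imply negative residual variance")
    comp <- a * z + cshare * Fc + sqrt(resid_var) * stats::rnorm(n)
    X[, j] <- exp(mets$meanlog[j] + mets$sdlog[j] * comp)
  }
  detected <- matrix(stats::runif(length(X)), n, ncol(X)) <=
    rep(mets$detection_prob, each = n)
  X[!detected] <- NA_real_
  class(X) <- c("metabolite_matrix", class(X))
  X
}

#' Write / read a metabolite matrix as CSV
#'
#' Subjects in rows (first column \code{id}), metabolites in columns, empty
#' cells for non-detected values.
#'
#' @param mat a \code{metabolite_matrix}.
#' @param path CSV file path.
#' @return \code{read_metabolite_csv} returns the matrix with \code{NA} for
#'   empty cells.
#' @export
write_metabolite_csv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(unclass(mat),
                                                     check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metabolite_csv
#' @export
read_metabolite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  class(m) <- c("metabolite_matrix", class(m))
  m
}
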