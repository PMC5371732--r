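#' Physiological constants of the fasting-state liver boundary model
#'
#' Returns the set of literature-derived physiological constants used to
#' translate a subject's body composition into exchange bounds for the liver
#' network. Every value can be overridden by name, e.g.
#' \code{physiology_constants(adipose_flow_ml_min_100g = 3.0)}.
#'
#' The defaults encode the fasting-state whole-body balance the model assumes:
#' \itemize{
#'   \item urinary urea (392 mmol/24 h) as a proxy for net hepatic amino-acid
#'     consumption, converted with a mean AA molar mass of 136.5 g/mol and a
#'     mean nitrogen content of 1.45 N atoms per AA;
#'   \item whole-body lactate production of 80 g/day delivered to the liver;
#'   \item adipose fatty-acid release of 1.8 mmol/h per kg fat mass, glycerol
#'     at a 1:3 molar ratio to FA, adipose blood flow of 3.5 ml/min per 100 g
#'     fat tissue (midpoint of the measured 3-4 range);
#'   \item a minimum gluconeogenic glucose output of 16.7 mmol/h (3 g/h) and
#'     glycogen breakdown of 5.5 umol/kg body weight/min;
#'   \item ketone-body secretion lower bounds of 0.1 mmol/h each for
#'     acetoacetate and beta-hydroxybutyrate;
#'   \item muscle AA release of 0.23 mmol/h per kg muscle mass, of which
#'     glutamine + alanine are 60\%; about 4\% of adipose FA release is taken
#'     up by muscle (recorded but not subtracted from the liver input).
#' }
#'
#' @param ... named overrides of individual constants.
#' @return named list of constants.
#' @export
physiology_constants <- function(...) {
  const <- list(
    urea_excretion_mmol_day   = 392,
    aa_mean_molar_mass        = 136.5,   # g/mol
    aa_nitrogen_factor        = 1.45,    # N atoms per AA
    lactate_total_g_day       = 80,
    lactate_molar_mass        = 90.08,
    fa_release_mmol_h_kg      = 1.8,     # per kg fat mass
    glycerol_to_fa_ratio      = 3,       # mol FA per mol glycerol released
    adipose_flow_ml_min_100g  = 3.5,     # midpoint of 3-4 ml/min/100 g
    gng_min_mmol_h            = 16.7,    # 3 g glucose/h
    glycogenolysis_umol_kg_min = 5.5,
    ketone_lb_mmol_h          = 0.1,     # per ketone body
    muscle_glnala_fraction    = 0.60,
    muscle_fa_uptake_fraction = 0.04,
    brain_glucose_g_h         = 6,
    glucose_molar_mass        = 180.16,
    muscle_aa_release_mmol_h_kg = 0.23,  # calibrated: external AA supply ~35 g/day
    aa_demand_g_day           = 77.6,    # urea-derived net hepatic AA consumption
    tg_fa_stoich              = 3,       # FA equivalents per TG
    ros_yield_per_fa          = 0.3,     # mol H2O2 per mol FA oxidized (free parameter)
    ros_yield_per_aax         = 0.2,     # mol H2O2 per mol pooled AA oxidized
    gsh_turnover_lb_mmol_h    = 0.05,    # biliary GSH efflux lower bound
    default_flux_ub           = 1e4      # mmol/h cap standing in for "unbounded"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(const))
    if (length(bad)) stop("unknown physiology constant(s): ",
                          paste(bad, collapse = ", "))
    const[names(dots)] <- dots
  }
  stopifnot(all(vapply(const, function(x) is.numeric(x) && x > 0, logical(1))))
  if (const$muscle_glnala_fraction >= 1)
    stop("muscle_glnala_fraction must lie in (0, 1)")
  const
}

#' Amino-acid release, concentration and composition profiles
#'
#' Loads the per-amino-acid profile table used by the boundary model: fasting
#' muscle release fractions, adipose veno-arterial concentration differences,
#' and the molar AA composition of liver protein (used for the autophagy input
#' and the apoB pseudo-protein). The packaged default is an editable TSV; a
#' custom table with the same columns can be supplied instead.
#'
#' @param path optional path to a profile TSV with columns \code{aa},
#'   \code{muscle_fraction}, \code{adipose_conc_umol_l},
#'   \code{liver_molar_ratio}, \code{molar_mass}, \code{carbons}.
#' @return data.frame, one row per amino-acid species, fractions validated.
#' @export
aa_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_profiles.tsv", package = "steatoflux",
                        mustWork = TRUE)
  prof <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("aa", "muscle_fraction", "adipose_conc_umol_l",
            "liver_molar_ratio", "molar_mass", "carbons")
  if (!all(need %in% names(prof)))
    stop("profile table must contain columns: ", paste(need, collapse = ", "))
  if (any(prof$muscle_fraction < 0) || any(prof$liver_molar_ratio < 0) ||
      any(prof$adipose_conc_umol_l < 0))
    stop("profile fractions and concentrations must be nonnegative")
  if (abs(sum(prof$muscle_fraction) - 1) > 1e-8)
    stop("muscle_fraction column must sum to 1")
  if (abs(sum(prof$liver_molar_ratio) - 1) > 1e-8)
    stop("liver_molar_ratio column must sum to 1")
  prof
}
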