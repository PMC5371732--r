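#' Convert urinary urea excretion into net hepatic amino-acid consumption
#'
#' Urinary urea is used as a proxy for the net loss of amino acids from the
#' liver in the fasting state. With the default mean AA molar mass
#' (136.5 g/mol) and mean nitrogen content (1.45 N per AA) the published
#' fasting urea excretion of 392 mmol/24 h converts to 77.6 g AA/day.
#'
#' Two nitrogen accounting modes are provided. \code{"printed"} (default)
#' applies the nitrogen factor multiplicatively,
#' \code{urea * mass / 1000 * factor}, reproducing the published figure of
#' 77.6 g/day. \code{"per_urea_nitrogen"} instead counts 2 N per urea and
#' divides by the per-AA nitrogen content,
#' \code{urea * 2 / factor * mass / 1000} (= 73.8 g/day at the defaults); see
#' the methods vignette for the rationale of the default.
#'
#' @param urea_mmol_per_day urinary urea excretion (mmol/24 h).
#' @param aa_molar_mass mean amino-acid molar mass (g/mol).
#' @param nitrogen_factor mean nitrogen atoms per amino acid.
#' @param mode nitrogen accounting mode, see Details.
#' @return net hepatic AA consumption in g/day.
#' @export
urea_to_aa_consumption <- function(urea_mmol_per_day,
                                   aa_molar_mass = 136.5,
                                   nitrogen_factor = 1.45,
                                   mode = c("printed", "per_urea_nitrogen")) {
  mode <- match.arg(mode)
  stopifnot(urea_mmol_per_day >= 0, aa_molar_mass >= 0, nitrogen_factor > 0)
  if (mode == "printed") {
    urea_mmol_per_day * aa_molar_mass / 1000 * nitrogen_factor
  } else {
    urea_mmol_per_day * 2 / nitrogen_factor * aa_molar_mass / 1000
  }
}

#' Hepatic lactate input rate
#'
#' Converts whole-body lactate production (g/day, default 80 g from red blood
#' cells, kidney medulla, retina and the rest of the body) into a molar hourly
#' liver input: 80 g/day of lactate corresponds to 37 mmol/h.
#'
#' @param total_g_per_day whole-body lactate production (g/day).
#' @param molar_mass lactate molar mass (g/mol).
#' @return lactate input rate in mmol/h.
#' @export
lactate_input_rate <- function(total_g_per_day = 80, molar_mass = 90.08) {
  stopifnot(total_g_per_day >= 0, molar_mass > 0)
  total_g_per_day / 24 / molar_mass * 1000
}

#' Adipose tissue blood flow
#'
#' Scales the measured adipose perfusion rate (ml/min per 100 g fat tissue,
#' default 3.5 = midpoint of the 3-4 range) by a subject's fat mass: 15 kg of
#' fat at 3.5 ml/min/100 g gives 31.5 l/h of whole-adipose blood flow.
#'
#' @param fat_mass_kg fat mass in kg.
#' @param flow_ml_min_per_100g perfusion in ml/min per 100 g fat tissue.
#' @return whole-adipose blood flow in l/h.
#' @export
adipose_blood_flow <- function(fat_mass_kg, flow_ml_min_per_100g = 3.5) {
  stopifnot(all(fat_mass_kg >= 0), flow_ml_min_per_100g >= 0)
  fat_mass_kg * 10 * flow_ml_min_per_100g * 60 / 1000
}

#' Adipose fatty-acid and glycerol release
#'
#' Fasting lipolysis releases 1.8 mmol FA/h per kg fat mass; glycerol is
#' released at a 1:3 molar ratio to FA (0.6 mmol/h/kg). Both rates are the
#' amounts delivered to the liver model (about 4\% of the FA is taken up by
#' muscle, which is recorded in the constants but deliberately not subtracted).
#'
#' @param fat_mass_kg fat mass in kg.
#' @param const physiology constants, see [physiology_constants()].
#' @return list with \code{fa_mmol_h} and \code{glycerol_mmol_h}.
#' @export
adipose_fa_glycerol_release <- function(fat_mass_kg,
                                        const = physiology_constants()) {
  stopifnot(all(fat_mass_kg >= 0))
  fa <- const$fa_release_mmol_h_kg * fat_mass_kg
  list(fa_mmol_h = fa, glycerol_mmol_h = fa / const$glycerol_to_fa_ratio)
}

#' Per-amino-acid release from muscle tissue
#'
#' Total fasting muscle AA release is linear in muscle mass
#' (\code{muscle_aa_release_mmol_h_kg}, calibrated so that cohort-mean
#' external AA supply is about 35 g/day) and distributed over amino-acid
#' species by the muscle release profile, in which glutamine + alanine carry
#' 60\% of the molar release.
#'
#' @param muscle_mass_kg muscle mass in kg.
#' @param profiles amino-acid profile table, see [aa_profiles()].
#' @param rate_mmol_h_kg total release per kg muscle (mmol/h/kg).
#' @return named numeric vector of per-AA release rates (mmol/h).
#' @export
muscle_aa_release <- function(muscle_mass_kg, profiles = aa_profiles(),
                              rate_mmol_h_kg =
                                physiology_constants()$muscle_aa_release_mmol_h_kg) {
  stopifnot(muscle_mass_kg >= 0)
  if (abs(sum(profiles$muscle_fraction) - 1) > 1e-8)
    stop("muscle release profile is not normalized")
  r <- muscle_mass_kg * rate_mmol_h_kg * profiles$muscle_fraction
  stats::setNames(r, profiles$aa)
}

#' Per-amino-acid release from adipose tissue
#'
#' Multiplies the adipose veno-arterial AA concentration differences (umol/l)
#' by the subject's whole-adipose blood flow (l/h). Release is linear in fat
#' mass at fixed perfusion per 100 g.
#'
#' @param fat_mass_kg fat mass in kg.
#' @param profiles amino-acid profile table.
#' @param const physiology constants.
#' @return named numeric vector of per-AA release rates (mmol/h).
#' @export
adipose_aa_release <- function(fat_mass_kg, profiles = aa_profiles(),
                               const = physiology_constants()) {
  flow_l_h <- adipose_blood_flow(fat_mass_kg, const$adipose_flow_ml_min_100g)
  r <- profiles$adipose_conc_umol_l * flow_l_h / 1000
  stats::setNames(r, profiles$aa)
}

#' Hepatic autophagy amino-acid input
#'
#' The AA supply from muscle and adipose tissue does not cover the
#' urea-derived hepatic AA demand; the shortfall (about 40-45 g/day at the
#' cohort mean, given a demand of 77.6 g/day) is assumed to come from the
#' liver catabolizing its own protein. The shortfall is distributed across
#' amino acids by the molar AA composition of liver protein, so that the
#' mass-weighted sum of the returned rates equals the shortfall exactly.
#'
#' @param total_aa_demand_g_day urea-derived AA demand (g/day).
#' @param external_supply_g_day muscle + adipose AA supply (g/day).
#' @param profiles amino-acid profile table (liver composition and masses).
#' @return named numeric vector of per-AA autophagy input rates (mmol/h).
#' @export
autophagy_aa_input <- function(total_aa_demand_g_day, external_supply_g_day,
                               profiles = aa_profiles()) {
  stopifnot(total_aa_demand_g_day >= 0, external_supply_g_day >= 0)
  if (external_supply_g_day > total_aa_demand_g_day) {
    warning("external AA supply exceeds demand; autophagy input set to zero")
    return(stats::setNames(rep(0, nrow(profiles)), profiles$aa))
  }
  shortfall <- total_aa_demand_g_day - external_supply_g_day
  # rate_aa = k * ratio_aa with mass closure:
  # sum(rate_aa * molar_mass) * 24 / 1000 = shortfall
  denom <- sum(profiles$liver_molar_ratio * profiles$molar_mass)
  k <- shortfall * 1000 / 24 / denom
  stats::setNames(k * profiles$liver_molar_ratio, profiles$aa)
}

#' Glucose and ketone-body output bounds
#'
#' Returns the fasting-state output constraints that do not depend on body
#' composition beyond weight: a minimum gluconeogenic glucose output of
#' 16.7 mmol/h (3 g/h); glycogen breakdown of 5.5 umol/kg/min scaled by body
#' weight (about 32 mmol/h = 5.77 g glucose/h at 97 kg); and lower bounds of
#' 0.1 mmol/h each on acetoacetate and beta-hydroxybutyrate secretion.
#'
#' @param weight body weight in kg.
#' @param const physiology constants.
#' @return list with \code{gng_min_mmol_h}, \code{glycogenolysis_mmol_h},
#'   \code{glycogenolysis_g_h}, \code{glucose_output_lb_mmol_h} (gng minimum
#'   plus glycogenolysis) and \code{ketone_lb_mmol_h}.
#' @export
glucose_and_ketone_bounds <- function(weight, const = physiology_constants()) {
  stopifnot(weight > 0)
  glyco <- const$glycogenolysis_umol_kg_min * weight * 60 / 1000  # mmol/h
  list(
    gng_min_mmol_h = const$gng_min_mmol_h,
    glycogenolysis_mmol_h = glyco,
    glycogenolysis_g_h = glyco * const$glucose_molar_mass / 1000,
    glucose_output_lb_mmol_h = const$gng_min_mmol_h + glyco,
    ketone_lb_mmol_h = const$ketone_lb_mmol_h
  )
}

#' Construct an exchange-bounds table
#'
#' @param metabolite boundary metabolite ids.
#' @param direction \code{"uptake"} or \code{"secretion"} per entry.
#' @param lower,upper bounds in mmol/h, \code{0 <= lower <= upper}.
#' @return data.frame of class \code{exchange_bounds}.
#' @export
exchange_bounds <- function(metabolite, direction, lower, upper) {
  if (!all(direction %in% c("uptake", "secretion")))
    stop("direction must be 'uptake' or 'secretion'")
  eb <- data.frame(metabolite = as.character(metabolite),
                   direction = direction,
                   lower = as.numeric(lower), upper = as.numeric(upper),
                   stringsAsFactors = FALSE)
  validate_exchange_bounds(eb)
}

validate_exchange_bounds <- function(eb) {
  stopifnot(is.data.frame(eb),
            all(c("metabolite", "direction", "lower", "upper") %in% names(eb)))
  if (any(eb$lower < 0) || any(eb$lower > eb$upper + 1e-12))
    stop("exchange bounds must satisfy 0 <= lower <= upper")
  if (anyDuplicated(paste(eb$metabolite, eb$direction)))
    stop("each metabolite may appear at most once per direction")
  class(eb) <- c("exchange_bounds", "data.frame")
  eb
}

#' Write / read exchange bounds as CSV
#'
#' @param eb an \code{exchange_bounds} table.
#' @param path CSV file path.
#' @return \code{read_exchange_bounds} returns the validated table.
#' @export
write_exchange_bounds <- function(eb, path) {
  utils::write.csv(as.data.frame(eb), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exchange_bounds
#' @export
read_exchange_bounds <- function(path) {
  validate_exchange_bounds(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assemble the personalized exchange bounds of one subject
#'
#' Combines every boundary computation into the complete fasting-state
#' input/output model of one subject's liver:
#' \itemize{
#'   \item per-AA uptake = muscle release + adipose release + autophagy input;
#'   \item lactate uptake at the whole-body production rate;
#'   \item FA and glycerol uptake from adipose lipolysis (fat mass measured,
#'     or imputed from BMI via [fat_mass_from_bmi()] when absent);
#'   \item glycogen mobilization at the weight-scaled glycogenolysis rate and
#'     a glucose output lower bound of gluconeogenesis minimum plus
#'     glycogenolysis;
#'   \item ketone-body secretion lower bounds, a biliary GSH efflux lower
#'     bound, and VLDL-TG and apoB secretion fixed at the subject's measured
#'     rates;
#'   \item free oxygen uptake and free CO2/water/urea secretion; all other
#'     uptakes closed (fasting state).
#' }
#'
#' By default the computed uptake rates are applied as fixed inputs
#' (lower = upper): in the fasting state the adipose and muscle release and
#' the erythrocyte lactate load are delivered to the liver, which must dispose
#' of them. With \code{input_mode = "bound"} they become availability caps
#' (lower = 0) instead.
#'
#' @param subject one-row data.frame or list with at least \code{weight},
#'   \code{bmi}, \code{vldl_tg_secretion}, \code{vldl_apob_secretion};
#'   optionally \code{fat_mass}.
#' @param profiles amino-acid profile table.
#' @param const physiology constants.
#' @param input_mode \code{"fixed"} (default) or \code{"bound"}, see Details.
#' @return an \code{exchange_bounds} table (attribute \code{body} carries the
#'   derived body composition and supply summary).
#' @export
assemble_subject_bounds <- function(subject, profiles = aa_profiles(),
                                    const = physiology_constants(),
                                    input_mode = c("fixed", "bound")) {
  input_mode <- match.arg(input_mode)
  need <- c("weight", "bmi", "vldl_tg_secretion", "vldl_apob_secretion")
  miss <- need[!vapply(need, function(f)
    !is.null(subject[[f]]) && is.finite(subject[[f]]), logical(1))]
  if (length(miss))
    stop("subject is missing mandatory field(s): ", paste(miss, collapse = ", "))
  if (subject$vldl_tg_secretion < 0 || subject$vldl_apob_secretion < 0)
    stop("measured secretion rates must be nonnegative")

  fat <- subject[["fat_mass"]]
  if (is.null(fat) || !is.finite(fat)) fat <- fat_mass_from_bmi(subject$bmi)
  body <- lean_and_muscle_mass(subject$weight, fat)

  musc <- muscle_aa_release(body$muscle_mass, profiles,
                            const$muscle_aa_release_mmol_h_kg)
  adip <- adipose_aa_release(fat, profiles, const)
  g_day <- function(r) sum(r * profiles$molar_mass) * 24 / 1000
  supply_g <- g_day(musc) + g_day(adip)
  auto <- autophagy_aa_input(const$aa_demand_g_day, supply_g, profiles)
  aa_in <- musc + adip + auto

  lip <- adipose_fa_glycerol_release(fat, const)
  lac <- lactate_input_rate(const$lactate_total_g_day, const$lactate_molar_mass)
  out <- glucose_and_ketone_bounds(subject$weight, const)
  big <- const$default_flux_ub

  up_lo <- function(x) if (input_mode == "fixed") x else 0 * x
  uptakes <- data.frame(
    metabolite = c(profiles$aa, "lac", "fa", "glycerol", "glycogen", "o2"),
    direction = "uptake",
    lower = c(up_lo(aa_in), up_lo(lac), up_lo(lip$fa_mmol_h),
              up_lo(lip$glycerol_mmol_h), out$glycogenolysis_mmol_h, 0),
    upper = c(aa_in, lac, lip$fa_mmol_h, lip$glycerol_mmol_h,
              out$glycogenolysis_mmol_h, big),
    stringsAsFactors = FALSE
  )
  secretions <- data.frame(
    metabolite = c("glc", "acac", "bhb", "vldl_tg", "apob", "gsh",
                   "urea", "co2", "h2o"),
    direction = "secretion",
    lower = c(out$glucose_output_lb_mmol_h, out$ketone_lb_mmol_h,
              out$ketone_lb_mmol_h, subject$vldl_tg_secretion,
              subject$vldl_apob_secretion, const$gsh_turnover_lb_mmol_h,
              0, 0, 0),
    upper = c(big, big, big, subject$vldl_tg_secretion,
              subject$vldl_apob_secretion, big, big, big, big),
    stringsAsFactors = FALSE
  )
  eb <- validate_exchange_bounds(rbind(uptakes, secretions))
  attr(eb, "body") <- c(body,
                        list(aa_supply_g_day = supply_g,
                             autophagy_g_day = const$aa_demand_g_day - supply_g))
  eb
}
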