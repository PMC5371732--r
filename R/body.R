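#' Predict fat mass from BMI
#'
#' Linear regression of fat mass on BMI fitted in the subjects with measured
#' body composition, used to impute fat mass where it was not measured:
#' \code{fat mass (kg) = 1.763 * BMI - 26.75}. Negative predictions (BMI below
#' about 15.2) are clipped to zero with a warning.
#'
#' @param bmi body mass index in kg/m^2 (vectorized).
#' @return predicted fat mass in kg.
#' @export
fat_mass_from_bmi <- function(bmi) {
  stopifnot(all(bmi > 0))
  fm <- 1.763 * bmi - 26.75
  if (any(fm < 0)) {
    warning("fat mass prediction negative at BMI below 15.2; clipped to 0")
    fm <- pmax(fm, 0)
  }
  fm
}

#' Derive lean and muscle mass from weight and fat mass
#'
#' Lean mass is body weight minus fat mass; muscle mass follows the
#' anthropometric relationship \code{muscle = 0.63 * lean - 4.1} (clipped at
#' zero for very low lean mass).
#'
#' @param weight body weight in kg.
#' @param fat_mass fat mass in kg; must not exceed weight.
#' @return list with \code{fat_mass}, \code{lean_mass}, \code{muscle_mass} (kg).
#' @export
lean_and_muscle_mass <- function(weight, fat_mass) {
  stopifnot(all(weight > 0), all(fat_mass >= 0))
  if (any(fat_mass > weight))
    stop("fat_mass exceeds body weight")
  lean <- weight - fat_mass
  muscle <- pmax(0.63 * lean - 4.1, 0)
  list(fat_mass = fat_mass, lean_mass = lean, muscle_mass = muscle)
}

#' Estimate body fat percent from BMI, age and sex
#'
#' Deurenberg prediction equation:
#' \code{body fat \% = 1.2 * BMI + 0.23 * age - 10.8 * sex - 5.4}, with sex
#' coded 1 for male and 0 for female.
#'
#' @param bmi body mass index in kg/m^2.
#' @param age age in years.
#' @param sex \code{"male"} or \code{"female"} (vectorized, recycled).
#' @return body fat percentage.
#' @export
body_fat_percent <- function(bmi, age, sex) {
  stopifnot(all(bmi > 0), all(age > 0))
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  g <- ifelse(sex == "male", 1, 0)
  1.2 * bmi + 0.23 * age - 10.8 * g - 5.4
}
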