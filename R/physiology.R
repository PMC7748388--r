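#' Patient demographics record
#'
#' Bundles the demographic and laboratory inputs the dosing calculations
#' need, normalising heights to inches, weights to kg and serum creatinine to
#' mg/dL at construction so that downstream arithmetic never sees mixed
#' units. Fields that a particular calculation does not use (e.g. height for
#' a maintenance dose, weight for a loading dose) may be left `NULL`; each
#' operation checks for what it needs.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (adults; values outside `age_range` trigger a
#'   warning, not an error, since end-stage inputs are clinically real).
#' @param height,height_unit Body height and its unit (`"in"` or `"cm"`).
#' @param weight,weight_unit Actual body weight and its unit (`"kg"` or
#'   `"lb"`).
#' @param scr,scr_unit Serum creatinine and its unit; `"mg_dl"` (default) or
#'   `"umol_l"` (divided by 88.4).
#' @param age_range Plausibility band for age in years; default 18--120.
#' @return An object of class `patient` with fields `sex`, `age`,
#'   `height_in`, `weight_kg`, `scr` (mg/dL).
#' @export
#' @examples
#' patient("male", age = 40, height = 70, weight = 72, scr = 1.0)
patient <- function(sex, age = NULL,
                    height = NULL, height_unit = c("in", "cm"),
                    weight = NULL, weight_unit = c("kg", "lb"),
                    scr = NULL, scr_unit = c("mg_dl", "umol_l"),
                    age_range = c(18, 120)) {
  sex <- match.arg(sex, c("male", "female"))
  scr_unit <- match.arg(scr_unit)
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
    as.numeric(x)
  }
  if (!is.null(age)) {
    age <- check_pos(age, "age")
    if (age < age_range[1] || age > age_range[2]) {
      warning("age ", age, " is outside the adult plausibility band [",
              age_range[1], ", ", age_range[2], "]", call. = FALSE)
    }
  }
  height_in <- if (!is.null(height)) {
    normalize_length(check_pos(height, "height"), match.arg(height_unit))
  }
  weight_kg <- if (!is.null(weight)) {
    normalize_mass(check_pos(weight, "weight"), match.arg(weight_unit))
  }
  if (!is.null(scr)) {
    scr <- check_pos(scr, "scr")
    if (scr_unit == "umol_l") scr <- scr / 88.4
  }
  structure(list(sex = sex, age = age, height_in = height_in,
                 weight_kg = weight_kg, scr = scr),
            class = "patient")
}

#' @export
print.patient <- function(x, ...) {
  cat("Patient:", x$sex,
      if (!is.null(x$age)) paste0(", ", x$age, " y"),
      if (!is.null(x$height_in)) sprintf(", %.1f in", x$height_in),
      if (!is.null(x$weight_kg)) sprintf(", %.1f kg", x$weight_kg),
      if (!is.null(x$scr)) sprintf(", SCr %.2f mg/dL", x$scr),
      "\n", sep = "")
  invisible(x)
}

#' Ideal body weight (Devine formula)
#'
#' IBW (kg) = 50 kg for males (45.5 kg for females) + 2.3 kg per inch of
#' height over 5 feet (60 inches). For heights below 60 inches the linear
#' extrapolation turns negative-sloped and can produce absurd loading doses,
#' so the result is floored at the sex-specific base constant and a warning
#' is emitted.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_in Height in inches (use [normalize_length()] for cm).
#' @return Ideal body weight in kg.
#' @export
#' @examples
#' ideal_body_weight("male", 70)   # 73 kg
#' ideal_body_weight("female", 60) # 45.5 kg
ideal_body_weight <- function(sex, height_in) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(height_in) || length(height_in) != 1L || is.na(height_in) ||
      height_in <= 0) {
    stop("'height_in' must be a single positive number", call. = FALSE)
  }
  base <- if (sex == "male") 50 else 45.5
  if (height_in < 60) {
    warning("height below 60 inches: ideal body weight floored at the ",
            "base constant ", base, " kg", call. = FALSE)
    return(base)
  }
  base + 2.3 * (height_in - 60)
}

#' Creatinine clearance (Cockcroft-Gault)
#'
#' CrCl (mL/min) = (140 - age) x weight / (72 x SCr), multiplied by 0.85 for
#' females. Actual body weight is used, matching a single bedside weight
#' input. For ages at or above 140 years the formula's numerator is
#' non-positive; the result is clamped to 0 mL/min with a warning rather
#' than raising an error.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param weight_kg Actual body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @return Estimated creatinine clearance in mL/min, always >= 0.
#' @export
#' @examples
#' creatinine_clearance("male", 40, 72, 1.0)   # 100 mL/min
#' creatinine_clearance("female", 40, 72, 1.0) # 85 mL/min
creatinine_clearance <- function(sex, age, weight_kg, scr) {
  sex <- match.arg(sex, c("male", "female"))
  for (nm in c("age", "weight_kg", "scr")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  crcl <- (140 - age) * weight_kg / (72 * scr)
  if (sex == "female") crcl <- crcl * 0.85
  if (crcl <= 0) {
    warning("Cockcroft-Gault clearance non-positive at age ", age,
            "; clamped to 0 mL/min", call. = FALSE)
    crcl <- 0
  }
  crcl
}
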