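#' Dose units for colistimethate
#'
#' Intravenous colistimethate doses are labelled in three interchangeable
#' conventions: milligrams of colistin base activity (`"mg_cba"`, North
#' America), million international units (`"miu"`, Europe and elsewhere), and
#' milligrams of colistimethate sodium (`"mg_cms"`, the chemical quantity).
#' The fixed identities used throughout the package are
#' 33.3 mg CBA = 1 million IU = 80 mg CMS. Confusion between these labels is a
#' documented source of serious prescribing error, which is why every
#' user-facing dose in this package is rendered in two units
#' (see [dual_unit_render()]).
#'
#' @return Character vector of the three recognised unit codes.
#' @export
#' @examples
#' dose_units()
dose_units <- function() c("mg_cba", "miu", "mg_cms")

# mg (or MIU) per one million IU; the pivot unit for all conversions
.mg_per_miu <- c(mg_cba = 33.3, miu = 1, mg_cms = 80)

.unit_label <- c(mg_cba = "mg CBA", miu = "million IU", mg_cms = "mg CMS")

#' A drug quantity with an explicit unit
#'
#' Constructs a dose amount: a non-negative quantity tagged with one of the
#' three colistimethate dose-labelling conventions. Keeping the unit attached
#' to the number, rather than implicit in a variable name, is the package's
#' guard against CBA/IU mix-ups.
#'
#' @param value Non-negative numeric scalar, the drug quantity.
#' @param unit One of `dose_units()`: `"mg_cba"`, `"miu"` or `"mg_cms"`.
#' @return An object of class `dose_amount` with fields `value` and `unit`.
#' @seealso [convert_dose()], [dual_unit_render()]
#' @export
#' @examples
#' dose_amount(300, "mg_cba")
#' dose_amount(9, "miu")
dose_amount <- function(value, unit = "mg_cba") {
  unit <- match.arg(unit, dose_units())
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("'value' must be a single non-missing number", call. = FALSE)
  }
  if (value < 0) {
    stop("'value' must be non-negative (got ", value, ")", call. = FALSE)
  }
  structure(list(value = as.numeric(value), unit = unit),
            class = "dose_amount")
}

#' @export
print.dose_amount <- function(x, ...) {
  cat(format(x$value), .unit_label[[x$unit]], "\n")
  invisible(x)
}

#' Convert a dose between CBA, million IU and CMS expressions
#'
#' Converts a [dose_amount()] to another labelling convention using the fixed
#' factors 33.3 mg CBA per 1 million IU and 80 mg CMS per 1 million IU. The
#' conversion is exact on the unrounded value; rounding happens only at
#' display time ([dual_unit_render()]). Converting to the unit the amount is
#' already in returns it unchanged.
#'
#' @param amount A [dose_amount()].
#' @param to Target unit, one of `dose_units()`.
#' @return A `dose_amount` in the target unit.
#' @export
#' @examples
#' convert_dose(dose_amount(1, "miu"), "mg_cba")   # 33.3 mg CBA
#' convert_dose(dose_amount(1, "miu"), "mg_cms")   # 80 mg CMS
#' convert_dose(dose_amount(300, "mg_cba"), "miu") # ~9.01 million IU
convert_dose <- function(amount, to) {
  if (!inherits(amount, "dose_amount")) {
    stop("'amount' must be a dose_amount object", call. = FALSE)
  }
  to <- match.arg(to, dose_units())
  if (amount$unit == to) {
    return(amount)
  }
  miu <- amount$value / .mg_per_miu[[amount$unit]]
  dose_amount(miu * .mg_per_miu[[to]], to)
}

# numeric shortcut used internally: mg CBA -> MIU
.cba_to_miu <- function(mg_cba) mg_cba / .mg_per_miu[["mg_cba"]]

#' Render a dose in both mg CBA and million IU
#'
#' Formats a dose in the two clinically used conventions side by side, e.g.
#' `"300 mg CBA (9.0 million IU)"`. Following the display convention of
#' bedside dosing tools, the mg CBA figure is rounded to the nearest
#' milligram first and the rounded figure is then converted to million IU and
#' shown to one decimal place, so that 300 mg CBA always reads as 9.0 million
#' IU.
#'
#' @param amount A [dose_amount()] in any unit.
#' @return A single character string.
#' @export
#' @examples
#' dual_unit_render(dose_amount(300, "mg_cba"))
#' dual_unit_render(dose_amount(33.3, "mg_cba"))
dual_unit_render <- function(amount) {
  if (!inherits(amount, "dose_amount")) {
    stop("'amount' must be a dose_amount object", call. = FALSE)
  }
  mg_cba <- round(convert_dose(amount, "mg_cba")$value)
  miu <- .cba_to_miu(mg_cba)
  sprintf("%d mg CBA (%.1f million IU)", as.integer(mg_cba), miu)
}

#' Normalise a body height to inches
#'
#' @param height Positive numeric scalar.
#' @param unit `"in"` or `"cm"`; centimetres are divided by 2.54.
#' @return Height in inches.
#' @export
#' @examples
#' normalize_length(152.4, "cm") # 60 inches
normalize_length <- function(height, unit = c("in", "cm")) {
  unit <- match.arg(unit)
  if (!is.numeric(height) || length(height) != 1L || is.na(height) ||
      height <= 0) {
    stop("'height' must be a single positive number", call. = FALSE)
  }
  if (unit == "cm") height / 2.54 else height
}

#' Normalise a body weight to kilograms
#'
#' @param weight Positive numeric scalar.
#' @param unit `"kg"` or `"lb"`; pounds are multiplied by 0.45359237
#'   (the international avoirdupois definition).
#' @return Weight in kg.
#' @export
#' @examples
#' normalize_mass(154, "lb")
normalize_mass <- function(weight, unit = c("kg", "lb")) {
  unit <- match.arg(unit)
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight <= 0) {
    stop("'weight' must be a single positive number", call. = FALSE)
  }
  if (unit == "lb") weight * 0.45359237 else weight
}
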