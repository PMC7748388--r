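#' Target colistin concentration grid
#'
#' The dosing target is the average steady-state plasma concentration of
#' formed colistin (Css,avg, mg/L). The selectable grid runs from 0.5 to
#' 4.0 mg/L in steps of 0.5 mg/L with a default of 2.0 mg/L, a suitable
#' initial target for bloodstream infections when the pathogen's colistin
#' MIC is at most 2 mg/L.
#'
#' @return Numeric vector of the eight allowed Css,avg values.
#' @export
css_grid <- function() seq(0.5, 4, by = 0.5)

#' Validate a target Css,avg value
#'
#' Accepts exactly the eight grid values (see [css_grid()]); anything else is
#' rejected with an error listing the grid. Called with no argument, returns
#' the default target of 2.0 mg/L.
#'
#' @param css Target Css,avg in mg/L.
#' @return The validated Css,avg value.
#' @export
#' @examples
#' validate_css()    # 2.0, the default
#' validate_css(0.5)
validate_css <- function(css = 2.0) {
  grid <- css_grid()
  if (!is.numeric(css) || length(css) != 1L || is.na(css) ||
      !any(abs(css - grid) < 1e-9)) {
    stop("target Css,avg must be one of {", paste(grid, collapse = ", "),
         "} mg/L (got ", deparse(css), ")", call. = FALSE)
  }
  grid[which.min(abs(css - grid))]
}

#' Renal replacement therapy description
#'
#' @param mode `"none"`, `"ihd"` (intermittent hemodialysis), `"sled"`
#'   (sustained low-efficiency dialysis) or `"crrt"` (continuous renal
#'   replacement therapy).
#' @param hours Dialysis session length in hours; must be 0 for `"none"` and
#'   positive for the active modes.
#' @param dialysis_day For IHD only: whether today is a dialysis day. On a
#'   non-dialysis day the supplement is 0 and only the baseline daily dose
#'   applies.
#' @return An object of class `renal_replacement`.
#' @export
#' @examples
#' renal_replacement("ihd", hours = 2, dialysis_day = TRUE)
#' renal_replacement("crrt", hours = 24)
renal_replacement <- function(mode = c("none", "ihd", "sled", "crrt"),
                              hours = 0, dialysis_day = NA) {
  mode <- match.arg(mode)
  if (!is.numeric(hours) || length(hours) != 1L || is.na(hours) || hours < 0) {
    stop("'hours' must be a single non-negative number", call. = FALSE)
  }
  if (mode == "none") {
    if (hours != 0) {
      stop("'hours' must be 0 when mode is \"none\"", call. = FALSE)
    }
    dialysis_day <- FALSE
  } else {
    if (mode == "ihd") {
      if (is.na(dialysis_day)) {
        stop("'dialysis_day' must be TRUE or FALSE for IHD", call. = FALSE)
      }
    } else {
      dialysis_day <- TRUE
    }
    if (hours <= 0 && isTRUE(dialysis_day)) {
      stop("'hours' must be positive for ", toupper(mode),
           " on a dialysis day", call. = FALSE)
    }
  }
  structure(list(mode = mode, hours = as.numeric(hours),
                 dialysis_day = isTRUE(dialysis_day)),
            class = "renal_replacement")
}

#' Maintenance dosing model configuration
#'
#' The maintenance (baseline) daily dose is `css * f(crcl)` where `f` is a
#' renal-function band table expressed in mg CBA per day per mg/L of target
#' Css,avg. The table is configuration data, not code: the engine is
#' agnostic to the coefficients and validates the table at load time.
#'
#' With `interpolate = FALSE` (the default) the table is a step function:
#' `crcl_upper` are strictly increasing exclusive upper bounds and the last
#' bound must be `Inf` so the bands cover CrCl in `[0, Inf)`. With
#' `interpolate = TRUE` the rows are read as `(crcl, rate)` knots of a
#' piecewise-linear function, held constant beyond the outermost knots.
#' In both readings the rate must be non-decreasing in CrCl.
#'
#' @param name Short name for the model.
#' @param bands Data frame with columns `crcl_upper` (mL/min) and
#'   `cba_per_css` (mg CBA/day per mg/L).
#' @param interpolate Logical; band semantics as described above.
#' @param max_daily_cba Safety cap in mg CBA applied to every emitted loading
#'   and daily dose (default 300).
#' @return An object of class `dosing_model`.
#' @seealso [default_dosing_model()], [read_dosing_model()]
#' @export
#' @examples
#' # identity model: baseline = css * crcl
#' m <- dosing_model("identity",
#'                   data.frame(crcl_upper = c(0, 1000),
#'                              cba_per_css = c(0, 1000)),
#'                   interpolate = TRUE)
#' baseline_daily_dose(2, 50, m) # 100
dosing_model <- function(name, bands, interpolate = FALSE,
                         max_daily_cba = 300) {
  bands <- as.data.frame(bands)
  if (!all(c("crcl_upper", "cba_per_css") %in% names(bands)) ||
      nrow(bands) < 1L) {
    stop("dosing model configuration error: 'bands' needs columns ",
         "'crcl_upper' and 'cba_per_css' and at least one row",
         call. = FALSE)
  }
  if (any(is.na(bands$crcl_upper)) || any(is.na(bands$cba_per_css)) ||
      any(bands$cba_per_css < 0)) {
    stop("dosing model configuration error: missing or negative band values",
         call. = FALSE)
  }
  if (any(diff(bands$crcl_upper) <= 0)) {
    stop("dosing model configuration error: 'crcl_upper' must be strictly ",
         "increasing", call. = FALSE)
  }
  if (any(diff(bands$cba_per_css) < 0)) {
    stop("dosing model configuration error: 'cba_per_css' must be ",
         "non-decreasing in CrCl", call. = FALSE)
  }
  if (!interpolate && is.finite(bands$crcl_upper[nrow(bands)])) {
    stop("dosing model configuration error: last 'crcl_upper' must be Inf ",
         "so the bands cover all of [0, Inf)", call. = FALSE)
  }
  if (!is.numeric(max_daily_cba) || length(max_daily_cba) != 1L ||
      is.na(max_daily_cba) || max_daily_cba <= 0) {
    stop("dosing model configuration error: 'max_daily_cba' must be positive",
         call. = FALSE)
  }
  structure(list(name = as.character(name), bands = bands,
                 interpolate = isTRUE(interpolate),
                 max_daily_cba = as.numeric(max_daily_cba)),
            class = "dosing_model")
}

#' @export
print.dosing_model <- function(x, ...) {
  cat("Dosing model '", x$name, "' (",
      if (x$interpolate) "piecewise-linear" else "step function",
      ", cap ", x$max_daily_cba, " mg CBA/day)\n", sep = "")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Read a dosing model from a YAML or JSON file
#'
#' @param path Path to a config file with fields `name`, `interpolate`,
#'   `max_daily_cba` and a `bands` table (list of `crcl_upper` /
#'   `cba_per_css` pairs; `.inf` in YAML for an unbounded top band).
#' @return A validated [dosing_model()].
#' @export
read_dosing_model <- function(path) {
  if (!file.exists(path)) {
    stop("dosing model config not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  bands <- raw$bands
  if (!is.data.frame(bands)) {
    bands <- data.frame(
      crcl_upper = vapply(raw$bands, function(b) as.numeric(b$crcl_upper), 0),
      cba_per_css = vapply(raw$bands, function(b) as.numeric(b$cba_per_css), 0)
    )
  }
  dosing_model(name = raw$name %||% basename(path), bands = bands,
               interpolate = isTRUE(raw$interpolate),
               max_daily_cba = raw$max_daily_cba %||% 300)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged default maintenance dosing model
#'
#' Loads the renal-function band table shipped with the package
#' (`inst/extdata/nation2017_model.yaml`), transcribed from the 2017
#' population-pharmacokinetic dosing guidance for intravenous colistin in
#' critically ill patients (Nation et al., Clin Infect Dis 2017). Values are
#' mg CBA per day per mg/L of target Css,avg; the published table is stated
#' for a 2 mg/L target and scales linearly in the target. Institutions
#' should review the table against the publication before clinical use; the
#' engine itself is agnostic to the coefficients.
#'
#' @return A [dosing_model()].
#' @export
default_dosing_model <- function() {
  read_dosing_model(system.file("extdata", "nation2017_model.yaml",
                                package = "colidose", mustWork = TRUE))
}

# cap text shared by loading and daily recommendations
.cap_warning <- function(max_daily_cba) {
  paste0("Immediate Attention: the calculated dose exceeds the maximum ",
         "recommended ", round(max_daily_cba), " mg CBA (",
         sprintf("%.1f", .cba_to_miu(round(max_daily_cba))),
         " million IU) and has been capped at ", round(max_daily_cba),
         " mg CBA due to safety considerations.")
}

.new_recommendation <- function(kind, uncapped_cba, supplement_cba,
                                max_daily_cba, warnings = character(),
                                notes = character(), extra = list()) {
  capped_cba <- min(uncapped_cba, max_daily_cba)
  capped <- uncapped_cba > max_daily_cba
  if (capped) warnings <- c(.cap_warning(max_daily_cba), warnings)
  rec <- c(list(kind = kind,
                uncapped_cba = uncapped_cba,
                capped_cba = capped_cba,
                supplement_cba = supplement_cba,
                total_cba = capped_cba,
                per_12h_cba = if (kind == "daily") capped_cba / 2 else NA_real_,
                capped = capped,
                max_daily_cba = max_daily_cba,
                rendered = dual_unit_render(dose_amount(capped_cba, "mg_cba")),
                warnings = warnings,
                notes = notes),
           extra)
  structure(rec, class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(if (x$kind == "loading") "Loading dose" else "Daily maintenance dose",
      "recommendation\n")
  if (!is.null(x$crcl)) {
    cat(sprintf("  Creatinine clearance: %.1f mL/min\n", x$crcl))
  }
  if (!is.null(x$baseline_cba)) {
    cat("  Baseline daily dose:  ",
        dual_unit_render(dose_amount(x$baseline_cba, "mg_cba")), "\n",
        sep = "")
    cat("  RRT supplement:       ",
        dual_unit_render(dose_amount(x$supplement_cba, "mg_cba")), "\n",
        sep = "")
  }
  cat("  Recommended dose:     ", x$rendered, "\n", sep = "")
  if (x$kind == "daily") {
    per12 <- round(x$per_12h_cba)
    cat("  Give ", per12, " mg CBA (",
        sprintf("%.1f", .cba_to_miu(per12)),
        " million IU) per 12 h\n", sep = "")
  }
  for (w in x$warnings) cat("  ! ", w, "\n", sep = "")
  for (n in x$notes) cat("  - ", n, "\n", sep = "")
  invisible(x)
}

#' Loading dose of colistimethate
#'
#' CBA (mg) = Css,avg (mg/L) x 2.0 x IBW (kg), where IBW is the Devine ideal
#' body weight. Loading doses above the safety ceiling (default 300 mg CBA,
#' i.e. 9.0 million IU) are capped and flagged with an "Immediate Attention"
#' warning; the uncapped value is retained in the returned record. The first
#' regular daily dose should be administered 12 hours after the loading
#' dose.
#'
#' @param css Target Css,avg in mg/L (validated against [css_grid()]).
#' @param ibw Ideal body weight in kg, from [ideal_body_weight()].
#' @param max_daily_cba Safety cap in mg CBA (default 300).
#' @return A `dose_recommendation` of kind `"loading"`.
#' @export
#' @examples
#' loading_dose(2.0, ideal_body_weight("male", 70)) # 292 mg CBA
loading_dose <- function(css = 2.0, ibw, max_daily_cba = 300) {
  css <- validate_css(css)
  if (!is.numeric(ibw) || length(ibw) != 1L || is.na(ibw) || ibw <= 0) {
    stop("'ibw' must be a single positive number", call. = FALSE)
  }
  .new_recommendation(
    kind = "loading",
    uncapped_cba = css * 2.0 * ibw,
    supplement_cba = 0,
    max_daily_cba = max_daily_cba,
    notes = paste("Administer the first regular daily dose 12 hours after",
                  "the loading dose."),
    extra = list(css = css, ibw = ibw)
  )
}

#' Loading dose for a patient record
#'
#' Convenience wrapper: computes the Devine ideal body weight from the
#' patient's sex and height, then calls [loading_dose()].
#'
#' @param p A [patient()] with `sex` and `height`.
#' @param css Target Css,avg in mg/L.
#' @param max_daily_cba Safety cap in mg CBA.
#' @return A `dose_recommendation` of kind `"loading"`.
#' @export
recommend_loading <- function(p, css = 2.0, max_daily_cba = 300) {
  stopifnot(inherits(p, "patient"))
  if (is.null(p$height_in)) {
    stop("'height' is required for a loading dose", call. = FALSE)
  }
  loading_dose(css, ideal_body_weight(p$sex, p$height_in), max_daily_cba)
}

#' Baseline maintenance daily dose from renal function
#'
#' Returns `css * f(crcl)` in mg CBA per day, where `f` is the model's band
#' table (see [dosing_model()]). This is the pre-cap baseline that dialysis
#' supplements are computed against.
#'
#' @param css Target Css,avg in mg/L (validated).
#' @param crcl Creatinine clearance in mL/min, >= 0.
#' @param model A [dosing_model()]; defaults to [default_dosing_model()].
#' @return Baseline daily dose in mg CBA.
#' @export
baseline_daily_dose <- function(css, crcl, model = default_dosing_model()) {
  css <- validate_css(css)
  stopifnot(inherits(model, "dosing_model"))
  if (!is.numeric(crcl) || length(crcl) != 1L || is.na(crcl) || crcl < 0) {
    stop("'crcl' must be a single non-negative number", call. = FALSE)
  }
  b <- model$bands
  rate <- if (model$interpolate) {
    stats::approx(b$crcl_upper, b$cba_per_css, xout = crcl, rule = 2)$y
  } else {
    b$cba_per_css[which(crcl < b$crcl_upper)[1]]
  }
  css * rate
}

#' Dialysis supplement to the baseline daily dose
#'
#' All three dialysis modalities remove colistimethate, so dialysis sessions
#' require a supplement on top of the baseline daily dose: 10% of the
#' baseline per hour of dialysis. For intermittent hemodialysis this
#' reproduces the published session recommendations (2-hour session: 20% of
#' baseline; 5-hour session: 50%), added after the session ends, and applies
#' only on dialysis days; SLED and CRRT accrue 10% per hour of therapy. IHD
#' session lengths outside 2--5 hours fall outside the published
#' recommendations and trigger a warning.
#'
#' @param baseline Baseline daily dose in mg CBA (>= 0).
#' @param rrt A [renal_replacement()].
#' @return Supplement in mg CBA (0 for no RRT or an IHD non-dialysis day).
#' @export
#' @examples
#' rrt_supplement(200, renal_replacement("ihd", 2, dialysis_day = TRUE)) # 40
#' rrt_supplement(200, renal_replacement("ihd", 5, dialysis_day = TRUE)) # 100
rrt_supplement <- function(baseline, rrt) {
  stopifnot(inherits(rrt, "renal_replacement"))
  if (!is.numeric(baseline) || length(baseline) != 1L || is.na(baseline) ||
      baseline < 0) {
    stop("'baseline' must be a single non-negative number", call. = FALSE)
  }
  if (rrt$mode == "none" || (rrt$mode == "ihd" && !rrt$dialysis_day)) {
    return(0)
  }
  if (rrt$mode == "ihd" && (rrt$hours < 2 || rrt$hours > 5)) {
    warning("IHD session of ", rrt$hours, " h is outside the 2-5 h range ",
            "covered by the published recommendations; supplement computed ",
            "as 10% of baseline per hour", call. = FALSE)
  }
  0.10 * rrt$hours * baseline
}

# mode-specific reminder shown with every daily recommendation
.rrt_notes <- function(rrt) {
  switch(rrt$mode,
    none = character(),
    ihd = if (rrt$dialysis_day) {
      paste("Add the supplemental dose after the dialysis session ends.")
    } else {
      paste("Non-dialysis day: give the baseline daily dose only.")
    },
    sled = paste("During SLED, add 10% of the baseline daily dose per 1 hour",
                 "of dialysis."),
    crrt = paste("During CRRT, add 10% per 1 hour of CRRT to the baseline",
                 "daily dose.")
  )
}

#' Daily maintenance dose recommendation
#'
#' Full maintenance pipeline: Cockcroft-Gault creatinine clearance from the
#' patient's demographics, baseline daily dose from the renal-function band
#' table, dialysis supplement, safety cap, and 12-hourly split. The total
#' (baseline + supplement) is capped at the model's ceiling (default 300 mg
#' CBA) with an "Immediate Attention" warning; the uncapped value is kept in
#' the record. The per-12-h dose is half the capped total; mg figures are
#' rounded to the nearest milligram for display and the rounded figures
#' converted to million IU.
#'
#' @param p A [patient()] with `sex`, `age`, `weight` and `scr`.
#' @param css Target Css,avg in mg/L.
#' @param rrt A [renal_replacement()]; default no RRT.
#' @param model A [dosing_model()]; defaults to [default_dosing_model()].
#' @return A `dose_recommendation` of kind `"daily"` with fields `crcl`,
#'   `baseline_cba`, `supplement_cba`, `uncapped_cba`, `capped_cba`,
#'   `per_12h_cba`, `warnings` and `notes`.
#' @export
#' @examples
#' p <- patient("male", age = 40, weight = 72, scr = 1.0)
#' m <- dosing_model("identity",
#'                   data.frame(crcl_upper = c(0, 1000),
#'                              cba_per_css = c(0, 1000)),
#'                   interpolate = TRUE)
#' daily_recommendation(p, css = 1.0, model = m)
daily_recommendation <- function(p, css = 2.0,
                                 rrt = renal_replacement("none"),
                                 model = default_dosing_model()) {
  stopifnot(inherits(p, "patient"), inherits(rrt, "renal_replacement"))
  for (nm in c("age", "weight_kg", "scr")) {
    if (is.null(p[[nm]])) {
      stop("'", sub("_kg", "", nm), "' is required for a daily dose",
           call. = FALSE)
    }
  }
  css <- validate_css(css)
  crcl <- creatinine_clearance(p$sex, p$age, p$weight_kg, p$scr)
  baseline <- baseline_daily_dose(css, crcl, model)
  supplement <- rrt_supplement(baseline, rrt)
  .new_recommendation(
    kind = "daily",
    uncapped_cba = baseline + supplement,
    supplement_cba = supplement,
    max_daily_cba = model$max_daily_cba,
    notes = c("Give as two divided doses 12 hours apart.", .rrt_notes(rrt)),
    extra = list(css = css, crcl = crcl, baseline_cba = baseline,
                 rrt_mode = rrt$mode, rrt_hours = rrt$hours,
                 dialysis_day = rrt$dialysis_day)
  )
}
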