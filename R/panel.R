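#' Generate a synthetic mock-patient panel
#'
#' Draws reproducible synthetic adult patients for validating the dosing
#' engine against the independent arithmetic oracle ([oracle_dose()]). The
#' default design mirrors the app-validation layout of 8 mock patients with
#' 2 on each renal replacement modality (none / IHD / SLED / CRRT); for
#' other `n` the modality is drawn uniformly. Demographics are sampled
#' uniformly within plausible critically-ill-adult ranges: age 18--90 y,
#' height 55--78 in, weight 40--150 kg, serum creatinine 0.4--8 mg/dL; the
#' target Css,avg is drawn from the 0.5--4 mg/L grid. IHD sessions are 2 or
#' 5 h on a dialysis day, SLED 6--12 h, CRRT 24 h. Panels are deterministic
#' for a fixed seed and every generated patient passes input validation.
#'
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param n Number of patients (>= 1; default 8).
#' @param design `"paper"` for the balanced 2-per-modality layout (requires
#'   `n` divisible by 4) or `"random"`.
#' @return A data frame of class `mock_panel` with one row per patient:
#'   `id`, `sex`, `age`, `height_in`, `weight_kg`, `scr`, `css`, `rrt_mode`,
#'   `rrt_hours`, `dialysis_day`.
#' @export
#' @examples
#' generate_panel(seed = 1)
generate_panel <- function(seed, n = 8, design = c("paper", "random")) {
  design <- match.arg(design)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (design == "paper" && n %% 4L != 0L) {
    stop("the balanced design needs 'n' divisible by 4 (2 per modality at ",
         "n = 8); use design = \"random\" otherwise", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  modes <- if (design == "paper") {
    rep(c("none", "ihd", "sled", "crrt"), each = n %/% 4L)
  } else {
    sample(c("none", "ihd", "sled", "crrt"), n, replace = TRUE)
  }
  hours <- vapply(modes, function(m) {
    switch(m,
           none = 0,
           ihd = sample(c(2, 5), 1L),
           sled = round(stats::runif(1L, 6, 12), 1),
           crrt = 24)
  }, 0)
  panel <- data.frame(
    id = seq_len(n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(stats::runif(n, 18, 90), 1),
    height_in = round(stats::runif(n, 55, 78), 1),
    weight_kg = round(stats::runif(n, 40, 150), 1),
    scr = round(stats::runif(n, 0.4, 8), 2),
    css = sample(css_grid(), n, replace = TRUE),
    rrt_mode = modes,
    rrt_hours = hours,
    dialysis_day = modes != "none",
    stringsAsFactors = FALSE
  )
  attr(panel, "seed") <- as.integer(seed)
  class(panel) <- c("mock_panel", "data.frame")
  panel
}

#' Independent arithmetic oracle for loading and daily doses
#'
#' Recomputes the loading dose and the capped daily total for one panel row
#' as a single straight-line arithmetic pass that shares no code with the
#' dosing engine: Devine ideal body weight, Cockcroft-Gault clearance, band
#' lookup, 10%-per-hour dialysis supplement and safety cap are all written
#' out inline at full precision with no intermediate rounding. Used to
#' reproduce the engine-versus-manual-calculation validation design.
#'
#' @param row One row of a [generate_panel()] data frame (or a list with the
#'   same fields).
#' @param model A [dosing_model()].
#' @return Named numeric vector `c(loading = ..., daily = ...)` in mg CBA.
#' @export
oracle_dose <- function(row, model = default_dosing_model()) {
  stopifnot(inherits(model, "dosing_model"))
  # ideal body weight, floored at the base constant below 60 in
  base <- if (row$sex == "male") 50 else 45.5
  ibw <- base + 2.3 * max(row$height_in - 60, 0)
  loading <- min(row$css * 2.0 * ibw, model$max_daily_cba)

  # Cockcroft-Gault, actual body weight, clamped at zero
  crcl <- (140 - row$age) * row$weight_kg / (72 * row$scr)
  if (row$sex == "female") crcl <- 0.85 * crcl
  crcl <- max(crcl, 0)

  # band table lookup / interpolation
  b <- model$bands
  rate <- if (model$interpolate) {
    if (crcl <= b$crcl_upper[1]) {
      b$cba_per_css[1]
    } else if (crcl >= b$crcl_upper[nrow(b)]) {
      b$cba_per_css[nrow(b)]
    } else {
      i <- max(which(b$crcl_upper <= crcl))
      w <- (crcl - b$crcl_upper[i]) / (b$crcl_upper[i + 1] - b$crcl_upper[i])
      (1 - w) * b$cba_per_css[i] + w * b$cba_per_css[i + 1]
    }
  } else {
    b$cba_per_css[match(TRUE, crcl < b$crcl_upper)]
  }
  baseline <- row$css * rate

  supplement <- if (row$rrt_mode == "none" ||
                    (row$rrt_mode == "ihd" && !isTRUE(row$dialysis_day))) {
    0
  } else {
    0.10 * row$rrt_hours * baseline
  }
  daily <- min(baseline + supplement, model$max_daily_cba)
  c(loading = loading, daily = daily)
}

#' Validate the dosing engine against the independent oracle
#'
#' Runs every panel patient through both the dosing engine
#' ([recommend_loading()], [daily_recommendation()]) and the independent
#' straight-line oracle ([oracle_dose()]) and compares the capped loading
#' and daily totals. Agreement within 0.5 mg CBA (a rounding-level
#' tolerance) counts as a pass.
#'
#' @param panel A [generate_panel()] data frame.
#' @param model A [dosing_model()].
#' @param tol Pass tolerance in mg CBA (default 0.5).
#' @return A data frame with one row per patient (engine and oracle loading
#'   and daily doses and their absolute differences) plus attributes
#'   `all_pass` (logical) and `tol`.
#' @export
#' @examples
#' m <- dosing_model("identity",
#'                   data.frame(crcl_upper = c(0, 1000),
#'                              cba_per_css = c(0, 1000)),
#'                   interpolate = TRUE)
#' run_validation(generate_panel(1), m)
run_validation <- function(panel, model = default_dosing_model(),
                           tol = 0.5) {
  stopifnot(is.data.frame(panel), inherits(model, "dosing_model"))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    row <- as.list(panel[i, , drop = FALSE])
    p <- patient(row$sex, age = row$age, height = row$height_in,
                 weight = row$weight_kg, scr = row$scr)
    rrt <- renal_replacement(row$rrt_mode, hours = row$rrt_hours,
                             dialysis_day = row$dialysis_day)
    eng_loading <- suppressWarnings(
      recommend_loading(p, row$css, model$max_daily_cba))$capped_cba
    eng_daily <- suppressWarnings(
      daily_recommendation(p, row$css, rrt, model))$capped_cba
    ora <- oracle_dose(row, model)
    data.frame(id = row$id,
               engine_loading = eng_loading, oracle_loading = ora[["loading"]],
               engine_daily = eng_daily, oracle_daily = ora[["daily"]],
               diff_loading = abs(eng_loading - ora[["loading"]]),
               diff_daily = abs(eng_daily - ora[["daily"]]))
  })
  out <- do.call(rbind, rows)
  out$pass <- out$diff_loading <= tol & out$diff_daily <= tol
  attr(out, "all_pass") <- all(out$pass)
  attr(out, "tol") <- tol
  out
}
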