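test_that("the Css,avg grid enforces the default, range and step", {
  expect_equal(validate_css(), 2.0)
  for (v in seq(0.5, 4, by = 0.5)) expect_equal(validate_css(v), v)
  expect_error(validate_css(4.5), "0.5")
  expect_error(validate_css(1.25), "mg/L")
  expect_error(validate_css(0), "mg/L")
  expect_error(validate_css(-2))
})

test_that("loading dose is Css,avg x 2.0 x IBW with a 12-h follow-on note", {
  rec <- loading_dose(2.0, ideal_body_weight("male", 70))
  expect_equal(rec$capped_cba, 292)
  expect_false(rec$capped)
  expect_match(paste(rec$notes, collapse = " "), "12 hours after")
  expect_match(rec$rendered, "mg CBA")
  expect_match(rec$rendered, "million IU")
  expect_equal(loading_dose(0.5, 45.5)$capped_cba, 45.5)
  expect_error(loading_dose(2.0, -1), "ibw")
})

test_that("doses above the ceiling are capped with an Immediate Attention warning", {
  # 78-in male at 2 mg/L: IBW 91.4 kg, uncapped 365.6 mg CBA
  rec <- loading_dose(2.0, ideal_body_weight("male", 78))
  expect_equal(rec$uncapped_cba, 365.6)
  expect_equal(rec$capped_cba, 300)
  expect_true(rec$capped)
  expect_match(paste(rec$warnings, collapse = " "), "Immediate Attention")
  expect_match(rec$rendered, "9\\.0 million IU")
  # the cap applies to the post-supplement daily total too
  p <- patient("male", age = 30, weight = 120, scr = 1.0)
  daily <- daily_recommendation(p, css = 2.0,
                                rrt = renal_replacement("crrt", 24),
                                model = identity_model())
  expect_true(daily$uncapped_cba > 300)
  expect_equal(daily$capped_cba, 300)
  expect_match(paste(daily$warnings, collapse = " "), "Immediate Attention")
})

test_that("baseline daily dose follows the configured band table", {
  m <- identity_model()
  expect_equal(baseline_daily_dose(2.0, 50, m), 100)
  # linear in the target concentration by construction
  expect_equal(baseline_daily_dose(2.0, 37, m),
               2 * baseline_daily_dose(1.0, 37, m))
  # step-function semantics: exclusive upper bounds, last band unbounded
  step <- dosing_model("step",
                       data.frame(crcl_upper = c(30, 80, Inf),
                                  cba_per_css = c(10, 20, 30)))
  expect_equal(baseline_daily_dose(1.0, 0, step), 10)
  expect_equal(baseline_daily_dose(1.0, 29.9, step), 10)
  expect_equal(baseline_daily_dose(1.0, 30, step), 20)
  expect_equal(baseline_daily_dose(1.0, 500, step), 30)
  expect_error(baseline_daily_dose(1.0, -1, step), "crcl")
})

test_that("malformed band tables are rejected at configuration load time", {
  expect_error(dosing_model("bad", data.frame(crcl_upper = c(30, 20, Inf),
                                              cba_per_css = c(1, 2, 3))),
               "increasing")
  expect_error(dosing_model("bad", data.frame(crcl_upper = c(30, Inf),
                                              cba_per_css = c(5, 2))),
               "non-decreasing")
  expect_error(dosing_model("bad", data.frame(crcl_upper = c(30, 90),
                                              cba_per_css = c(1, 2))),
               "Inf")
  expect_error(dosing_model("bad", data.frame(crcl_upper = Inf,
                                              cba_per_css = 1),
                            max_daily_cba = 0), "max_daily_cba")
})

test_that("the packaged default model loads, is monotone and covers all CrCl", {
  m <- default_dosing_model()
  expect_s3_class(m, "dosing_model")
  expect_equal(m$max_daily_cba, 300)
  expect_true(all(diff(m$bands$cba_per_css) >= 0))
  expect_equal(m$bands$crcl_upper[nrow(m$bands)], Inf)
  # doses at a 2 mg/L target rise with renal function
  doses <- vapply(c(0, 15, 45, 75, 120),
                  function(cc) baseline_daily_dose(2, cc, m), 0)
  expect_true(all(diff(doses) > 0))
})

test_that("dialysis supplements reproduce the published percentages exactly", {
  ihd2 <- renal_replacement("ihd", 2, dialysis_day = TRUE)
  ihd5 <- renal_replacement("ihd", 5, dialysis_day = TRUE)
  for (b in c(1, 73.5, 200, 1234)) {
    expect_equal(rrt_supplement(b, ihd2) / b, 0.20)
    expect_equal(rrt_supplement(b, ihd5) / b, 0.50)
    # SLED/CRRT: 10% of baseline per hour, linear in session length
    for (h in c(1, 6, 10.5, 24)) {
      expect_equal(rrt_supplement(b, renal_replacement("crrt", h)) / b,
                   0.10 * h)
      expect_equal(rrt_supplement(b, renal_replacement("sled", h)) / b,
                   0.10 * h)
    }
  }
  # no supplement without RRT or on an IHD non-dialysis day
  expect_equal(rrt_supplement(200, renal_replacement("none")), 0)
  expect_equal(rrt_supplement(200, renal_replacement("ihd", 2,
                                                     dialysis_day = FALSE)),
               0)
  # IHD sessions outside the published 2-5 h window warn but stay on 10%/h
  expect_warning(
    s <- rrt_supplement(200, renal_replacement("ihd", 6, dialysis_day = TRUE)),
    "2-5"
  )
  expect_equal(s, 120)
  expect_error(renal_replacement("ihd", -1, dialysis_day = TRUE), "hours")
})

test_that("daily recommendation composes clearance, bands, supplement and split", {
  # male 65 y, 72 kg, SCr 1.0 -> CrCl 75; identity model at 2 mg/L -> 150/day
  p <- patient("male", age = 65, weight = 72, scr = 1.0)
  rec <- daily_recommendation(p, css = 2.0, model = identity_model())
  expect_equal(rec$crcl, 75)
  expect_equal(rec$baseline_cba, 150)
  expect_equal(rec$supplement_cba, 0)
  expect_equal(rec$capped_cba, 150)
  expect_equal(rec$per_12h_cba, 75)
  expect_output(print(rec), "75 mg CBA")
  expect_output(print(rec), "million IU")

  # with a 5-h IHD session on a dialysis day the supplement is 50%
  rec_ihd <- daily_recommendation(p, css = 2.0,
                                  rrt = renal_replacement("ihd", 5,
                                                          dialysis_day = TRUE),
                                  model = identity_model())
  expect_equal(rec_ihd$supplement_cba, 75)
  expect_equal(rec_ihd$uncapped_cba, 225)
  expect_match(paste(rec_ihd$notes, collapse = " "), "after the dialysis")

  # CRRT attaches the verbatim bedside reminder
  rec_crrt <- daily_recommendation(p, css = 1.0,
                                   rrt = renal_replacement("crrt", 10),
                                   model = identity_model())
  expect_match(paste(rec_crrt$notes, collapse = " "),
               "During CRRT, add 10% per 1 hour of CRRT to the baseline daily dose",
               fixed = TRUE)
  # per-12h is always half the capped total
  for (r in list(rec, rec_ihd, rec_crrt)) {
    expect_equal(r$per_12h_cba * 2, r$capped_cba)
  }
  expect_error(daily_recommendation(patient("male", age = 40), css = 2.0),
               "weight")
})

test_that("doses are monotone in target, renal function and session length", {
  m <- identity_model(max_daily_cba = Inf)
  p <- function(scr) patient("male", age = 40, weight = 72, scr = scr)
  # non-decreasing in css
  totals_css <- vapply(css_grid(), function(cs)
    daily_recommendation(p(1.0), cs, model = m)$capped_cba, 0)
  expect_true(all(diff(totals_css) >= 0))
  # non-decreasing in crcl (lower scr -> higher crcl)
  totals_crcl <- vapply(c(4, 2, 1, 0.5), function(s)
    daily_recommendation(p(s), 2, model = m)$capped_cba, 0)
  expect_true(all(diff(totals_crcl) >= 0))
  # non-decreasing in session hours
  totals_h <- vapply(c(1, 4, 12, 24), function(h)
    daily_recommendation(p(1.0), 2, renal_replacement("crrt", h), m)$capped_cba,
    0)
  expect_true(all(diff(totals_h) >= 0))
  # loading dose non-decreasing in css and ibw
  expect_true(all(diff(vapply(css_grid(), function(cs)
    loading_dose(cs, 70, max_daily_cba = Inf)$capped_cba, 0)) >= 0))
})
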