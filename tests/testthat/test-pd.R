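test_that("fraction of time above handles the edge regimes", {
  const <- concentration_profile(seq(0, 72, by = 1), rep(10, 73))
  expect_equal(fraction_time_above(const, 8), 1.0)
  expect_equal(fraction_time_above(const, 10), 1.0)  # ties count as above
  expect_equal(fraction_time_above(const, 10.5), 0.0)
  # mono-exponential decay from 16 mg/L at ke = 0.1/h crosses 8 mg/L at
  # ln(2)/0.1 = 6.931 h -> fraction 6.931/72 = 0.09627
  tt <- seq(0, 72, by = 0.01)
  dec <- concentration_profile(tt, 16 * exp(-0.1 * tt))
  expect_equal(fraction_time_above(dec, 8), log(2) / 0.1 / 72,
               tolerance = 1e-4)
  expect_equal(fraction_time_above(dec, 20), 0.0)
  expect_error(fraction_time_above(const, 0), "threshold")
  expect_error(fraction_time_above(const, 8, window = c(-1, 80)), "window")
})

test_that("analytic time-above agrees with the brute-force grid oracle", {
  set.seed(44)
  worst <- 0
  for (i in 1:100) {
    p <- make_patient(runif(1, 10, 60), runif(1, 0.01, 0.5),
                      free_fraction = runif(1, 0.3, 1))
    reg <- dose_regimen(runif(1, 250, 4000), sample(c(6, 8, 12, 24), 1),
                        0.5, 72)
    pr <- conc_profile(p, reg, grid_step = 9)   # sparse; analytic path
    cmax <- max(pr$free_conc)
    thr <- runif(1, 0.05, 1.2) * cmax
    if (thr <= 0) next
    a <- fraction_time_above(pr, thr)
    o <- grid_fraction_above(pr, thr, dt = 1e-3)
    worst <- max(worst, abs(a - o))
  }
  expect_lt(worst, 1e-4)
})

test_that("window arithmetic matches between analytic and grid paths", {
  p <- make_patient(30, 0.15, 0.8)
  reg <- dose_regimen(1000, 12, 0.5, 72)
  pr <- conc_profile(p, reg, grid_step = 0.01)
  raw <- concentration_profile(pr$time, pr$total_conc, pr$free_conc)
  for (w in list(c(0, 72), c(0.5, 72), c(10, 30), c(3.7, 64.2))) {
    expect_equal(fraction_time_above(pr, 5, window = w),
                 fraction_time_above(raw, 5, window = w),
                 tolerance = 1e-5, label = paste(w, collapse = "-"))
  }
})

test_that("target evaluation applies the percent-time thresholds", {
  # meropenem needs 40% fT >= 1xMIC: a fraction of 0.41 attains;
  # piperacillin needs 50%: the same fraction fails
  mero <- scn$drugs$meropenem
  pip <- scn$drugs$piperacillin
  # engineered patient: free conc above 2 mg/L for ~41% of 72 h
  # decay from free 20 at ke such that crossing happens at 0.41*72 h
  ke <- log(20 / 2) / (0.41 * 72)
  p <- make_patient(vd_total = 20, ke = ke, free_fraction = 1)
  # single bolus-like dose: short infusion, peak free = dose/vd = 20
  reg <- dose_regimen(400, 72, 0.05, 72)
  pr <- conc_profile(p, reg)
  rec_m <- evaluate_targets(pr, mero)
  expect_gt(rec_m$fraction_pct_above_1xMIC, 0.40)
  expect_lt(rec_m$fraction_pct_above_1xMIC, 0.42)
  expect_true(rec_m$attain_pct_above_1xMIC)
  rec_p <- evaluate_targets(pr, pip, targets = pd_targets(pip, mic = 2))
  expect_false(rec_p$attain_pct_above_1xMIC)
})

test_that("always-above is independent of the 4xMIC percent target", {
  # steady profile sitting between MIC and 4xMIC: always_above holds while
  # the 4xMIC fraction is ~0
  mero <- scn$drugs$meropenem
  # slow single-dose decay pinned between MIC (2) and 4xMIC (8): peak ~6,
  # 72-h trough ~2.9
  p <- make_patient(vd_total = 20, ke = 0.01, free_fraction = 1)
  reg <- dose_regimen(120, 72, 0.5, 72)
  pr <- conc_profile(p, reg)
  rec <- evaluate_targets(pr, mero)
  expect_true(rec$always_above)
  expect_true(rec$attain_always_above_1xMIC)
  expect_equal(rec$fraction_pct_above_4xMIC, 0)
  expect_false(rec$attain_pct_above_4xMIC)
})

test_that("attainment dominance invariants hold across a full cohort run", {
  for (case in list(list(d = "cefepime", a = "less_intensive",
                         dose = 2000, tau = 12),
                    list(d = "imipenem", a = "intensive",
                         dose = 1000, tau = 8),
                    list(d = "ertapenem", a = "intensive",
                         dose = 1000, tau = 24))) {
    drug <- scn$drugs[[case$d]]
    co <- generate_cohort(drug, scn$arms[[case$a]], 2000, seed = 55)
    att <- cohort_attainment(co, dose_regimen(case$dose, case$tau, 0.5, 72),
                             drug)
    expect_true(all(att$fraction_pct_above_4xMIC <=
                      att$fraction_pct_above_1xMIC + 1e-12), label = case$d)
    expect_true(all(att$fraction_pct_above_1xMIC >= 0 &
                      att$fraction_pct_above_1xMIC <= 1), label = case$d)
    expect_true(all(!att$attain_pct_above_4xMIC |
                      att$attain_pct_above_1xMIC), label = case$d)
    expect_true(all(!att$always_above | att$attain_pct_above_1xMIC),
                label = case$d)
  }
})

test_that("cohort engine equals the per-patient profile path", {
  drug <- scn$drugs$piperacillin
  co <- generate_cohort(drug, scn$arms$less_intensive, 40, seed = 66)
  reg <- dose_regimen(4000, 6, 0.5, 72)
  att <- cohort_attainment(co, reg, drug)
  for (i in c(1, 7, 23, 40)) {
    rec <- evaluate_targets(conc_profile(co[i, ], reg), drug)
    expect_equal(att$fraction_pct_above_1xMIC[i],
                 rec$fraction_pct_above_1xMIC, tolerance = 1e-12)
    expect_equal(att$fraction_pct_above_4xMIC[i],
                 rec$fraction_pct_above_4xMIC, tolerance = 1e-12)
    expect_identical(att$always_above[i], rec$always_above)
  }
})

test_that("trough-based always-above mode is at least as strict on troughs", {
  drug <- scn$drugs$meropenem
  co <- generate_cohort(drug, scn$arms$less_intensive, 1000, seed = 77)
  reg <- dose_regimen(500, 12, 0.5, 72)
  win <- cohort_attainment(co, reg, drug,
                           always_above_mode = "post_first_infusion")
  tro <- cohort_attainment(co, reg, drug, always_above_mode = "troughs")
  # the window mode also checks the end of the first infusion, so it can
  # only fail more patients than the troughs-only reading
  expect_true(all(tro$always_above >= win$always_above))
})
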