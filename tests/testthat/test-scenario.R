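test_that("packaged scenario carries the study parameter table digit-for-digit", {
  expect_s3_class(scn, "crrt_scenario")
  expect_setequal(names(scn$drugs),
                  c("cefepime", "ceftazidime", "ertapenem", "imipenem",
                    "meropenem", "piperacillin", "tazobactam"))
  expect_setequal(names(scn$arms), c("less_intensive", "intensive"))

  # mean, sd, lower, upper per drug and field
  expected <- list(
    cefepime = list(vd_per_kg = c(0.48, 0.24, 0.16, 1.11),
                    free_fraction = c(0.79, 0.09, 0.72, 0.85),
                    cl_nr = c(24.33, 11.25, 13, 44),
                    sieving = c(0.67, 0.13, 0, 1)),
    ceftazidime = list(vd_per_kg = c(0.34, 0.20, 0.13, 1.1),
                       free_fraction = c(0.86, 0.05, 0.75, 0.94),
                       cl_nr = c(15.9, 9.9, 8, 37.7),
                       sieving = c(0.85, 0.05, 0, 1)),
    ertapenem = list(vd_per_kg = c(0.19, 0.07, 0.13, 0.34),
                     free_fraction = c(0.25, 0.45, 0, 1),
                     cl_nr = c(11, 3, 10, 19),
                     sieving = c(0.2, 0.06, 0, 1)),
    imipenem = list(vd_per_kg = c(0.34, 0.1, 0.21, 0.63),
                    free_fraction = c(0.8, 0.16, 0, 1),
                    cl_nr = c(100.5, 28, 53, 160),
                    sieving = c(0.57, 0.1, 0, 1)),
    meropenem = list(vd_per_kg = c(0.41, 0.18, 0.08, 1.07),
                     free_fraction = c(0.79, 0.09, 0, 1),
                     cl_nr = c(54.9, 49, 0, 251),
                     sieving = c(0.63, 0.13, 0, 1)),
    piperacillin = list(vd_per_kg = c(0.40, 0.21, 0, 1.11),
                        free_fraction = c(0.76, 0.2, 0, 1),
                        cl_nr = c(48.5, 37, 0, 187),
                        sieving = c(0.6, 0.28, 0, 1)),
    tazobactam = list(vd_per_kg = c(0.50, 0.37, 0, 2.13),
                      free_fraction = c(0.74, 0.27, 0, 1),
                      cl_nr = c(40.4, 70, 0, 381),
                      sieving = c(0.8, 0.36, 0, 1)))
  for (dn in names(expected)) {
    for (fn in names(expected[[dn]])) {
      spec <- scn$drugs[[dn]][[fn]]
      expect_identical(c(spec$mean, spec$sd, spec$lower, spec$upper),
                       expected[[dn]][[fn]],
                       label = paste(dn, fn))
    }
  }
  r2vd <- c(cefepime = 0.4197, ceftazidime = 0.0237, ertapenem = 0.3318,
            imipenem = 0.17, meropenem = 0.1435, piperacillin = 0.0567,
            tazobactam = 0.0049)
  r2cl <- c(cefepime = 0.038, ceftazidime = 0.1254, ertapenem = 0.1156,
            imipenem = 0.013, meropenem = 0.0072, piperacillin = 0.036,
            tazobactam = 0.0098)
  for (dn in names(r2vd)) {
    expect_identical(scn$drugs[[dn]]$vd_per_kg$r2_weight, unname(r2vd[dn]),
                     label = paste(dn, "r2 vd"))
    expect_identical(scn$drugs[[dn]]$cl_nr$r2_weight, unname(r2cl[dn]),
                     label = paste(dn, "r2 cl_nr"))
  }

  li <- scn$arms$less_intensive
  expect_identical(c(li$weight$mean, li$weight$sd, li$weight$lower,
                     li$weight$upper), c(84.1, 18.9, 40, Inf))
  expect_identical(c(li$effluent_rate$mean, li$effluent_rate$sd,
                     li$effluent_rate$lower, li$effluent_rate$upper),
                   c(22, 6.1, 0, 47.5))
  expect_identical(c(li$delivered_fraction$mean, li$delivered_fraction$sd),
                   c(0.95, 0.35))
  int <- scn$arms$intensive
  expect_identical(c(int$weight$mean, int$weight$sd), c(84.1, 19.6))
  expect_identical(c(int$effluent_rate$mean, int$effluent_rate$sd,
                     int$effluent_rate$lower, int$effluent_rate$upper),
                   c(35.8, 6.4, 0, 47.5))
  expect_identical(c(int$delivered_fraction$mean,
                     int$delivered_fraction$sd), c(0.89, 0.39))

  # breakpoints and %T thresholds
  mics <- c(cefepime = 8, ceftazidime = 8, piperacillin = 16,
            tazobactam = 4, meropenem = 2, imipenem = 2, ertapenem = 1)
  pct <- c(cefepime = 60, ceftazidime = 60, piperacillin = 50,
           tazobactam = 50, meropenem = 40, imipenem = 40, ertapenem = 40)
  for (dn in names(mics)) {
    expect_identical(scn$drugs[[dn]]$mic, unname(mics[dn]))
    expect_identical(scn$drugs[[dn]]$pct_time_threshold, unname(pct[dn]))
  }
})

test_that("parameter invariant violations raise errors naming the field", {
  expect_error(param_spec(5, 1, lower = 2, upper = 1), "lower")
  expect_error(param_spec(5, -1), "sd")
  expect_error(param_spec(5, 1, lower = 6, upper = 10), "mean")
  expect_error(param_spec(5, 1, r2_weight = 1.5), "r2_weight")
  expect_error(drug_model("x", param_spec(0.4, 0.1), param_spec(0.8, 0.1,
               upper = 1), param_spec(20, 5), param_spec(0.6, 0.1,
               upper = 1), mic = -1, pct_time_threshold = 50), "mic")
  expect_error(dose_regimen(1000, 12, infusion_duration = 13),
               "infusion_duration")
  expect_error(pd_target("pct_above_1xMIC", 2, 1.5), "required_fraction")
})

test_that("scenario round-trips through YAML identically", {
  path <- tempfile(fileext = ".yaml")
  write_scenario(scn, path)
  again <- load_scenario(path)
  expect_equal(again, scn)
})

test_that("loading a scenario with violated bounds names the offending field", {
  raw <- yaml::read_yaml(system.file("extdata", "atn_trial.yaml",
                                     package = "crrtpta"))
  raw$drugs$cefepime$vd_per_kg$lower <- 2   # above upper bound 1.11
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, bad)
  expect_error(load_scenario(bad), "cefepime\\$vd_per_kg")
  raw2 <- yaml::read_yaml(system.file("extdata", "atn_trial.yaml",
                                      package = "crrtpta"))
  raw2$regimens[[1]]$drug <- "nosuchdrug"
  bad2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw2, bad2)
  expect_error(load_scenario(bad2), "unknown drug")
})

test_that("regimen enumeration matches the study's printed regimen rows", {
  regs <- enumerate_paper_regimens(scn)
  expect_equal(nrow(regs), 29L)
  counts <- table(regs$drug)
  expect_equal(unname(counts[c("cefepime", "ceftazidime", "piperacillin",
                               "tazobactam", "ertapenem", "imipenem",
                               "meropenem")]),
               c(4L, 2L, 6L, 6L, 2L, 4L, 5L), ignore_attr = TRUE)
  expect_true(any(regs$drug == "meropenem" & regs$dose_mg == 2000 &
                    regs$interval_h == 12))
  expect_true(any(regs$drug == "tazobactam" & regs$dose_mg == 375 &
                    regs$interval_h == 6))
  # ertapenem appears once per breakpoint variant
  ert <- regs[regs$drug == "ertapenem", ]
  expect_equal(sort(ert$mic_mg_l), c(1, 2))
  expect_true(all(ert$dose_mg == 1000 & ert$interval_h == 24))
})
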