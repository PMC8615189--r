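# Shared fixtures and independent oracles for the test suite.

scn <- default_scenario()

# a bare patient record (enough for the PK/PD functions)
make_patient <- function(vd_total, ke, free_fraction = 1) {
  structure(data.frame(vd_total = vd_total, ke = ke,
                       cl_total = ke * vd_total,
                       free_fraction = free_fraction),
            class = c("cohort", "data.frame"))
}

# wrap a plain data frame of patients as a cohort
as_cohort <- function(df, drug = "synthetic", arm = "synthetic", seed = 0L) {
  attr(df, "drug") <- drug
  attr(df, "arm") <- arm
  attr(df, "n") <- nrow(df)
  attr(df, "seed") <- seed
  class(df) <- c("cohort", "data.frame")
  df
}

# Independent ODE oracle: integrate dC/dt = rate(t)/V - ke C segment by
# segment with deSolve (discontinuities at infusion starts/ends handled by
# restarting the solver), returning total concentration at `times`.
ode_conc <- function(vd_total, ke, regimen, times) {
  nd <- ceiling(regimen$horizon / regimen$interval - 1e-9)
  starts <- regimen$interval * (seq_len(nd) - 1)
  bounds <- sort(unique(c(0, starts, starts + regimen$infusion_duration,
                          regimen$horizon, times)))
  bounds <- bounds[bounds <= regimen$horizon + 1e-12]
  bounds <- bounds[c(TRUE, diff(bounds) > 1e-9)]
  R0 <- regimen$dose / regimen$infusion_duration
  c0 <- 0
  out <- c(0)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    infusing <- any(a >= starts - 1e-12 &
                      a < starts + regimen$infusion_duration - 1e-12)
    rate <- if (infusing) R0 else 0
    sol <- deSolve::ode(
      y = c(C = c0), times = c(a, b),
      func = function(t, y, p) list(rate / vd_total - ke * y[1]),
      parms = NULL, rtol = 1e-11, atol = 1e-12)
    c0 <- unname(sol[nrow(sol), 2])
    out <- c(out, c0)
  }
  stats::approx(bounds, out, xout = times)$y
}

# Brute-force grid oracle for time-above: dense sampling of the analytic
# concentrations with linear-interpolated crossings (independent of the
# closed-form crossing solver under test).
grid_fraction_above <- function(profile, threshold, dt = 1e-3) {
  reg <- attr(profile, "regimen")
  pk <- attr(profile, "pk")
  dense <- conc_profile(make_patient(pk$vd_total, pk$ke, pk$free_fraction),
                        reg, grid_step = dt)
  raw <- concentration_profile(dense$time, dense$total_conc,
                               dense$free_conc)
  fraction_time_above(raw, threshold)
}

# Truncated log-normal moments by numerical integration (oracle for the
# rejection sampler under heavy truncation).
trunc_lnorm_moments <- function(spec) {
  s2 <- log1p((spec$sd / spec$mean)^2)
  sigma <- sqrt(s2)
  mu <- log(spec$mean) - s2 / 2
  p <- stats::plnorm(spec$upper, mu, sigma) -
    stats::plnorm(spec$lower, mu, sigma)
  m1 <- stats::integrate(function(x) x * stats::dlnorm(x, mu, sigma),
                         spec$lower, spec$upper, rel.tol = 1e-10)$value / p
  m2 <- stats::integrate(function(x) x^2 * stats::dlnorm(x, mu, sigma),
                         spec$lower, spec$upper, rel.tol = 1e-10)$value / p
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}
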