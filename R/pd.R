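# Time above threshold within one monotone infusion segment
# C(t) = Css + (C0 - Css) exp(-ke t) for ke > 0, C0 + R0/V t for ke = 0.
# All arguments are per-patient vectors except dur (scalar, h).
.seg_above_infusion <- function(C0, C1, dur, ke, Css, R0_over_V, thr) {
  res <- numeric(length(C0))
  hi <- C0 >= thr & C1 >= thr
  res[hi] <- dur
  cr <- (C0 >= thr) != (C1 >= thr)
  if (any(cr)) {
    kz <- ke < 1e-12
    t_cross <- numeric(length(C0))
    i <- cr & !kz
    t_cross[i] <- log((C0[i] - Css[i]) / (thr[i] - Css[i])) / ke[i]
    j <- cr & kz
    t_cross[j] <- (thr[j] - C0[j]) / R0_over_V[j]
    rising <- cr & C1 >= thr
    res[rising] <- dur - t_cross[rising]
    falling <- cr & C0 >= thr
    res[falling] <- t_cross[falling]
  }
  pmin(pmax(res, 0), dur)
}

# Time above threshold within one decay segment C(t) = C0 exp(-ke t).
.seg_above_decay <- function(C0, dur, ke, thr) {
  res <- numeric(length(C0))
  above <- C0 >= thr
  kz <- ke < 1e-12
  res[above & kz] <- dur
  i <- above & !kz
  res[i] <- pmin(dur, log(C0[i] / thr[i]) / ke[i])
  res
}

# Vectorized attainment engine. Walks the 2 x n_dose monotone segments of
# the multiple-dose profile once per cohort, accumulating exact time above
# each total-concentration threshold (closed-form crossing times) and the
# running minima used by the always-above target. thr_total: list of
# per-patient total-concentration threshold vectors.
.attainment_engine <- function(ke, vd_total, cl_total, dose, interval, tinf,
                               horizon, thr_total) {
  npat <- length(ke)
  R0 <- dose / tinf
  R0_over_V <- rep(R0, npat) / vd_total
  kz <- ke < 1e-12
  Css <- ifelse(kz, Inf, R0 / cl_total)
  n_dose <- length(.dose_times(dose_regimen(dose, interval, tinf, horizon)))
  n_thr <- length(thr_total)
  time_above <- matrix(0, npat, n_thr)
  C <- numeric(npat)
  min_window <- rep(Inf, npat)   # from end of first infusion to horizon
  min_trough <- rep(Inf, npat)   # pre-dose troughs + horizon
  for (k in seq_len(n_dose)) {
    t0 <- (k - 1) * interval
    idur <- min(tinf, horizon - t0)
    ddur <- min(interval, horizon - t0) - idur
    C1 <- ifelse(kz, C + R0_over_V * idur, Css + (C - Css) * exp(-ke * idur))
    for (j in seq_len(n_thr))
      time_above[, j] <- time_above[, j] +
        .seg_above_infusion(C, C1, idur, ke, Css, R0_over_V, thr_total[[j]])
    C2 <- ifelse(kz, C1, C1 * exp(-ke * ddur))
    if (ddur > 0)
      for (j in seq_len(n_thr))
        time_above[, j] <- time_above[, j] +
          .seg_above_decay(C1, ddur, ke, thr_total[[j]])
    min_window <- pmin(min_window, C1, C2)
    if (k < n_dose) min_trough <- pmin(min_trough, C2)
    C <- C2
  }
  min_trough <- pmin(min_trough, C)
  list(fraction = time_above / horizon, min_window = min_window,
       min_trough = min_trough)
}

# fraction of [window] with free concentration >= threshold, computed on a
# grid profile by linear interpolation of threshold crossings
.fraction_above_grid <- function(times, free, threshold, window) {
  f_at <- stats::approx(times, free, xout = window, rule = 2)$y
  keep <- times > window[1] & times < window[2]
  t <- c(window[1], times[keep], window[2])
  y <- c(f_at[1], free[keep], f_at[2])
  m <- length(t)
  above <- y >= threshold
  dt <- diff(t)
  a0 <- above[-m]; a1 <- above[-1L]
  total <- sum(dt[a0 & a1])
  cross <- which(a0 != a1)
  if (length(cross)) {
    tc <- t[cross] + dt[cross] * (threshold - y[cross]) /
      (y[cross + 1L] - y[cross])
    total <- total + sum(ifelse(above[cross], tc - t[cross],
                                t[cross + 1L] - tc))
  }
  total / diff(window)
}

#' Fraction of time the free concentration is at or above a threshold
#'
#' For profiles produced by [conc_profile()] the computation is exact:
#' within each monotone segment (infusion or decay) the threshold crossing
#' time is solved in closed form. For raw profiles
#' ([concentration_profile()]) crossings are located by linear
#' interpolation between grid points. `free_conc >= threshold` counts as
#' above (ties matter only for degenerate flat profiles).
#'
#' @param profile A `conc_profile`.
#' @param threshold Free-concentration threshold, mg/L (> 0).
#' @param window Evaluation window `c(t_start, t_end)` in h; defaults to
#'   the full profile span.
#' @return Fraction in `[0, 1]`.
#' @examples
#' p <- concentration_profile(0:72, rep(10, 73))
#' fraction_time_above(p, 8)  # 1
#' @export
fraction_time_above <- function(profile, threshold, window = NULL) {
  stopifnot(inherits(profile, "conc_profile"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold: must be > 0", call. = FALSE)
  span <- range(profile$time)
  if (is.null(window)) window <- span
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9 ||
      window[1] >= window[2])
    stop("window: must be an increasing interval within the profile span",
         call. = FALSE)
  pk <- attr(profile, "pk")
  reg <- attr(profile, "regimen")
  if (is.null(pk) || is.null(reg))
    return(.fraction_above_grid(profile$time, profile$free_conc,
                                threshold, window))
  # analytic path: walk monotone sub-segments clipped to the window
  thr_tot <- threshold / pk$free_fraction
  starts <- .dose_times(reg)
  bounds <- sort(unique(c(window,
                          pmin(pmax(c(starts, starts + reg$infusion_duration),
                                    window[1]), window[2]))))
  R0 <- reg$dose / reg$infusion_duration
  cl <- pk$ke * pk$vd_total
  css <- if (pk$ke > 1e-12) R0 / cl else Inf
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (b - a < 1e-12) next
    Ca <- .conc_at(a, reg$dose, reg$infusion_duration, reg$interval,
                   reg$horizon, pk$vd_total, pk$ke)
    Cb <- .conc_at(b, reg$dose, reg$infusion_duration, reg$interval,
                   reg$horizon, pk$vd_total, pk$ke)
    infusing <- any(a >= starts - 1e-12 &
                      a < starts + reg$infusion_duration - 1e-12)
    total <- total + if (infusing)
      .seg_above_infusion(Ca, Cb, b - a, pk$ke, css, R0 / pk$vd_total,
                          thr_tot)
    else .seg_above_decay(Ca, b - a, pk$ke, thr_tot)
  }
  total / diff(window)
}

#' Evaluate the pharmacodynamic targets for one profile
#'
#' The `%fT` targets are attained when the fraction of `[0, horizon]` with
#' free concentration at or above the threshold reaches the target's
#' required fraction. The always-above target is attained when the free
#' concentration never falls below the MIC over the window from the end of
#' the first infusion to the horizon (`"post_first_infusion"`, the
#' default) or, alternatively, when every inter-dose trough and the final
#' concentration are at or above the MIC (`"troughs"`).
#'
#' @param profile A `conc_profile` from [conc_profile()].
#' @param drug A [drug_model()].
#' @param targets List of [pd_target()]s, defaults to [pd_targets()] of the
#'   drug.
#' @param always_above_mode `"post_first_infusion"` or `"troughs"`.
#' @return A one-row data frame (`attainment_record`) with the fractions of
#'   time above 1x and 4x MIC, the always-above flag, and one logical
#'   attainment flag per target.
#' @export
evaluate_targets <- function(profile, drug, targets = pd_targets(drug),
                             always_above_mode = c("post_first_infusion",
                                                   "troughs")) {
  stopifnot(inherits(profile, "conc_profile"), inherits(drug, "drug_model"))
  always_above_mode <- match.arg(always_above_mode)
  pk <- attr(profile, "pk")
  reg <- attr(profile, "regimen")
  if (is.null(pk) || is.null(reg))
    stop("evaluate_targets: needs an analytic profile from conc_profile()",
         call. = FALSE)
  eng <- .attainment_engine(
    ke = pk$ke, vd_total = pk$vd_total, cl_total = pk$ke * pk$vd_total,
    dose = reg$dose, interval = reg$interval,
    tinf = reg$infusion_duration, horizon = reg$horizon,
    thr_total = lapply(targets,
                       function(tg) tg$threshold_concentration /
                         pk$free_fraction))
  .attainment_from_engine(eng, targets, pk$free_fraction, always_above_mode)
}

# shared flag assembly for evaluate_targets / cohort_attainment
.attainment_from_engine <- function(eng, targets, free_fraction, mode) {
  minc <- if (mode == "post_first_infusion") eng$min_window else
    eng$min_trough
  out <- list()
  for (j in seq_along(targets)) {
    tg <- targets[[j]]
    nm <- names(targets)[j]
    if (tg$kind == "always_above_1xMIC") {
      flag <- minc >= tg$threshold_concentration / free_fraction
      out[["always_above"]] <- flag
      out[[paste0("attain_", nm)]] <- flag
    } else {
      frac <- eng$fraction[, j]
      out[[paste0("fraction_", nm)]] <- frac
      out[[paste0("attain_", nm)]] <- frac >= tg$required_fraction
    }
  }
  res <- as.data.frame(out)
  attr(res, "targets") <- targets
  class(res) <- c("attainment_record", "data.frame")
  res
}

#' Per-patient target attainment for a whole cohort
#'
#' Vectorized equivalent of [conc_profile()] + [evaluate_targets()] for
#' every patient at once: the engine walks the multiple-dose profile's
#' monotone segments a single time for the whole cohort, solving threshold
#' crossings in closed form, so results are grid-free and exact.
#'
#' @param cohort A [generate_cohort()] result.
#' @param regimen A [dose_regimen()].
#' @param drug A [drug_model()].
#' @param mic Optional MIC override, mg/L.
#' @param targets List of [pd_target()]s (default [pd_targets()]).
#' @param always_above_mode See [evaluate_targets()].
#' @return An `attainment_record` data frame with one row per patient.
#' @export
cohort_attainment <- function(cohort, regimen, drug, mic = NULL,
                              targets = pd_targets(drug, mic),
                              always_above_mode = c("post_first_infusion",
                                                    "troughs")) {
  stopifnot(inherits(cohort, "cohort"), inherits(regimen, "dose_regimen"),
            inherits(drug, "drug_model"))
  always_above_mode <- match.arg(always_above_mode)
  eng <- .attainment_engine(
    ke = cohort$ke, vd_total = cohort$vd_total, cl_total = cohort$cl_total,
    dose = regimen$dose, interval = regimen$interval,
    tinf = regimen$infusion_duration, horizon = regimen$horizon,
    thr_total = lapply(targets,
                       function(tg) tg$threshold_concentration /
                         cohort$free_fraction))
  .attainment_from_engine(eng, targets, cohort$free_fraction,
                          always_above_mode)
}
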