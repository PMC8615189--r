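#' Drug pharmacokinetic/pharmacodynamic model definition
#'
#' Bundles the sampled-parameter specifications of one antibiotic with its
#' susceptibility breakpoint and the percent-of-time threshold used by its
#' `%fT>=MIC` targets (40% for carbapenems, 50% for piperacillin and
#' tazobactam, 60% for cephalosporins).
#'
#' @param name Drug identifier (lower case).
#' @param vd_per_kg [param_spec()] for the volume of distribution, L/kg.
#' @param free_fraction [param_spec()] for the unbound fraction (0-1).
#' @param cl_nr [param_spec()] for nonrenal clearance, mL/min.
#' @param sieving [param_spec()] for the CRRT sieving coefficient (0-1).
#' @param mic Susceptibility breakpoint, mg/L (for tazobactam this is its
#'   4 mg/L exposure threshold, used by the same machinery).
#' @param pct_time_threshold Required percent of the 72-h window for the
#'   `%fT` targets, in (0, 100].
#' @return An object of class `drug_model`.
#' @export
drug_model <- function(name, vd_per_kg, free_fraction, cl_nr, sieving,
                       mic, pct_time_threshold) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mic) || mic <= 0)
    stop(sprintf("%s$mic: must be > 0", name), call. = FALSE)
  if (!is.numeric(pct_time_threshold) ||
      pct_time_threshold <= 0 || pct_time_threshold > 100)
    stop(sprintf("%s$pct_time_threshold: must be in (0, 100]", name),
         call. = FALSE)
  for (f in c("vd_per_kg", "free_fraction", "cl_nr", "sieving")) {
    spec <- get(f)
    if (!inherits(spec, "param_spec"))
      stop(sprintf("%s$%s: must be a param_spec", name, f), call. = FALSE)
    spec$name <- paste(name, f, sep = "$")
    validate_param_spec(spec)
    assign(f, spec)
  }
  for (f in c("free_fraction", "sieving")) {
    spec <- get(f)
    if (spec$lower < 0 || spec$upper > 1)
      stop(sprintf("%s$%s: bounds must lie within [0, 1]", name, f),
           call. = FALSE)
  }
  structure(list(name = name, vd_per_kg = vd_per_kg,
                 free_fraction = free_fraction, cl_nr = cl_nr,
                 sieving = sieving, mic = as.numeric(mic),
                 pct_time_threshold = as.numeric(pct_time_threshold)),
            class = "drug_model")
}

#' CRRT intensity arm definition
#'
#' One effluent-intensity arm of the simulated trial population: the body
#' weight distribution and the prescribed effluent rate, the fraction of
#' prescribed CRRT actually delivered, and the (recorded, unused)
#' replacement fluid rate.
#'
#' @param name Arm identifier, `"less_intensive"` or `"intensive"`.
#' @param weight [param_spec()] in kg; the lower truncation bound must be
#'   40 kg (no upper limit).
#' @param effluent_rate [param_spec()] in mL/kg/h.
#' @param delivered_fraction [param_spec()] in `[0, 1]`.
#' @param replacement_rate Optional [param_spec()] in L/h. Stored for
#'   completeness; it does not enter the clearance model.
#' @return An object of class `crrt_arm`.
#' @export
crrt_arm <- function(name, weight, effluent_rate, delivered_fraction,
                     replacement_rate = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  for (f in c("weight", "effluent_rate", "delivered_fraction")) {
    spec <- get(f)
    if (!inherits(spec, "param_spec"))
      stop(sprintf("%s$%s: must be a param_spec", name, f), call. = FALSE)
    spec$name <- paste(name, f, sep = "$")
    validate_param_spec(spec)
    assign(f, spec)
  }
  if (weight$lower != 40)
    stop(sprintf("%s$weight: lower bound must be 40 kg", name),
         call. = FALSE)
  if (delivered_fraction$lower < 0 || delivered_fraction$upper > 1)
    stop(sprintf("%s$delivered_fraction: bounds must lie within [0, 1]",
                 name), call. = FALSE)
  structure(list(name = name, weight = weight,
                 effluent_rate = effluent_rate,
                 delivered_fraction = delivered_fraction,
                 replacement_rate = replacement_rate),
            class = "crrt_arm")
}

#' Intermittent-infusion dosing regimen
#'
#' @param dose Dose per administration, mg.
#' @param interval Dosing interval, h.
#' @param infusion_duration Zero-order infusion duration, h (default 0.5 h,
#'   a standard intermittent infusion).
#' @param horizon Simulation length, h (default 72 h, the evaluation window
#'   of all pharmacodynamic targets).
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(2000, 12)
#' @export
dose_regimen <- function(dose, interval, infusion_duration = 0.5,
                         horizon = 72) {
  if (!is.numeric(dose) || dose <= 0)
    stop("dose: must be > 0", call. = FALSE)
  if (!is.numeric(infusion_duration) || infusion_duration <= 0)
    stop("infusion_duration: must be > 0", call. = FALSE)
  if (!(infusion_duration <= interval && interval <= horizon))
    stop("regimen: must satisfy 0 < infusion_duration <= interval <= horizon",
         call. = FALSE)
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration, horizon = horizon),
            class = "dose_regimen")
}

#' Pharmacodynamic target specification
#'
#' @param kind One of `"pct_above_1xMIC"`, `"pct_above_4xMIC"`,
#'   `"always_above_1xMIC"`.
#' @param threshold_concentration Free-drug concentration threshold, mg/L
#'   (MIC or 4xMIC).
#' @param required_fraction Required fraction of the evaluation window in
#'   (0, 1]; 1.0 for the always-above target.
#' @return An object of class `pd_target`.
#' @export
pd_target <- function(kind, threshold_concentration, required_fraction) {
  kind <- match.arg(kind, c("pct_above_1xMIC", "pct_above_4xMIC",
                            "always_above_1xMIC"))
  if (!is.numeric(threshold_concentration) || threshold_concentration <= 0)
    stop("threshold_concentration: must be > 0", call. = FALSE)
  if (!is.numeric(required_fraction) ||
      required_fraction <= 0 || required_fraction > 1)
    stop("required_fraction: must be in (0, 1]", call. = FALSE)
  structure(list(kind = kind,
                 threshold_concentration = threshold_concentration,
                 required_fraction = required_fraction),
            class = "pd_target")
}

#' Standard target set for a drug
#'
#' The three target families evaluated for every drug: `%fT >= 1xMIC` and
#' `%fT >= 4xMIC` at the drug's percent-of-time threshold, and
#' `100%fT >= MIC` (free concentration never below the breakpoint).
#'
#' @param drug A [drug_model()].
#' @param mic Optional MIC override in mg/L (used for the ertapenem
#'   breakpoint variants); defaults to `drug$mic`.
#' @return Named list of three [pd_target()] objects.
#' @export
pd_targets <- function(drug, mic = NULL) {
  m <- if (is.null(mic)) drug$mic else mic
  req <- drug$pct_time_threshold / 100
  list(
    pct_above_1xMIC = pd_target("pct_above_1xMIC", m, req),
    pct_above_4xMIC = pd_target("pct_above_4xMIC", 4 * m, req),
    always_above_1xMIC = pd_target("always_above_1xMIC", m, 1.0)
  )
}

# expected unit annotation per scenario field
.expected_units <- c(
  vd_per_kg = "L/kg", free_fraction = "fraction", cl_nr = "mL/min",
  sieving = "fraction", weight = "kg", effluent_rate = "mL/kg/h",
  delivered_fraction = "fraction", replacement_rate = "L/h")

.spec_from_yaml <- function(x, field, owner) {
  lbl <- paste(owner, field, sep = "$")
  if (!is.list(x) || is.null(x$mean) || is.null(x$sd))
    stop(sprintf("%s: missing mean/sd", lbl), call. = FALSE)
  if (is.null(x$unit) || !identical(x$unit, unname(.expected_units[field])))
    stop(sprintf("%s$unit: expected \"%s\"", lbl, .expected_units[field]),
         call. = FALSE)
  param_spec(x$mean, x$sd,
             lower = if (is.null(x$lower)) 0 else x$lower,
             upper = if (is.null(x$upper)) Inf else x$upper,
             r2_weight = x$r2_weight, unit = x$unit, name = lbl)
}

.spec_to_yaml <- function(spec) {
  out <- list(mean = spec$mean, sd = spec$sd, lower = spec$lower)
  if (is.finite(spec$upper)) out$upper <- spec$upper
  if (!is.null(spec$r2_weight)) out$r2_weight <- spec$r2_weight
  out$unit <- spec$unit
  out
}

#' Load a simulation scenario from a YAML file
#'
#' A scenario file defines the drugs (parameter distributions, breakpoints,
#' percent-time thresholds), the CRRT arms, the dosing regimen rows and
#' global infusion settings. The packaged fixture
#' `system.file("extdata", "atn_trial.yaml", package = "crrtpta")` ships the
#' full study configuration. Every field carries an explicit unit string
#' which is validated at load; violations of any parameter invariant raise
#' an error naming the offending field.
#'
#' @param path Path to a scenario YAML file.
#' @return An object of class `crrt_scenario`: a list with elements `name`,
#'   `infusion_duration`, `horizon`, `drugs` (named list of
#'   [drug_model()]), `arms` (named list of [crrt_arm()]), and `regimens`
#'   (data frame with columns `drug`, `dose_mg`, `interval_h`, `mic_mg_l`,
#'   `label`).
#' @seealso [write_scenario()], [default_scenario()],
#'   [enumerate_paper_regimens()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    stop(sprintf("scenario file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (f in c("name", "infusion_duration", "horizon", "drugs", "arms",
              "regimens"))
    if (is.null(raw[[f]]))
      stop(sprintf("scenario$%s: missing", f), call. = FALSE)

  drugs <- lapply(names(raw$drugs), function(dn) {
    d <- raw$drugs[[dn]]
    for (f in c("mic", "pct_time_threshold", "vd_per_kg", "free_fraction",
                "cl_nr", "sieving"))
      if (is.null(d[[f]]))
        stop(sprintf("%s$%s: missing", dn, f), call. = FALSE)
    drug_model(dn,
               vd_per_kg = .spec_from_yaml(d$vd_per_kg, "vd_per_kg", dn),
               free_fraction = .spec_from_yaml(d$free_fraction,
                                               "free_fraction", dn),
               cl_nr = .spec_from_yaml(d$cl_nr, "cl_nr", dn),
               sieving = .spec_from_yaml(d$sieving, "sieving", dn),
               mic = d$mic, pct_time_threshold = d$pct_time_threshold)
  })
  names(drugs) <- names(raw$drugs)

  arms <- lapply(names(raw$arms), function(an) {
    a <- raw$arms[[an]]
    crrt_arm(an,
             weight = .spec_from_yaml(a$weight, "weight", an),
             effluent_rate = .spec_from_yaml(a$effluent_rate,
                                             "effluent_rate", an),
             delivered_fraction = .spec_from_yaml(a$delivered_fraction,
                                                  "delivered_fraction", an),
             replacement_rate = if (is.null(a$replacement_rate)) NULL
             else .spec_from_yaml(a$replacement_rate, "replacement_rate", an))
  })
  names(arms) <- names(raw$arms)

  regs <- do.call(rbind, lapply(seq_along(raw$regimens), function(i) {
    r <- raw$regimens[[i]]
    if (is.null(r$drug) || is.null(r$dose) || is.null(r$interval))
      stop(sprintf("regimens[[%d]]: needs drug, dose, interval", i),
           call. = FALSE)
    if (!r$drug %in% names(drugs))
      stop(sprintf("regimens[[%d]]$drug: unknown drug \"%s\"", i, r$drug),
           call. = FALSE)
    mic <- as.numeric(if (is.null(r$mic)) drugs[[r$drug]]$mic else r$mic)
    label <- if (is.null(r$label))
      sprintf("%s %g mg q%gh", r$drug, r$dose, r$interval) else r$label
    data.frame(drug = r$drug, dose_mg = as.numeric(r$dose),
               interval_h = as.numeric(r$interval), mic_mg_l = mic,
               label = label, stringsAsFactors = FALSE)
  }))

  structure(list(name = raw$name,
                 infusion_duration = as.numeric(raw$infusion_duration),
                 horizon = as.numeric(raw$horizon),
                 drugs = drugs, arms = arms, regimens = regs),
            class = "crrt_scenario")
}

#' Write a scenario back to YAML
#'
#' Inverse of [load_scenario()]; writing then re-loading yields an
#' identical scenario object.
#'
#' @param scenario A `crrt_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "crrt_scenario"))
  drugs <- lapply(scenario$drugs, function(d) {
    list(mic = d$mic, pct_time_threshold = d$pct_time_threshold,
         vd_per_kg = .spec_to_yaml(d$vd_per_kg),
         free_fraction = .spec_to_yaml(d$free_fraction),
         cl_nr = .spec_to_yaml(d$cl_nr),
         sieving = .spec_to_yaml(d$sieving))
  })
  arms <- lapply(scenario$arms, function(a) {
    out <- list(weight = .spec_to_yaml(a$weight),
                effluent_rate = .spec_to_yaml(a$effluent_rate),
                delivered_fraction = .spec_to_yaml(a$delivered_fraction))
    if (!is.null(a$replacement_rate))
      out$replacement_rate <- .spec_to_yaml(a$replacement_rate)
    out
  })
  regimens <- lapply(seq_len(nrow(scenario$regimens)), function(i) {
    r <- scenario$regimens[i, ]
    out <- list(drug = r$drug, dose = r$dose_mg, interval = r$interval_h)
    if (r$mic_mg_l != scenario$drugs[[r$drug]]$mic) out$mic <- r$mic_mg_l
    out$label <- r$label
    out
  })
  yaml::write_yaml(list(name = scenario$name,
                        infusion_duration = scenario$infusion_duration,
                        horizon = scenario$horizon,
                        drugs = drugs, arms = arms, regimens = regimens),
                   path, precision = 12)
  invisible(path)
}

#' The packaged study scenario
#'
#' Loads the scenario shipped with the package: seven antibiotics
#' (cefepime, ceftazidime, piperacillin, tazobactam, ertapenem, imipenem,
#' meropenem) with their parameter distributions, the two CRRT intensity
#' arms (less-intensive 22 mL/kg/h, intensive 35.8 mL/kg/h), and all 29
#' simulated regimen rows (ertapenem 1 g q24h appears twice, at its 1 and
#' 2 mg/L breakpoints).
#'
#' @return A `crrt_scenario`.
#' @export
default_scenario <- function() {
  load_scenario(system.file("extdata", "atn_trial.yaml",
                            package = "crrtpta", mustWork = TRUE))
}

#' Enumerate the study's drug-regimen rows
#'
#' @param scenario A `crrt_scenario` (defaults to the packaged study
#'   scenario).
#' @return Data frame with one row per simulated regimen row: `drug`,
#'   `dose_mg`, `interval_h`, `mic_mg_l`, `label`.
#' @export
enumerate_paper_regimens <- function(scenario = default_scenario()) {
  stopifnot(inherits(scenario, "crrt_scenario"))
  scenario$regimens
}

#' @export
print.crrt_scenario <- function(x, ...) {
  cat(sprintf("<crrt_scenario \"%s\">: %d drugs, %d arms, %d regimen rows\n",
              x$name, length(x$drugs), length(x$arms), nrow(x$regimens)))
  cat(sprintf("  infusion %g h, horizon %g h\n",
              x$infusion_duration, x$horizon))
  invisible(x)
}
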