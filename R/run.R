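#' Derive a per-combination seed from the master seed
#'
#' Stable counter-based scheme keyed on the drug and arm names, so a subset
#' run reproduces exactly the cohorts of a full run under the same master
#' seed.
#'
#' @param seed Master seed (integer).
#' @param drug Drug name.
#' @param arm Arm name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, drug, arm) {
  key <- utf8ToInt(paste(drug, arm, sep = "/"))
  h <- 0
  for (k in key) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 69069 + h * 7919 + 1) %% 2147483647)
}

#' Run the full Monte Carlo attainment simulation
#'
#' Orchestrates sampler, PK engine, PD metrics and PTA aggregation for
#' every requested (drug, arm, regimen) combination. One cohort is sampled
#' per (drug, arm) with a seed derived from the master seed
#' ([derive_seed()]) and shared across that drug's regimens (variance
#' reduction); set `resample_per_regimen = TRUE` to draw a fresh cohort per
#' regimen row instead.
#'
#' @param scenario A `crrt_scenario` (default: packaged study scenario).
#' @param drugs Optional character vector restricting the drugs.
#' @param arms Optional character vector restricting the arms.
#' @param regimens Optional integer vector of regimen row indices
#'   (into `scenario$regimens`, after the drug filter).
#' @param n Cohort size; must be >= 4 and divisible by 4 (default 10000).
#' @param seed Master seed.
#' @param infusion_duration Optional override of the scenario's infusion
#'   duration, h.
#' @param always_above_mode See [evaluate_targets()].
#' @param resample_per_regimen Draw a fresh cohort per regimen row.
#' @param out_dir Optional output directory; when given, every table is
#'   written via [write_pta_table()] along with a JSON run manifest and a
#'   plain-text log.
#' @return List with `tables` (named list of [pta_table()]s, one per
#'   (arm, regimen row)) and `manifest`.
#' @export
run_simulation <- function(scenario = default_scenario(), drugs = NULL,
                           arms = NULL, regimens = NULL, n = 10000,
                           seed = 1, infusion_duration = NULL,
                           always_above_mode = "post_first_infusion",
                           resample_per_regimen = FALSE, out_dir = NULL) {
  stopifnot(inherits(scenario, "crrt_scenario"))
  if (!is.numeric(n) || n < 4 || n %% 4 != 0)
    stop(sprintf("n (%g): must be >= 4 and divisible by 4", n),
         call. = FALSE)
  tinf <- if (is.null(infusion_duration)) scenario$infusion_duration else
    infusion_duration
  drugs <- if (is.null(drugs)) names(scenario$drugs) else drugs
  bad <- setdiff(drugs, names(scenario$drugs))
  if (length(bad)) stop(sprintf("unknown drug: %s", bad[1]), call. = FALSE)
  arms <- if (is.null(arms)) names(scenario$arms) else arms
  bad <- setdiff(arms, names(scenario$arms))
  if (length(bad)) stop(sprintf("unknown arm: %s", bad[1]), call. = FALSE)
  regs <- scenario$regimens[scenario$regimens$drug %in% drugs, ]
  if (!is.null(regimens)) regs <- regs[regimens, ]
  if (nrow(regs) == 0) stop("no regimen rows selected", call. = FALSE)

  tables <- list()
  log_lines <- character(0)
  for (arm_name in arms) {
    arm <- scenario$arms[[arm_name]]
    for (drug_name in unique(regs$drug)) {
      drug <- scenario$drugs[[drug_name]]
      sub_seed <- derive_seed(seed, drug_name, arm_name)
      cohort <- NULL
      rows <- which(regs$drug == drug_name)
      for (ri in seq_along(rows)) {
        r <- regs[rows[ri], ]
        if (is.null(cohort) || resample_per_regimen)
          cohort <- generate_cohort(drug, arm, n,
                                    seed = sub_seed +
                                      if (resample_per_regimen) ri - 1L
                                      else 0L)
        regimen <- dose_regimen(r$dose_mg, r$interval_h, tinf,
                                scenario$horizon)
        t0 <- proc.time()[["elapsed"]]
        att <- cohort_attainment(cohort, regimen, drug, mic = r$mic_mg_l,
                                 always_above_mode = always_above_mode)
        tab <- pta_table(cohort, att, regimen_label = r$label)
        key <- paste(arm_name, r$label, sep = " | ")
        tables[[key]] <- tab
        log_lines <- c(log_lines, sprintf(
          "%s: n=%d seed=%d elapsed=%.2fs PTA(always)=%.1f%%",
          key, n, sub_seed, proc.time()[["elapsed"]] - t0,
          tab$pta_always_above_1xMIC[tab$group == "Overall"]))
      }
    }
  }
  manifest <- list(
    scenario = scenario$name,
    n = n, master_seed = seed,
    derived_seeds = stats::setNames(
      lapply(arms, function(a)
        stats::setNames(lapply(unique(regs$drug), derive_seed,
                               seed = seed, arm = a), unique(regs$drug))),
      arms),
    infusion_duration_h = tinf,
    always_above_mode = always_above_mode,
    version = as.character(utils::packageVersion("crrtpta")),
    timestamp = format(Sys.time(), tz = "UTC"),
    tables = names(tables))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(tables)) {
      fn <- paste0(gsub("[^A-Za-z0-9._-]+", "_", key), ".tsv")
      write_pta_table(tables[[key]], file.path(out_dir, fn))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(tables = tables, manifest = manifest)
}

#' Write a PTA table as delimited text
#'
#' Tab-separated with `#`-prefixed header lines carrying drug, arm,
#' regimen, `n` and seed; round-trips through [read_pta_table()].
#'
#' @param table A [pta_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pta_table <- function(table, path) {
  stopifnot(inherits(table, "pta_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# drug=%s", attr(table, "drug")),
               sprintf("# arm=%s", attr(table, "arm")),
               sprintf("# regimen=%s", attr(table, "regimen")),
               sprintf("# n=%d", attr(table, "n")),
               sprintf("# seed=%d", attr(table, "seed"))), con)
  df <- as.data.frame(table)
  for (cn in grep("^pta_", names(df), value = TRUE))
    df[[cn]] <- sprintf("%.10g", df[[cn]])
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PTA table written by [write_pta_table()]
#'
#' @param path File path.
#' @return A `pta_table` with its attributes restored.
#' @export
read_pta_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- function(key)
    sub(sprintf("^# %s=", key), "",
        grep(sprintf("^# %s=", key), hdr, value = TRUE)[1])
  out <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  attr(out, "drug") <- kv("drug")
  attr(out, "arm") <- kv("arm")
  attr(out, "regimen") <- kv("regimen")
  attr(out, "n") <- as.integer(kv("n"))
  attr(out, "seed") <- as.integer(kv("seed"))
  class(out) <- c("pta_table", "data.frame")
  out
}
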