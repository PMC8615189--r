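#' Partition a cohort into weight quartiles
#'
#' Stable sort by body weight (ties keep patient order), split into four
#' groups of exactly `n/4` from lightest (Q1) to heaviest (Q4).
#'
#' @param cohort A [generate_cohort()] result; `nrow` must be divisible
#'   by 4.
#' @return List with `groups` (list of four index vectors Q1-Q4), `ranges`
#'   (4 x 2 matrix of min/max weight per group, kg) and `ranges_kg`
#'   (the same rounded to integer kg, as reported in attainment tables).
#' @examples
#' sc <- default_scenario()
#' co <- generate_cohort(sc$drugs$cefepime, sc$arms$less_intensive, 100, 1)
#' quartile_partition(co)$ranges_kg
#' @export
quartile_partition <- function(cohort) {
  n <- nrow(cohort)
  if (n %% 4 != 0)
    stop(sprintf("quartile_partition: n (%d) must be divisible by 4", n),
         call. = FALSE)
  ord <- order(cohort$weight, seq_len(n))  # stable under ties
  groups <- split(ord, rep(1:4, each = n / 4))
  names(groups) <- paste0("Q", 1:4)
  ranges <- t(vapply(groups, function(g) range(cohort$weight[g]),
                     numeric(2)))
  colnames(ranges) <- c("min", "max")
  list(groups = groups, ranges = ranges, ranges_kg = round(ranges))
}

#' Probability of target attainment in a patient group
#'
#' @param flags Logical per-patient attainment flags.
#' @param group Index vector of the group (defaults to all patients).
#' @return PTA in percent.
#' @export
compute_pta <- function(flags, group = seq_along(flags)) {
  if (length(group) == 0) stop("compute_pta: empty group", call. = FALSE)
  100 * mean(flags[group])
}

#' Traffic-light classification of a PTA value
#'
#' `green` for PTA >= 90% (the optimality threshold), `orange` for
#' 60% <= PTA < 90%, `red` below 60%. Classification uses the unrounded
#' value.
#'
#' @param pta PTA in percent, in `[0, 100]`; vectorized.
#' @return Character vector of `"green"`, `"orange"`, `"red"`.
#' @examples
#' classify_pta(c(90, 60, 59.99))
#' @export
classify_pta <- function(pta) {
  if (any(!is.finite(pta)) || any(pta < 0) || any(pta > 100))
    stop("classify_pta: pta must be in [0, 100]", call. = FALSE)
  ifelse(pta >= 90, "green", ifelse(pta >= 60, "orange", "red"))
}

#' Build the attainment table for one regimen
#'
#' Aggregates per-patient attainment flags into overall and per-quartile
#' PTA for each target, with traffic-light classification. Because the
#' quartiles have equal size, the overall PTA equals the mean of the four
#' quartile PTAs exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param attainment An `attainment_record` from [cohort_attainment()].
#' @param regimen_label Label identifying the regimen row.
#' @return Data frame of class `pta_table`: rows `Overall`, `Q1`-`Q4`;
#'   columns `group`, `weight_min_kg`, `weight_max_kg`, then
#'   `pta_<target>` and `class_<target>` per target in the order 1xMIC,
#'   4xMIC, always-above. Attributes: `drug`, `arm`, `regimen`, `n`,
#'   `seed`.
#' @export
pta_table <- function(cohort, attainment, regimen_label = "") {
  stopifnot(inherits(cohort, "cohort"),
            inherits(attainment, "attainment_record"))
  part <- quartile_partition(cohort)
  flag_cols <- grep("^attain_", names(attainment), value = TRUE)
  groups <- c(list(Overall = seq_len(nrow(cohort))), part$groups)
  out <- data.frame(group = names(groups),
                    weight_min_kg = c(round(min(cohort$weight)),
                                      part$ranges_kg[, "min"]),
                    weight_max_kg = c(round(max(cohort$weight)),
                                      part$ranges_kg[, "max"]),
                    stringsAsFactors = FALSE)
  for (fc in flag_cols) {
    nm <- sub("^attain_", "", fc)
    pta <- vapply(groups, function(g) compute_pta(attainment[[fc]], g),
                  numeric(1))
    out[[paste0("pta_", nm)]] <- unname(pta)
    out[[paste0("class_", nm)]] <- classify_pta(unname(pta))
  }
  rownames(out) <- NULL
  attr(out, "drug") <- attr(cohort, "drug")
  attr(out, "arm") <- attr(cohort, "arm")
  attr(out, "regimen") <- regimen_label
  attr(out, "n") <- nrow(cohort)
  attr(out, "seed") <- attr(cohort, "seed")
  class(out) <- c("pta_table", "data.frame")
  out
}

#' @export
print.pta_table <- function(x, ...) {
  cat(sprintf("PTA table: %s, %s arm, %s (n = %d, seed = %s)\n",
              attr(x, "drug"), attr(x, "arm"), attr(x, "regimen"),
              attr(x, "n"), format(attr(x, "seed"))))
  df <- as.data.frame(x)
  for (cn in grep("^pta_", names(df), value = TRUE))
    df[[cn]] <- sprintf("%.1f", df[[cn]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Lowest regimen attaining the optimality threshold
#'
#' Candidates are ordered by total daily dose, then by dosing frequency;
#' the first whose PTA reaches the threshold (default 90%) for the chosen
#' target and group is returned.
#'
#' @param cohort Shared cohort the candidates are evaluated on.
#' @param drug A [drug_model()].
#' @param regimens List of candidate [dose_regimen()]s.
#' @param target_kind One of `"always_above_1xMIC"`, `"pct_above_1xMIC"`,
#'   `"pct_above_4xMIC"`.
#' @param group `"overall"` or `"Q1"`-`"Q4"`.
#' @param mic Optional MIC override, mg/L.
#' @param pta_threshold Optimality threshold in percent (default 90).
#' @param always_above_mode See [evaluate_targets()].
#' @return The optimal [dose_regimen()] with an added `pta` attribute, or
#'   `NULL` when no candidate qualifies.
#' @export
find_optimal_regimen <- function(cohort, drug, regimens,
                                 target_kind = "always_above_1xMIC",
                                 group = "overall", mic = NULL,
                                 pta_threshold = 90,
                                 always_above_mode = "post_first_infusion") {
  if (length(regimens) == 0)
    stop("find_optimal_regimen: empty candidate list", call. = FALSE)
  daily <- vapply(regimens, function(r) r$dose * 24 / r$interval, numeric(1))
  freq <- vapply(regimens, function(r) 24 / r$interval, numeric(1))
  ord <- order(daily, freq)
  idx <- if (group == "overall") seq_len(nrow(cohort)) else
    quartile_partition(cohort)$groups[[group]]
  for (i in ord) {
    att <- cohort_attainment(cohort, regimens[[i]], drug, mic = mic,
                             always_above_mode = always_above_mode)
    flags <- att[[paste0("attain_", target_kind)]]
    pta <- compute_pta(flags, idx)
    if (pta >= pta_threshold) {
      out <- regimens[[i]]
      attr(out, "pta") <- pta
      return(out)
    }
  }
  NULL
}

#' Per-quartile pharmacokinetic summary
#'
#' Arithmetic means of weight, weight-normalized and total volume of
#' distribution, and nonrenal clearance per weight quartile, used to
#' explain weight-gradient patterns in the attainment tables.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Data frame with rows Q1-Q4 and columns `mean_weight_kg`,
#'   `mean_vd_per_kg`, `mean_vd_total_l`, `mean_cl_nr_ml_min`.
#' @export
summarize_quartile_pk <- function(cohort) {
  part <- quartile_partition(cohort)
  do.call(rbind, lapply(names(part$groups), function(q) {
    g <- part$groups[[q]]
    data.frame(quartile = q,
               mean_weight_kg = mean(cohort$weight[g]),
               mean_vd_per_kg = mean(cohort$vd_per_kg[g]),
               mean_vd_total_l = mean(cohort$vd_total[g]),
               mean_cl_nr_ml_min = mean(cohort$cl_nr[g]))
  }))
}
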