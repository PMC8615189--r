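# run code with a local RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Truncated log-normal sampling with arithmetic moment matching
#'
#' Draws from the log-normal distribution whose *untruncated* arithmetic
#' mean and standard deviation equal `spec$mean` and `spec$sd`
#' (moment matching: `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`), rejecting and redrawing any value outside
#' `[spec$lower, spec$upper]`. Truncation therefore preserves the
#' distributional shape inside the bounds; under heavy truncation the
#' realized moments deviate from the nominal ones by construction (they are
#' the moments of the conditional distribution).
#'
#' `sd = 0` is the degenerate case and returns `rep(mean, n)`.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws, >= 1.
#' @param seed Optional integer seed. When supplied, sampling runs in a
#'   local RNG state (the caller's stream is untouched); when `NULL`, draws
#'   come from the current stream.
#' @return Numeric vector of `n` draws, all inside the truncation bounds.
#' @examples
#' w <- sample_truncated_lognormal(param_spec(84.1, 18.9, lower = 40), 1000,
#'                                 seed = 1)
#' min(w) >= 40
#' @export
sample_truncated_lognormal <- function(spec, n, seed = NULL) {
  validate_param_spec(spec)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (spec$sd == 0) return(rep(spec$mean, n))
  s2 <- log1p((spec$sd / spec$mean)^2)
  sigma <- sqrt(s2)
  mu <- log(spec$mean) - s2 / 2
  p_acc <- stats::plnorm(spec$upper, mu, sigma) -
    stats::plnorm(spec$lower, mu, sigma)
  if (p_acc < 1e-6)
    stop(sprintf("%s: truncation interval [%g, %g] has negligible mass (%.2g)",
                 if (is.null(spec$name)) "param_spec" else spec$name,
                 spec$lower, spec$upper, p_acc), call. = FALSE)
  .with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      m <- ceiling((n - length(out)) / p_acc * 1.2) + 16L
      x <- stats::rlnorm(m, mu, sigma)
      out <- c(out, x[x >= spec$lower & x <= spec$upper])
    }
    out[seq_len(n)]
  })
}

#' Induce a rank-based weight correlation
#'
#' Reorders `values` against `anchor` (body weight) so that the realized
#' correlation approximates `+sqrt(r2)` while the marginal distribution of
#' `values` is exactly preserved (the output is a permutation of the
#' input). The mechanism is a Gaussian-copula score: normal scores of the
#' anchor ranks are mixed with independent Gaussian noise at weight
#' `sqrt(r2)`, and the sorted values are assigned by the rank of the score
#' (an Iman-Conover-style reordering).
#'
#' @param anchor Numeric vector the correlation is induced against.
#' @param values Numeric vector to reorder; same length as `anchor`.
#' @param r2 Squared target correlation, in `[0, 1]`.
#' @param seed Optional integer seed for the mixing noise (local RNG state
#'   when supplied).
#' @return `values` reordered; `sort(output)` is identical to
#'   `sort(values)`.
#' @examples
#' w <- rlnorm(1000, 4.4, 0.2)
#' v <- rlnorm(1000, -0.8, 0.4)
#' cor(w, induce_rank_correlation(w, v, 0.42, seed = 1))
#' @export
induce_rank_correlation <- function(anchor, values, r2, seed = NULL) {
  if (length(anchor) != length(values))
    stop("anchor and values must have the same length", call. = FALSE)
  if (!is.numeric(r2) || length(r2) != 1L || r2 < 0 || r2 > 1)
    stop("r2: must be in [0, 1]", call. = FALSE)
  n <- length(anchor)
  r <- sqrt(r2)
  z_anchor <- stats::qnorm(rank(anchor, ties.method = "first") / (n + 1))
  .with_seed(seed, {
    score <- r * z_anchor + sqrt(1 - r2) * stats::rnorm(n)
    sort(values)[rank(score, ties.method = "first")]
  })
}

#' Generate a cohort of virtual CRRT patients
#'
#' Samples every patient-level parameter by truncated log-normal draws
#' ([sample_truncated_lognormal()]), induces the drug's weight-Vd and
#' weight-CL_NR correlations ([induce_rank_correlation()]), and derives the
#' per-patient clearances and elimination rate constant:
#' \deqn{CL_{CRRT} = SC \cdot Q_{eff} \cdot weight \cdot delivered / 1000
#'   \ \mathrm{(L/h)}}
#' \deqn{CL_{total} = 0.06 \cdot CL_{NR} + CL_{CRRT}, \quad
#'   k_e = CL_{total} / V_d}
#' (0.06 converts mL/min to L/h). Sampling order is fixed (weight,
#' vd_per_kg, free_fraction, cl_nr, sieving, effluent_rate,
#' delivered_fraction, then the two correlation reorderings), so a cohort
#' is reproducible bit-for-bit from `(drug, arm, n, seed)`.
#'
#' @param drug A [drug_model()].
#' @param arm A [crrt_arm()].
#' @param n Cohort size, >= 4.
#' @param seed Integer seed.
#' @return A data frame of class `cohort` with one row per patient and
#'   columns `weight`, `vd_per_kg`, `vd_total`, `free_fraction`, `cl_nr`,
#'   `sieving`, `effluent_rate`, `delivered_fraction`, `cl_crrt`,
#'   `cl_total`, `ke`; attributes `drug`, `arm`, `n`, `seed`.
#' @examples
#' sc <- default_scenario()
#' co <- generate_cohort(sc$drugs$meropenem, sc$arms$intensive, 100, seed = 1)
#' all(co$weight >= 40)
#' @export
generate_cohort <- function(drug, arm, n, seed) {
  stopifnot(inherits(drug, "drug_model"), inherits(arm, "crrt_arm"))
  if (!is.numeric(n) || n < 4) stop("n: must be >= 4", call. = FALSE)
  n <- as.integer(n)
  .with_seed(seed, {
    weight <- sample_truncated_lognormal(arm$weight, n)
    vd_per_kg <- sample_truncated_lognormal(drug$vd_per_kg, n)
    free_fraction <- sample_truncated_lognormal(drug$free_fraction, n)
    cl_nr <- sample_truncated_lognormal(drug$cl_nr, n)
    sieving <- sample_truncated_lognormal(drug$sieving, n)
    effluent_rate <- sample_truncated_lognormal(arm$effluent_rate, n)
    delivered_fraction <- sample_truncated_lognormal(arm$delivered_fraction, n)
    r2_vd <- drug$vd_per_kg$r2_weight
    r2_cl <- drug$cl_nr$r2_weight
    if (!is.null(r2_vd) && r2_vd > 0)
      vd_per_kg <- induce_rank_correlation(weight, vd_per_kg, r2_vd)
    if (!is.null(r2_cl) && r2_cl > 0)
      cl_nr <- induce_rank_correlation(weight, cl_nr, r2_cl)
    vd_total <- vd_per_kg * weight
    cl_crrt <- sieving * effluent_rate * weight * delivered_fraction / 1000
    cl_total <- 0.06 * cl_nr + cl_crrt
    ke <- cl_total / vd_total
    out <- data.frame(weight = weight, vd_per_kg = vd_per_kg,
                      vd_total = vd_total, free_fraction = free_fraction,
                      cl_nr = cl_nr, sieving = sieving,
                      effluent_rate = effluent_rate,
                      delivered_fraction = delivered_fraction,
                      cl_crrt = cl_crrt, cl_total = cl_total, ke = ke)
    attr(out, "drug") <- drug$name
    attr(out, "arm") <- arm$name
    attr(out, "n") <- n
    attr(out, "seed") <- seed
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Export a cohort as delimited text
#'
#' One patient per row, tab-separated, with `#`-prefixed header lines
#' carrying the drug, arm, size, seed and column units so the file is a
#' self-describing regression fixture.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# drug=%s", attr(cohort, "drug")),
    sprintf("# arm=%s", attr(cohort, "arm")),
    sprintf("# n=%d", attr(cohort, "n")),
    sprintf("# seed=%d", attr(cohort, "seed")),
    paste("# units: weight=kg vd_per_kg=L/kg vd_total=L cl_nr=mL/min",
          "effluent_rate=mL/kg/h cl_crrt=L/h cl_total=L/h ke=1/h")), con)
  utils::write.table(as.data.frame(cohort), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path File path.
#' @return A `cohort` data frame with its `drug`, `arm`, `n`, `seed`
#'   attributes restored.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  out <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  attr(out, "drug") <- kv("drug")
  attr(out, "arm") <- kv("arm")
  attr(out, "n") <- as.integer(kv("n"))
  attr(out, "seed") <- as.integer(kv("seed"))
  class(out) <- c("cohort", "data.frame")
  out
}
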