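#' Simulate a NIPT cohort under the two-Gaussian screening model
#'
#' Draws a synthetic cohort directly from the generative model the risk
#' engine assumes: each pregnancy is trisomic with the given prevalence;
#' every sample receives a foetal fraction drawn from the supplied prior;
#' euploid samples score `z ~ N(0, 1)` and trisomic samples score
#' `z ~ N(expected_z(f, CV), 1)`. Because generator and scorer share the
#' model, the simulator provides exact ground truth for validating
#' sensitivity, specificity and posterior calibration without any external
#' data. It does not emulate read counts, GC bias or sequencing error -
#' only the Z-score abstraction.
#'
#' Draws are made in a fixed order (trisomy status for all samples, then
#' mixture component and foetal fraction, then z) from one seeded
#' generator, so a cohort is fully reproducible from its parameters and
#' seed.
#'
#' @param n number of samples.
#' @param prevalence probability that a sample is trisomic, in (0, 1).
#' @param ff fetal-fraction prior samples are drawn from.
#' @param cv_percent assay coefficient of variation, percent.
#' @param seed integer seed; required, so cohorts are reproducible.
#' @param chromosome target chromosome label for the output table.
#' @return A data frame of class `simulated_cohort` with columns
#'   `sample_id`, `chromosome`, `true_status` (`"euploid"`/`"trisomic"`),
#'   `f_percent` and `z`, carrying the generating parameters as attributes
#'   `prevalence`, `cv_percent`, `ff`, `seed`.
#' @examples
#' sim <- simulate_cohort(1000, prevalence = 0.5, ff = ff_fixed(6),
#'                        cv_percent = 0.5, seed = 1)
#' mean(sim$z[sim$true_status == "trisomic"] > 3)
#' @export
simulate_cohort <- function(n, prevalence, ff = ff_default(),
                            cv_percent = 0.5, seed, chromosome = 21) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  check_cv(cv_percent)
  ff <- as_ff_prior(ff)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an explicit integer seed is required", call. = FALSE)
  chromosome <- check_chromosome(chromosome)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  trisomic <- stats::runif(n) < prevalence
  f <- sample_ff(n, ff)
  mu <- ifelse(trisomic, expected_z(f, cv_percent), 0)
  z <- stats::rnorm(n, mean = mu, sd = 1)

  out <- data.frame(
    sample_id = sprintf("sim%06d", seq_len(n)),
    chromosome = chromosome,
    true_status = ifelse(trisomic, "trisomic", "euploid"),
    f_percent = f,
    z = z,
    stringsAsFactors = FALSE
  )
  structure(out, prevalence = prevalence, cv_percent = cv_percent,
            ff = ff, seed = as.integer(seed),
            class = c("simulated_cohort", "data.frame"))
}

sample_ff <- function(n, ff) {
  co <- ff$components
  comp <- if (nrow(co) == 1L) rep(1L, n)
          else sample.int(nrow(co), n, replace = TRUE, prob = co$weight)
  lo <- co$low[comp]; hi <- co$high[comp]
  lo + (hi - lo) * stats::runif(n)
}

#' Write a simulated cohort as a batch input table
#'
#' Emits the cohort in the sample-table schema accepted by
#' [read_samples()] (columns `sample_id`, `chromosome`, `z`, plus a
#' `prior` column filled with the given a priori risk), so simulated data
#' flow through the same scoring path as real data. The truth column is
#' omitted - the scorer must not see it.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output TSV path.
#' @param prior prior string written for every row (default: the
#'   generating prevalence).
#' @export
write_cohort_samples <- function(cohort, path, prior = NULL) {
  if (is.null(prior)) prior <- format(attr(cohort, "prevalence"), digits = 10)
  df <- data.frame(sample_id = cohort$sample_id, chromosome = cohort$chromosome,
                   z = cohort$z, prior = prior, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Posterior calibration check on a simulated cohort
#'
#' Scores every sample of a simulated cohort with the *generating*
#' prevalence as prior and the *generating* fetal-fraction prior and CV,
#' bins the posteriors, and compares each bin's mean posterior with the
#' observed trisomy frequency. When scorer and generator match, Bayes'
#' theorem guarantees calibration: among samples assigned posterior around
#' q, a fraction close to q is truly trisomic, up to binomial noise. Each
#' bin passes if the observed frequency lies within `n_se` binomial
#' standard errors of the mean posterior; empty bins are reported as
#' no-data, not failures.
#'
#' A scorer prior different from the generating prevalence (via
#' `prior_override`) deliberately breaks calibration and should be flagged
#' by this check - the negative control.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param n_bins number of equal-width posterior bins on \[0, 1\].
#' @param n_se width of the acceptance band in binomial standard errors.
#' @param prior_override scorer prior probability; default `NULL` uses the
#'   generating prevalence (the matched, calibrated case).
#' @return A data frame of class `calibration_check`, one row per bin:
#'   `bin_low`, `bin_high`, `n`, `mean_ppr`, `observed_freq`, `se`,
#'   `pass` (`NA` for empty bins); attribute `all_pass` summarises the
#'   non-empty bins.
#' @export
calibration_check <- function(cohort, n_bins = 10, n_se = 3,
                              prior_override = NULL) {
  if (!inherits(cohort, "simulated_cohort"))
    stop("'cohort' must come from simulate_cohort()", call. = FALSE)
  p <- prior_override %||% attr(cohort, "prevalence")
  ff <- attr(cohort, "ff"); cv <- attr(cohort, "cv_percent")
  ppr <- ppr_vector(p, cohort$z, ff, cv)
  truth <- cohort$true_status == "trisomic"
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(ppr, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                    n = 0L, mean_ppr = NA_real_, observed_freq = NA_real_,
                    se = NA_real_, pass = NA)
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    out$n[b] <- length(idx)
    if (length(idx) == 0L) next
    m <- mean(ppr[idx]); obs <- mean(truth[idx])
    se <- sqrt(m * (1 - m) / length(idx))
    out$mean_ppr[b] <- m; out$observed_freq[b] <- obs; out$se[b] <- se
    out$pass[b] <- abs(obs - m) <= n_se * se
  }
  structure(out, all_pass = all(out$pass[!is.na(out$pass)]),
            class = c("calibration_check", "data.frame"))
}

# vectorised raw posterior for a shared prior/ff/cv
ppr_vector <- function(p, z, ff, cv_percent) {
  vapply(z, function(zi) posterior_risk(p, zi, ff, cv_percent)$ppr, numeric(1))
}

#' @export
print.calibration_check <- function(x, ...) {
  cat("Posterior calibration check (", sum(x$n), " samples, ",
      nrow(x), " bins): ",
      if (isTRUE(attr(x, "all_pass"))) "all non-empty bins pass"
      else "MISCALIBRATION detected", "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
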