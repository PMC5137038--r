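#' Assay profile for a target chromosome
#'
#' Bundles the two assay-level parameters of the screening model: the
#' coefficient of variation (CV) of the target-chromosome fraction among
#' diploid control samples, expressed in percent of the mean, and the
#' positive-call cutoff on the Z scale.
#'
#' The CV captures everything that limits assay precision (read depth,
#' library preparation, reference set, GC handling). Defaults follow common
#' practice for genome-wide NIPT: 0.5% for chromosome 21 and 0.4% for
#' chromosomes 13 and 18, which enjoy higher read counts.
#'
#' @param chromosome target chromosome: 13, 18 or 21.
#' @param cv_percent coefficient of variation in percent; if `NULL`, the
#'   per-chromosome default is used.
#' @param z_threshold positive-call cutoff on the Z scale (default 3).
#' @return An object of class `assay_profile` with elements `chromosome`,
#'   `cv_percent` and `z_threshold`.
#' @examples
#' assay_profile(21)
#' assay_profile(13, cv_percent = 0.3)
#' @export
assay_profile <- function(chromosome, cv_percent = NULL, z_threshold = 3) {
  chromosome <- check_chromosome(chromosome)
  if (is.null(cv_percent)) cv_percent <- default_cv(chromosome)
  check_cv(cv_percent)
  if (!is.numeric(z_threshold) || length(z_threshold) != 1L || z_threshold <= 0)
    stop("z_threshold must be a single positive number", call. = FALSE)
  structure(list(chromosome = chromosome, cv_percent = cv_percent,
                 z_threshold = z_threshold),
            class = "assay_profile")
}

#' @export
print.assay_profile <- function(x, ...) {
  cat(sprintf("NIPT assay profile: chr%d, CV %g%%, call threshold Z > %g\n",
              x$chromosome, x$cv_percent, x$z_threshold))
  invisible(x)
}

#' Default coefficient of variation per chromosome
#'
#' @param chromosome 13, 18 or 21.
#' @return CV in percent: 0.5 for chromosome 21, 0.4 for 13 and 18.
#' @export
default_cv <- function(chromosome) {
  chromosome <- check_chromosome(chromosome)
  if (chromosome == 21) 0.5 else 0.4
}

check_chromosome <- function(chromosome) {
  chromosome <- suppressWarnings(as.integer(sub("^chr", "", as.character(chromosome))))
  if (length(chromosome) != 1L || is.na(chromosome) || !chromosome %in% c(13L, 18L, 21L))
    stop("target chromosome must be one of 13, 18, 21", call. = FALSE)
  chromosome
}

check_cv <- function(cv_percent) {
  if (!is.numeric(cv_percent) || length(cv_percent) != 1L || !is.finite(cv_percent))
    stop("cv_percent must be a single finite number", call. = FALSE)
  if (cv_percent <= 0 || cv_percent >= 5)
    stop("cv_percent = ", cv_percent, " is outside (0, 5); the CV is a ",
         "percentage of the mean (typical NIPT values are 0.2-0.5) - check units",
         call. = FALSE)
  invisible(cv_percent)
}

check_z <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("z must be a single finite number", call. = FALSE)
  if (abs(z) > 50)
    stop("|z| = ", abs(z), " exceeds the sanity bound of 50", call. = FALSE)
  invisible(z)
}

#' Expected Z-score of a trisomic sample
#'
#' An extra copy of the target chromosome raises its plasma fraction by half
#' the foetal fraction relative to the diploid mean, so the mean of the
#' trisomic Z distribution is `(f/2) / CV` with both the foetal fraction `f`
#' and the CV in percent. The spread of the trisomic Z distribution is taken
#' to be 1, as for controls.
#'
#' @param f_percent foetal DNA fraction, percent (> 0).
#' @param cv_percent coefficient of variation, percent (> 0).
#' @return The expected Z-score (dimensionless). Vectorised over `f_percent`.
#' @examples
#' expected_z(6, 0.5)   # 6
#' expected_z(4, 0.5)   # 4
#' @export
expected_z <- function(f_percent, cv_percent) {
  if (!is.numeric(f_percent) || any(!is.finite(f_percent)) || any(f_percent <= 0))
    stop("f_percent must be positive and finite", call. = FALSE)
  if (!is.numeric(cv_percent) || any(!is.finite(cv_percent)) || any(cv_percent <= 0))
    stop("cv_percent must be positive and finite", call. = FALSE)
  (f_percent / 2) / cv_percent
}

#' Density of the observed Z-score under the euploid model
#'
#' Diploid samples score as a standard normal by construction of the
#' Z-score, so this is the standard normal density.
#'
#' @param z observed Z-score(s).
#' @return Probability density at `z`.
#' @export
euploid_density <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("z must be finite", call. = FALSE)
  stats::dnorm(z)
}

#' Marginal density of the observed Z-score under the trisomic model
#'
#' Conditional on a foetal fraction `f`, a trisomic sample scores as
#' `N(expected_z(f, CV), 1)`. The foetal fraction is a nuisance parameter:
#' for a uniform or mixture prior it is integrated out, giving a weighted
#' sum over components of
#' \deqn{\frac{1}{hi-lo}\int_{lo}^{hi} \phi(z - (f/2)/CV)\, df
#'   = \frac{2\,CV}{hi-lo}\left[\Phi(z - lo/(2CV)) - \Phi(z - hi/(2CV))\right],}
#' evaluated in whichever tail orientation avoids cancellation. The
#' marginal is therefore exact (no quadrature error) and deterministic.
#'
#' @param z observed Z-score.
#' @param ff fetal-fraction prior (see [ff_prior]); a single number is taken
#'   as a fixed fraction, a length-2 numeric as a uniform range.
#' @param cv_percent coefficient of variation, percent.
#' @param log return the log density.
#' @return Probability density (or log density) at `z`.
#' @examples
#' trisomy_density(3, ff_fixed(4), 0.5)    # dnorm(3 - 4)
#' trisomy_density(4, ff_default(), 0.5)
#' @export
trisomy_density <- function(z, ff, cv_percent, log = FALSE) {
  check_z(z)
  check_cv(cv_percent)
  ff <- as_ff_prior(ff)
  co <- ff$components
  dens <- 0
  for (i in seq_len(nrow(co))) {
    if (co$low[i] == co$high[i]) {
      part <- stats::dnorm(z - expected_z(co$low[i], cv_percent))
    } else {
      u_lo <- expected_z(co$low[i], cv_percent)
      u_hi <- expected_z(co$high[i], cv_percent)
      # Phi(z - u_lo) - Phi(z - u_hi), mirrored into the small tail so the
      # difference never cancels catastrophically
      mass <- if (z > (u_lo + u_hi) / 2)
        stats::pnorm(u_hi - z) - stats::pnorm(u_lo - z)
      else
        stats::pnorm(z - u_lo) - stats::pnorm(z - u_hi)
      part <- mass / (u_hi - u_lo)
    }
    dens <- dens + co$weight[i] * part
  }
  if (log) base::log(dens) else dens
}

#' Likelihood ratio of trisomy given an observed Z-score
#'
#' The ratio of the (marginal) trisomic density to the euploid density at
#' the observed Z. For a fixed foetal fraction this has the closed form
#' `exp(z_exp * z - z_exp^2 / 2)` with `z_exp = expected_z(f, CV)`. The
#' ratio is computed on the log scale so extreme Z-scores (where the
#' euploid density underflows) still yield a finite or infinite LR rather
#' than NaN.
#'
#' @inheritParams trisomy_density
#' @return The likelihood ratio (>= 0, possibly `Inf` for very large `z`).
#' @examples
#' likelihood_ratio(3, ff_fixed(4), 0.5)   # dnorm(1)/dnorm(3) = exp(7.5)/exp(4.5)... = 54.6
#' @export
likelihood_ratio <- function(z, ff, cv_percent) {
  log_num <- trisomy_density(z, ff, cv_percent, log = TRUE)
  log_den <- stats::dnorm(z, log = TRUE)
  if (log_num == -Inf) return(0)
  exp(log_num - log_den)
}

#' Personalised a posteriori risk of foetal trisomy
#'
#' Combines the a priori risk with the NIPT likelihood ratio through a
#' Bayes odds update:
#' \deqn{PPR = \frac{p \cdot LR}{p \cdot LR + 1 - p}.}
#' The prior odds `p/(1-p)` are multiplied by the likelihood ratio of the
#' observed Z-score and converted back to a probability. A Z-score below
#' half the expected Z gives LR < 1 and a posterior below the prior, which
#' is reported as-is (evidence against trisomy is evidence).
#'
#' @param prior a priori risk: a probability in (0, 1), an odds string such
#'   as `"1:250"` or `"1/4"`, or a [prior_risk] object.
#' @inheritParams trisomy_density
#' @return An object of class `posterior_result` with elements
#'   `likelihood_diploid`, `likelihood_trisomy`, `likelihood_ratio`, `ppr`
#'   (raw posterior probability), `prior` (the [prior_risk] used) and
#'   `display_percent` (clinician-facing string, see [format_ppr]).
#' @examples
#' posterior_risk("1:1000", z = 3, ff = ff_fixed(4), cv_percent = 0.5)
#' posterior_risk(0.1, z = 2.5, ff = ff_fixed(4), cv_percent = 0.5)
#' @export
posterior_risk <- function(prior, z, ff, cv_percent) {
  prior <- as_prior_risk(prior)
  p <- prior$probability
  if (p <= 0 || p >= 1)
    stop("degenerate prior: the a priori risk must lie strictly in (0, 1)",
         call. = FALSE)
  ff <- as_ff_prior(ff)
  lr <- likelihood_ratio(z, ff, cv_percent)
  ppr <- if (is.infinite(lr)) 1 else (p * lr) / (p * lr + 1 - p)
  structure(list(
    likelihood_diploid = euploid_density(z),
    likelihood_trisomy = trisomy_density(z, ff, cv_percent),
    likelihood_ratio = lr,
    ppr = ppr,
    prior = prior,
    display_percent = format_ppr(ppr)
  ), class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("Personalised a posteriori risk\n")
  cat(sprintf("  a priori risk     : %s (p = %.6g)\n",
              x$prior$notation %||% format(x$prior$probability), x$prior$probability))
  cat(sprintf("  likelihood ratio  : %.6g\n", x$likelihood_ratio))
  cat(sprintf("  posterior (raw)   : %.6g\n", x$ppr))
  cat(sprintf("  posterior (report): %s%%\n", x$display_percent))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clinical display rounding of a posterior probability
#'
#' The raw posterior is kept at full precision internally; the reported
#' figure rounds to an integer percent between 1 and 99, shows `"<0.1"`
#' below 0.1% and `"<1"` below 1%, and caps at `"99.9"` where integer
#' rounding would reach 100 - a screening result is never reported as
#' certainty.
#'
#' @param ppr posterior probability in \[0, 1\] (vectorised).
#' @return Character vector of display percentages (without the `%` sign).
#' @examples
#' format_ppr(c(0.0004, 0.005, 0.36, 0.999))
#' @export
format_ppr <- function(ppr) {
  if (!is.numeric(ppr) || any(is.na(ppr)) || any(ppr < 0 | ppr > 1))
    stop("ppr must be probabilities in [0, 1]", call. = FALSE)
  pct <- ppr * 100
  out <- as.character(round(pct))
  out[round(pct) >= 100] <- "99.9"
  out[pct < 1] <- "<1"
  out[pct < 0.1] <- "<0.1"
  out
}

#' Detection sensitivity of the assay
#'
#' Probability that a trisomic sample with a given foetal fraction scores
#' above the call threshold: `pnorm(expected_z(f, CV) - z_threshold)`.
#'
#' @param f_percent foetal DNA fraction, percent.
#' @param cv_percent coefficient of variation, percent.
#' @param z_threshold positive-call cutoff (default 3).
#' @return Detection probability in (0, 1). Vectorised over `f_percent`.
#' @examples
#' nipt_sensitivity(6, 0.5)   # 0.99865
#' nipt_sensitivity(4, 0.5)   # 0.84134
#' @export
nipt_sensitivity <- function(f_percent, cv_percent, z_threshold = 3) {
  check_cv(cv_percent)
  stats::pnorm(expected_z(f_percent, cv_percent) - z_threshold)
}

#' Coefficient of variation required for a target sensitivity
#'
#' Inverts the sensitivity formula: the CV at which a trisomic sample with
#' foetal fraction `f` is detected with the requested probability,
#' `CV = (f/2) / (z_threshold + qnorm(target_sensitivity))`.
#'
#' @param f_percent foetal DNA fraction, percent.
#' @param target_sensitivity required detection probability, in (0.5, 1).
#' @param z_threshold positive-call cutoff (default 3).
#' @return The required CV in percent.
#' @examples
#' required_cv(4, pnorm(3))   # 0.333...
#' @export
required_cv <- function(f_percent, target_sensitivity, z_threshold = 3) {
  if (!is.numeric(target_sensitivity) || any(target_sensitivity <= 0.5) ||
      any(target_sensitivity >= 1))
    stop("target_sensitivity must lie in (0.5, 1): at 0.5 or below the ",
         "expected Z would not exceed the threshold", call. = FALSE)
  (f_percent / 2) / (z_threshold + stats::qnorm(target_sensitivity))
}

#' Central coverage of the euploid Z distribution
#'
#' Fraction of diploid samples whose Z-score falls within `[-z_bound,
#' z_bound]`: `2 * pnorm(z_bound) - 1`. At the conventional bound of 3 this
#' is 99.7%, the specificity side of the screening model.
#'
#' @param z_bound positive Z bound.
#' @return Coverage probability.
#' @examples
#' euploid_central_coverage(3)   # 0.9973
#' @export
euploid_central_coverage <- function(z_bound) {
  if (!is.numeric(z_bound) || any(z_bound < 0))
    stop("z_bound must be non-negative", call. = FALSE)
  2 * stats::pnorm(z_bound) - 1
}
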