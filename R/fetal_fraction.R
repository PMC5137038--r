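#' Fetal-fraction priors
#'
#' The fraction of cell-free DNA in maternal plasma that is of foetal
#' (placental) origin scales the trisomic signal: an extra chromosome copy
#' shifts the target-chromosome fraction by half the foetal fraction. Because
#' the fraction is often unmeasured or imprecise, the engine treats it as a
#' nuisance parameter with a prior that is either a fixed value, a uniform
#' range, or a weighted mixture of uniform ranges, all expressed in percent
#' of total cell-free DNA.
#'
#' `ff_default()` returns the mixture used when nothing is known about the
#' foetal fraction: 0.4 * U(1, 23) + 0.6 * U(6, 18). The broad component
#' covers the population range seen mid-gestation and the narrow component
#' concentrates mass around typical values, deliberately leaving extra weight
#' on the extremes relative to a Gaussian so that low-fraction samples are
#' not over-called.
#'
#' @param f_percent fixed foetal fraction, percent.
#' @param low,high bounds of a uniform range, percent.
#' @param components data frame (or matrix) with columns `low`, `high`,
#'   `weight`; weights must be positive and sum to 1.
#'
#' @return An object of class `ff_prior`: a list with elements `kind`
#'   (`"fixed"`, `"uniform"` or `"mixture"`) and `components` (data frame
#'   with columns `low`, `high`, `weight`).
#' @examples
#' ff_fixed(4)
#' ff_uniform(1, 23)
#' ff_default()
#' @name ff_prior
NULL

#' @rdname ff_prior
#' @export
ff_fixed <- function(f_percent) {
  new_ff_prior("fixed", data.frame(low = f_percent, high = f_percent, weight = 1))
}

#' @rdname ff_prior
#' @export
ff_uniform <- function(low, high) {
  new_ff_prior("uniform", data.frame(low = low, high = high, weight = 1))
}

#' @rdname ff_prior
#' @export
ff_mixture <- function(components) {
  components <- as.data.frame(components)
  if (!all(c("low", "high", "weight") %in% names(components)))
    stop("mixture components need columns 'low', 'high', 'weight'", call. = FALSE)
  new_ff_prior("mixture", components[c("low", "high", "weight")])
}

#' @rdname ff_prior
#' @export
ff_default <- function() {
  ff_mixture(data.frame(low = c(1, 6), high = c(23, 18), weight = c(0.4, 0.6)))
}

new_ff_prior <- function(kind, components) {
  stopifnot(kind %in% c("fixed", "uniform", "mixture"))
  if (nrow(components) < 1L || anyNA(components))
    stop("fetal-fraction prior needs at least one complete component", call. = FALSE)
  with(components, {
    if (any(weight <= 0) || abs(sum(weight) - 1) > 1e-12)
      stop("component weights must be positive and sum to 1", call. = FALSE)
    if (any(low <= 0) || any(high < low) || any(high > 50))
      stop("fetal fractions are percentages: need 0 < low <= high <= 50 ",
           "(a value above 50 suggests a fraction was given instead of a percent)",
           call. = FALSE)
  })
  if (kind == "fixed" && any(components$low != components$high))
    stop("a fixed prior must have low == high", call. = FALSE)
  structure(list(kind = kind, components = components), class = "ff_prior")
}

#' @export
print.ff_prior <- function(x, ...) {
  cat("Fetal-fraction prior (", x$kind, ")\n", sep = "")
  for (i in seq_len(nrow(x$components))) {
    co <- x$components[i, ]
    if (co$low == co$high)
      cat(sprintf("  fixed at %g%%  (weight %g)\n", co$low, co$weight))
    else
      cat(sprintf("  uniform %g-%g%%  (weight %g)\n", co$low, co$high, co$weight))
  }
  invisible(x)
}

is_ff_prior <- function(x) inherits(x, "ff_prior")

as_ff_prior <- function(x) {
  if (is_ff_prior(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(ff_fixed(x))
  if (is.numeric(x) && length(x) == 2L) return(ff_uniform(x[1], x[2]))
  stop("cannot interpret as a fetal-fraction prior: supply ff_fixed(), ",
       "ff_uniform(), ff_mixture() or a numeric of length 1 or 2", call. = FALSE)
}
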