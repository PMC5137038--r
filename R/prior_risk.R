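#' A priori trisomy risk
#'
#' The pre-test probability that the foetus carries the target trisomy.
#' Clinically this comes from a first-trimester combined test (FCT), from a
#' previous affected pregnancy, or from population risk tables indexed by
#' maternal and gestational age. Risks are quoted interchangeably as
#' probabilities ("0.001") and odds-style ratios ("1:1000", "1/4"); both
#' ratio forms are read as *1 in n*, i.e. probability `1/n`.
#'
#' @param probability pre-test probability in (0, 1).
#' @param source one of `"direct"`, `"odds_notation"`, `"fct"`, `"age_table"`.
#' @param notation original string, if the risk was parsed from one.
#' @return An object of class `prior_risk`.
#' @seealso [parse_prior()], [interpolate_risk()]
#' @export
prior_risk <- function(probability, source = "direct", notation = NULL) {
  if (!is.numeric(probability) || length(probability) != 1L ||
      !is.finite(probability) || probability <= 0 || probability >= 1)
    stop("a priori risk must be a probability strictly between 0 and 1",
         call. = FALSE)
  source <- match.arg(source, c("direct", "odds_notation", "fct", "age_table"))
  structure(list(probability = probability, source = source, notation = notation),
            class = "prior_risk")
}

#' @export
print.prior_risk <- function(x, ...) {
  cat(sprintf("A priori risk: %.6g (%s%s)\n", x$probability, x$source,
              if (!is.null(x$notation)) paste0(", '", x$notation, "'") else ""))
  invisible(x)
}

as_prior_risk <- function(x, source = "direct") {
  if (inherits(x, "prior_risk")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_prior(x, source = source))
  if (is.numeric(x) && length(x) == 1L) return(prior_risk(x, source = source))
  stop("cannot interpret as an a priori risk: supply a probability, an odds ",
       "string ('1:n' or '1/n'), or a prior_risk object", call. = FALSE)
}

#' Parse an a priori risk from text
#'
#' Accepts a decimal probability (`"0.001"`), or the ratio forms `"1:n"`
#' and `"1/n"` with `n >= 2`, both mapped to probability `1/n` (the
#' conventional *1 in n* reading; the strict-odds reading `1/(n+1)` is not
#' used).
#'
#' @param text risk string.
#' @param source provenance label stored on the result (default
#'   `"odds_notation"` for ratio forms, `"direct"` for decimals).
#' @return A [prior_risk].
#' @examples
#' parse_prior("1:1000")  # 0.001
#' parse_prior("1/4")     # 0.25
#' parse_prior("0.5")
#' @export
parse_prior <- function(text, source = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("prior must be a non-empty string", call. = FALSE)
  s <- trimws(text)
  if (grepl("^([0-9]*\\.?[0-9]+)[:/]([0-9]*\\.?[0-9]+)$", s)) {
    parts <- as.numeric(strsplit(s, "[:/]")[[1]])
    num <- parts[1]; den <- parts[2]
    if (num != 1)
      stop("malformed prior '", text, "': ratio priors must be of the form 1:n or 1/n",
           call. = FALSE)
    if (!is.finite(den) || den < 2)
      stop("malformed prior '", text, "': n must be at least 2", call. = FALSE)
    return(prior_risk(1 / den, source = source %||% "odds_notation", notation = s))
  }
  p <- suppressWarnings(as.numeric(s))
  if (is.na(p))
    stop("malformed prior '", text, "': expected a probability or '1:n'/'1/n'",
         call. = FALSE)
  if (p <= 0 || p >= 1)
    stop("prior '", text, "' is outside (0, 1)", call. = FALSE)
  prior_risk(p, source = source %||% "direct", notation = s)
}

#' Format an a priori risk
#'
#' Writes a [prior_risk] back to text: the original notation when one was
#' parsed, otherwise a `"1:n"` form when `1/p` is (nearly) integral,
#' otherwise the decimal probability. `parse_prior(format_prior(x))`
#' recovers the same probability.
#'
#' @param x a [prior_risk] or probability.
#' @return A single string.
#' @export
format_prior <- function(x) {
  x <- as_prior_risk(x)
  if (!is.null(x$notation)) return(x$notation)
  n <- 1 / x$probability
  if (abs(n - round(n)) < 1e-9) sprintf("1:%d", as.integer(round(n)))
  else format(x$probability, digits = 10)
}

#' Maternal-age by gestational-age risk table
#'
#' A grid of population a priori risks indexed by maternal age (years) and
#' gestational age (completed weeks), as published for trisomies 21, 18 and
#' 13. Axes must be strictly ascending and every cell a probability in
#' (0, 1).
#'
#' @param trisomy target chromosome: 13, 18 or 21.
#' @param maternal_ages ascending numeric vector of maternal ages (years).
#' @param gestational_ages ascending numeric vector of gestational weeks.
#' @param risks numeric matrix of probabilities, rows = maternal ages,
#'   columns = gestational weeks.
#' @return An object of class `risk_table`.
#' @seealso [read_risk_table()], [interpolate_risk()]
#' @export
risk_table <- function(trisomy, maternal_ages, gestational_ages, risks) {
  trisomy <- check_chromosome(trisomy)
  risks <- as.matrix(risks)
  if (is.unsorted(maternal_ages, strictly = TRUE) ||
      is.unsorted(gestational_ages, strictly = TRUE))
    stop("risk-table axes must be strictly ascending", call. = FALSE)
  if (nrow(risks) != length(maternal_ages) || ncol(risks) != length(gestational_ages))
    stop("risk grid is ", nrow(risks), "x", ncol(risks), " but axes have ",
         length(maternal_ages), " ages and ", length(gestational_ages), " weeks",
         call. = FALSE)
  if (!is.numeric(risks) || anyNA(risks) || any(risks <= 0 | risks >= 1))
    stop("all risks must be probabilities in (0, 1)", call. = FALSE)
  structure(list(trisomy = trisomy,
                 maternal_ages = as.numeric(maternal_ages),
                 gestational_ages = as.numeric(gestational_ages),
                 risks = unname(risks)),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("Risk table for trisomy %d: %d maternal ages (%g-%g y) x %d gestational weeks (%g-%g)\n",
              x$trisomy, length(x$maternal_ages), min(x$maternal_ages),
              max(x$maternal_ages), length(x$gestational_ages),
              min(x$gestational_ages), max(x$gestational_ages)))
  invisible(x)
}

#' Read a risk table from CSV
#'
#' Expected layout: the first row holds the gestational weeks, the first
#' column the maternal ages, and each cell the corresponding risk as a
#' decimal probability or a `"1:n"`/`"1/n"` string. The top-left cell is
#' ignored.
#'
#' @param path CSV file path.
#' @param trisomy target chromosome the table applies to.
#' @return A [risk_table].
#' @examples
#' path <- system.file("extdata", "synthetic_risk_table_t21.csv", package = "niptppr")
#' read_risk_table(path, trisomy = 21)
#' @export
read_risk_table <- function(path, trisomy) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("risk-table CSV needs at least one age row and one week column", call. = FALSE)
  weeks <- as.numeric(raw[1, -1])
  ages  <- as.numeric(raw[-1, 1])
  if (anyNA(weeks) || anyNA(ages))
    stop("risk-table axes must be numeric (first row = weeks, first column = ages)",
         call. = FALSE)
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  grid <- apply(cells, c(1, 2), function(s) parse_prior(s)$probability)
  risk_table(trisomy, ages, weeks, grid)
}

#' Interpolate an a priori risk from a table
#'
#' Standard bilinear interpolation on the probability grid: linear in
#' maternal age along each column, linear in gestational age along each
#' row, exact at grid nodes. Queries outside the table are refused - no
#' extrapolation of clinical risk.
#'
#' @param table a [risk_table].
#' @param maternal_age query maternal age, years.
#' @param gestational_age query gestational age, weeks.
#' @return A [prior_risk] with source `"age_table"`.
#' @examples
#' tab <- risk_table(21, c(25, 30), c(10, 12), matrix(c(1, 2, 3, 4) / 1000, 2))
#' interpolate_risk(tab, 27.5, 11)
#' @export
interpolate_risk <- function(table, maternal_age, gestational_age) {
  if (!inherits(table, "risk_table")) stop("'table' must be a risk_table", call. = FALSE)
  ages <- table$maternal_ages; weeks <- table$gestational_ages
  if (maternal_age < ages[1] || maternal_age > ages[length(ages)] ||
      gestational_age < weeks[1] || gestational_age > weeks[length(weeks)])
    stop(sprintf(paste0("query (age %g y, week %g) is outside the table ",
                        "(ages %g-%g, weeks %g-%g); risks are not extrapolated"),
                 maternal_age, gestational_age, ages[1], ages[length(ages)],
                 weeks[1], weeks[length(weeks)]), call. = FALSE)
  i <- max(findInterval(maternal_age, ages, rightmost.closed = TRUE), 1L)
  j <- max(findInterval(gestational_age, weeks, rightmost.closed = TRUE), 1L)
  i2 <- min(i + 1L, length(ages)); j2 <- min(j + 1L, length(weeks))
  tx <- if (i2 > i) (maternal_age - ages[i]) / (ages[i2] - ages[i]) else 0
  ty <- if (j2 > j) (gestational_age - weeks[j]) / (weeks[j2] - weeks[j]) else 0
  g <- table$risks
  p <- (1 - tx) * (1 - ty) * g[i, j] + tx * (1 - ty) * g[i2, j] +
       (1 - tx) * ty * g[i, j2] + tx * ty * g[i2, j2]
  prior_risk(p, source = "age_table")
}
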