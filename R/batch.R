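#' Scoring configuration
#'
#' Built-in defaults for batch scoring: per-chromosome CV defaults (0.5%
#' for chromosome 21, 0.4% for 13 and 18), the default fetal-fraction
#' mixture prior (see [ff_default()]), the advised bounds used to complete
#' a half-specified fetal-fraction range (1% and 23%), and the positive-call
#' threshold Z = 3. `read_config()` loads a flat YAML or JSON file whose
#' keys override these; anything not mentioned keeps its default.
#'
#' Recognised config keys: `cv_chr13`, `cv_chr18`, `cv_chr21`,
#' `z_threshold`, `ff_advised_low`, `ff_advised_high`, and `ff` - either
#' `{fixed: x}`, `{low: a, high: b}`, or
#' `{components: [{low, high, weight}, ...]}`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) config file.
#' @param ... named overrides of individual settings.
#' @return A list of effective settings with class `ppr_config`.
#' @examples
#' ppr_config()
#' ppr_config(cv_chr21 = 0.35)
#' @export
ppr_config <- function(...) {
  cfg <- list(
    cv_chr13 = 0.4, cv_chr18 = 0.4, cv_chr21 = 0.5,
    z_threshold = 3,
    ff_advised_low = 1, ff_advised_high = 23,
    ff_prior = ff_default()
  )
  apply_config_overrides(cfg, list(...))
}

#' @rdname ppr_config
#' @export
read_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  cfg <- apply_config_overrides(ppr_config(), vals)
  apply_config_overrides(cfg, list(...))
}

apply_config_overrides <- function(cfg, vals) {
  if (length(vals) == 0L) return(structure(cfg, class = "ppr_config"))
  known <- c("cv_chr13", "cv_chr18", "cv_chr21", "z_threshold",
             "ff_advised_low", "ff_advised_high", "ff", "ff_prior")
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  for (k in intersect(names(vals), known[known != "ff"])) cfg[[k]] <- vals[[k]]
  if (!is.null(vals$ff)) {
    ff <- vals$ff
    cfg$ff_prior <-
      if (!is.null(ff$fixed)) ff_fixed(ff$fixed)
      else if (!is.null(ff$components)) ff_mixture(as.data.frame(ff$components))
      else if (!is.null(ff$low)) ff_uniform(ff$low, ff$high)
      else stop("config key 'ff' must give 'fixed', 'low'/'high' or 'components'",
                call. = FALSE)
  }
  for (k in c("cv_chr13", "cv_chr18", "cv_chr21")) check_cv(cfg[[k]])
  structure(cfg, class = "ppr_config")
}

#' @export
print.ppr_config <- function(x, ...) {
  cat(sprintf("PPR scoring configuration: CV chr13 %g%%, chr18 %g%%, chr21 %g%%; threshold Z > %g\n",
              x$cv_chr13, x$cv_chr18, x$cv_chr21, x$z_threshold))
  print(x$ff_prior)
  invisible(x)
}

config_cv <- function(cfg, chromosome) {
  cfg[[paste0("cv_chr", check_chromosome(chromosome))]]
}

#' Read a sample table
#'
#' Loads a per-sample input table in TSV or CSV form. The delimiter is
#' sniffed from the header line (a tab wins over a comma) unless given.
#' Required columns: `sample_id`, `chromosome`, `z`. Optional columns:
#' `cv` (percent), `prior` (probability or `1:n`/`1/n` string),
#' `maternal_age` and `gestational_age` (the alternative prior pathway),
#' and `ff_low`/`ff_high` (fetal-fraction bounds, percent). Decimal points
#' only; no locale commas.
#'
#' @param path input file.
#' @param sep field separator; `NULL` (default) to sniff.
#' @return A data frame, one row per sample, with missing optional columns
#'   added as `NA`.
#' @export
read_samples <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          strip.white = TRUE)
  required <- c("sample_id", "chromosome", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  optional <- c("cv", "prior", "maternal_age", "gestational_age", "ff_low", "ff_high")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA_character_
  num_cols <- c("z", "cv", "maternal_age", "gestational_age", "ff_low", "ff_high")
  for (col in num_cols) {
    df[[col]][!nzchar(trimws(ifelse(is.na(df[[col]]), "", df[[col]])))] <- NA
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$prior[!is.na(df$prior) & !nzchar(trimws(df$prior))] <- NA
  df[c(required, optional)]
}

resolve_row_ff <- function(row, cfg) {
  has_lo <- !is.na(row$ff_low); has_hi <- !is.na(row$ff_high)
  if (!has_lo && !has_hi)
    return(list(ff = cfg$ff_prior, note = "ff: config default"))
  lo <- if (has_lo) row$ff_low else cfg$ff_advised_low
  hi <- if (has_hi) row$ff_high else cfg$ff_advised_high
  note <- if (has_lo && has_hi) NULL
          else sprintf("ff: missing %s bound filled with advised %g%%",
                       if (has_lo) "upper" else "lower", if (has_lo) hi else lo)
  ff <- if (lo == hi) ff_fixed(lo) else ff_uniform(lo, hi)
  list(ff = ff, note = note)
}

resolve_row_prior <- function(row, risk_tables) {
  has_prior <- !is.na(row$prior)
  has_age <- !is.na(row$maternal_age) && !is.na(row$gestational_age)
  if (has_prior && has_age)
    stop("both a prior and maternal/gestational age given; supply exactly one pathway")
  if (has_prior) return(parse_prior(row$prior, source = "fct"))
  if (!has_age)
    stop("no a priori risk: give 'prior' or both 'maternal_age' and 'gestational_age'")
  chrom <- as.character(check_chromosome(row$chromosome))
  tab <- risk_tables[[chrom]]
  if (is.null(tab))
    stop("age-based prior requested but no risk table supplied for chromosome ", chrom)
  interpolate_risk(tab, row$maternal_age, row$gestational_age)
}

#' Score a batch of samples
#'
#' Computes the posterior risk for every row of a sample table (see
#' [read_samples()] for the schema). Rows that fail validation are reported
#' in the `error` column with `NA` results, never dropped; row order is
#' preserved. Missing per-row CV or fetal-fraction settings fall back to
#' the configuration defaults and the fallback is noted in the output, so
#' every result is auditable. The output echoes the effective CV and
#' fetal-fraction settings used per row.
#'
#' @param samples data frame from [read_samples()], or a file path.
#' @param config a [ppr_config()] list.
#' @param risk_tables named list of [risk_table] objects keyed by
#'   chromosome (`"13"`, `"18"`, `"21"`), used for rows that give maternal
#'   and gestational age instead of a prior.
#' @return A data frame of class `ppr_batch` with one row per input row:
#'   `sample_id`, `chromosome`, `z`, `prior_probability`, `cv_used`,
#'   `ff_used` (human-readable description), `likelihood_ratio`, `ppr`
#'   (raw posterior), `ppr_display`, `note`, `error`. The attribute
#'   `n_errors` counts failed rows.
#' @examples
#' path <- system.file("extdata", "example_samples.tsv", package = "niptppr")
#' res <- run_batch(read_samples(path))
#' res[, c("sample_id", "z", "ppr_display")]
#' @export
run_batch <- function(samples, config = ppr_config(), risk_tables = NULL) {
  if (is.character(samples)) samples <- read_samples(samples)
  n <- nrow(samples)
  out <- data.frame(
    sample_id = samples$sample_id,
    chromosome = samples$chromosome,
    z = samples$z,
    prior_probability = NA_real_, cv_used = NA_real_, ff_used = NA_character_,
    likelihood_ratio = NA_real_, ppr = NA_real_, ppr_display = NA_character_,
    note = NA_character_, error = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    row <- samples[i, ]
    res <- tryCatch({
      chrom <- check_chromosome(row$chromosome)
      notes <- character(0)
      cv <- row$cv
      if (is.na(cv)) {
        cv <- config_cv(config, chrom)
        notes <- c(notes, sprintf("cv: config default %g", cv))
      }
      check_cv(cv)
      prior <- resolve_row_prior(row, risk_tables)
      ffres <- resolve_row_ff(row, config)
      notes <- c(notes, ffres$note)
      post <- posterior_risk(prior, check_z(row$z), ffres$ff, cv)
      list(chrom = chrom, cv = cv, prior = prior, ff = ffres$ff, post = post,
           note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$chromosome[i] <- res$chrom
      out$prior_probability[i] <- res$prior$probability
      out$cv_used[i] <- res$cv
      out$ff_used[i] <- describe_ff(res$ff)
      out$likelihood_ratio[i] <- res$post$likelihood_ratio
      out$ppr[i] <- res$post$ppr
      out$ppr_display[i] <- res$post$display_percent
      out$note[i] <- res$note
    }
  }
  n_err <- sum(!is.na(out$error))
  if (n_err > 0)
    message(n_err, " of ", n, " rows failed validation; see the 'error' column")
  structure(out, n_errors = n_err, class = c("ppr_batch", "data.frame"))
}

describe_ff <- function(ff) {
  co <- ff$components
  paste(vapply(seq_len(nrow(co)), function(i) {
    if (co$low[i] == co$high[i]) sprintf("fixed %g%%", co$low[i])
    else sprintf("U(%g,%g)%%*%g", co$low[i], co$high[i], co$weight[i])
  }, character(1)), collapse = " + ")
}

#' Write batch results
#'
#' Writes a [run_batch()] result as TSV (default) or CSV. Output is
#' deterministic: identical input and configuration give byte-identical
#' files.
#'
#' @param results data frame from [run_batch()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_results <- function(results, path, sep = "\t") {
  utils::write.table(results, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Posterior-risk grid over priors and Z-scores
#'
#' Evaluates the posterior risk on the cartesian grid of a priori risks and
#' observed Z-scores, in long format, for tabulating or plotting how the
#' posterior depends on the pre-test risk. The default axes are the twelve
#' priors from 0.0001 to 0.1 and Z-scores 2 to 6 in steps of 0.5 used to
#' illustrate the calculator.
#'
#' @param priors numeric vector of a priori risks (probabilities).
#' @param z_values numeric vector of observed Z-scores.
#' @param ff fetal-fraction prior (default: the unknown-fraction mixture).
#' @param cv_percent coefficient of variation, percent.
#' @return A data frame with columns `prior`, `z`, `ppr` (raw posterior
#'   probability), `ppr_percent` and `ppr_display`, ordered by prior then z.
#' @examples
#' generate_grid(priors = c(0.001, 0.01, 0.1), z_values = 3,
#'               ff = ff_fixed(4), cv_percent = 0.5)
#' @export
generate_grid <- function(priors = c(0.0001, 0.0002, 0.0005, 0.0010, 0.0015,
                                     0.0020, 0.0025, 0.0050, 0.0100, 0.0250,
                                     0.0500, 0.1000),
                          z_values = seq(2, 6, by = 0.5),
                          ff = ff_default(), cv_percent = 0.5) {
  if (length(priors) == 0L || length(z_values) == 0L)
    stop("grid axes must be non-empty", call. = FALSE)
  if (any(priors <= 0 | priors >= 1))
    stop("priors must be probabilities in (0, 1)", call. = FALSE)
  ff <- as_ff_prior(ff)
  grid <- expand.grid(z = z_values, prior = priors)[, c("prior", "z")]
  grid$ppr <- mapply(function(p, z) posterior_risk(p, z, ff, cv_percent)$ppr,
                     grid$prior, grid$z)
  grid$ppr_percent <- 100 * grid$ppr
  grid$ppr_display <- format_ppr(grid$ppr)
  rownames(grid) <- NULL
  grid
}

#' Plot a posterior-risk grid
#'
#' One curve of posterior risk (percent) against Z-score per a priori risk.
#'
#' @param grid data frame from [generate_grid()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_ppr_grid <- function(grid, ...) {
  wide <- stats::reshape(grid[c("prior", "z", "ppr_percent")],
                         idvar = "z", timevar = "prior", direction = "wide")
  wide <- wide[order(wide$z), ]
  priors <- sort(unique(grid$prior))
  graphics::matplot(wide$z, as.matrix(wide[-1]), type = "b", pch = 20, lty = 1,
                    xlab = "Observed Z-score", ylab = "Posterior risk (%)", ...)
  graphics::legend("topleft", legend = format_prior_vec(priors), lty = 1,
                   col = seq_along(priors), bty = "n", cex = 0.8)
  invisible(wide)
}

format_prior_vec <- function(p) vapply(p, function(x) format_prior(prior_risk(x)), character(1))
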