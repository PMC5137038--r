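# Independent numerical oracles, kept deliberately naive: the implementation
# must agree with these, never the other way around.

# composite trapezoid rule
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# brute-force marginal trisomy density: fine-grid trapezoid over each
# uniform component of the fetal-fraction prior
oracle_trisomy_density <- function(z, ff, cv_percent, n_nodes = 1e5) {
  co <- ff$components
  total <- 0
  for (i in seq_len(nrow(co))) {
    if (co$low[i] == co$high[i]) {
      total <- total + co$weight[i] * dnorm(z - (co$low[i] / 2) / cv_percent)
    } else {
      f <- seq(co$low[i], co$high[i], length.out = n_nodes)
      y <- dnorm(z - (f / 2) / cv_percent)
      total <- total + co$weight[i] * trapz(f, y) / (co$high[i] - co$low[i])
    }
  }
  total
}

# two-pass 1-D linear interpolation (rows first, then across) as an
# independent check of bilinear interpolation
oracle_bilinear <- function(tab, age, week) {
  along_week <- vapply(seq_along(tab$maternal_ages), function(i)
    approx(tab$gestational_ages, tab$risks[i, ], xout = week)$y, numeric(1))
  approx(tab$maternal_ages, along_week, xout = age)$y
}

example_samples_path <- function() {
  system.file("extdata", "example_samples.tsv", package = "niptppr")
}
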