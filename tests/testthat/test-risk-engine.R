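test_that("expected Z follows the signal-over-noise form and its monotonicities", {
  expect_equal(expected_z(6, 0.5), 6)
  expect_equal(expected_z(4, 0.5), 4)
  expect_equal(expected_z(4, 0.4), 5)
  # strictly increasing in f, strictly decreasing in CV
  f <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(expected_z(f, 0.5)) > 0))
  cvs <- seq(0.2, 1, by = 0.1)
  expect_true(all(diff(sapply(cvs, function(cv) expected_z(4, cv))) < 0))
  # vanishing foetal DNA gives a vanishing shift
  expect_lt(expected_z(1e-12, 0.5), 1e-11)
  expect_error(expected_z(0, 0.5), "positive")
  expect_error(expected_z(4, -1), "positive")
})

test_that("euploid Z-scores follow a standard normal density", {
  expect_equal(euploid_density(0), 1 / sqrt(2 * pi))
  expect_equal(euploid_density(3), dnorm(3))
  expect_equal(euploid_density(-3), euploid_density(3))
  expect_error(euploid_density(Inf), "finite")
})

test_that("fetal-fraction priors validate their components", {
  expect_equal(ff_fixed(4)$kind, "fixed")
  def <- ff_default()
  expect_equal(def$components$weight, c(0.4, 0.6))
  expect_equal(def$components$low, c(1, 6))
  expect_equal(def$components$high, c(23, 18))
  expect_error(ff_uniform(0, 10), "percentages")
  expect_error(ff_uniform(8, 4), "percentages")
  expect_error(ff_fixed(60), "percentages")
  expect_error(ff_mixture(data.frame(low = c(1, 6), high = c(23, 18),
                                     weight = c(0.5, 0.6))), "sum to 1")
  # numeric shortcuts
  expect_equal(trisomy_density(3, 4, 0.5), trisomy_density(3, ff_fixed(4), 0.5))
  expect_equal(trisomy_density(3, c(4, 8), 0.5),
               trisomy_density(3, ff_uniform(4, 8), 0.5))
})

test_that("trisomic density matches closed forms for a known fetal fraction", {
  expect_equal(trisomy_density(3, ff_fixed(4), 0.5), dnorm(3 - 4))
  # expected Z of 0 collapses onto the euploid density
  expect_equal(trisomy_density(0, ff_fixed(1e-9), 0.5), dnorm(0),
               tolerance = 1e-8)
  expect_error(trisomy_density(3, ff_fixed(4), 7), "outside")
  expect_error(trisomy_density(60, ff_fixed(4), 0.5), "sanity bound")
})

test_that("marginal trisomic density agrees with a fine-grid trapezoid oracle", {
  cases <- expand.grid(z = c(-2, 0, 2, 3, 4, 6, 10),
                       cv = c(0.3, 0.5))
  for (ff in list(ff_default(), ff_uniform(4, 8), ff_uniform(1, 23))) {
    for (k in seq_len(nrow(cases))) {
      z <- cases$z[k]; cv <- cases$cv[k]
      expect_equal(trisomy_density(z, ff, cv),
                   oracle_trisomy_density(z, ff, cv),
                   tolerance = 1e-6,
                   label = sprintf("density(z=%g, cv=%g)", z, cv))
    }
  }
})

test_that("marginal trisomic density integrates to 1", {
  for (ff in list(ff_fixed(4), ff_uniform(4, 8), ff_default())) {
    z_max <- max(ff$components$high) / (2 * 0.5)
    zs <- seq(-10, z_max + 10, length.out = 4001)
    dens <- vapply(zs, function(z) trisomy_density(z, ff, 0.5), numeric(1))
    expect_equal(trapz(zs, dens), 1, tolerance = 1e-6, label = ff$kind)
  }
})

test_that("a degenerate uniform range collapses onto the fixed-fraction result", {
  for (z in c(-1, 0, 2.5, 4)) {
    expect_equal(trisomy_density(z, ff_uniform(4, 4), 0.5),
                 trisomy_density(z, ff_fixed(4), 0.5), tolerance = 1e-9)
    # and a vanishingly narrow range converges to it
    expect_equal(trisomy_density(z, ff_uniform(4 - 1e-7, 4 + 1e-7), 0.5),
                 trisomy_density(z, ff_fixed(4), 0.5), tolerance = 1e-6)
  }
})

test_that("fixed-fraction likelihood ratio equals its exponential closed form", {
  set.seed(42)
  for (rep in 1:200) {
    z <- runif(1, -5, 30)
    z_exp <- runif(1, 0.1, 30)
    cv <- 0.5
    f <- 2 * z_exp * cv
    lr <- likelihood_ratio(z, ff_fixed(f), cv)
    expect_equal(lr, exp(z_exp * z - z_exp^2 / 2), tolerance = 1e-10,
                 label = sprintf("LR(z=%.3f, z_exp=%.3f)", z, z_exp))
  }
})

test_that("likelihood-ratio anchors hold", {
  expect_equal(likelihood_ratio(3, ff_fixed(4), 0.5), dnorm(1) / dnorm(3),
               tolerance = 1e-12)
  expect_equal(likelihood_ratio(2.5, ff_fixed(4), 0.5), dnorm(1.5) / dnorm(2.5),
               tolerance = 1e-12)
  # at half the expected Z the data are neutral
  for (f in c(2, 4, 8)) {
    z_exp <- expected_z(f, 0.5)
    expect_equal(likelihood_ratio(z_exp / 2, ff_fixed(f), 0.5), 1,
                 tolerance = 1e-12)
  }
  # extreme Z-scores where the euploid density underflows stay usable
  expect_true(is.finite(likelihood_ratio(28.8, ff_default(), 0.33)))
  expect_gt(likelihood_ratio(28.8, ff_default(), 0.33), 1e100)
})

test_that("posterior risk reproduces the worked screening examples", {
  # z = 3, 4% foetal DNA, CV 0.5: posteriors 5% / 36% / 86% across priors
  expect_equal(round(100 * posterior_risk("1:1000", 3, ff_fixed(4), 0.5)$ppr), 5)
  expect_equal(round(100 * posterior_risk("1:100", 3, ff_fixed(4), 0.5)$ppr), 36)
  expect_equal(round(100 * posterior_risk("1:10", 3, ff_fixed(4), 0.5)$ppr), 86)
  # borderline-negative case: z = 2.5 at high prior still leaves 45%
  expect_equal(round(100 * posterior_risk("1:10", 2.5, ff_fixed(4), 0.5)$ppr), 45)
})

test_that("posterior result is internally consistent and validates its prior", {
  res <- posterior_risk(0.01, 3.2, ff_default(), 0.5)
  p <- res$prior$probability
  expect_equal(res$ppr,
               p * res$likelihood_ratio / (p * res$likelihood_ratio + 1 - p),
               tolerance = 1e-12)
  expect_equal(res$likelihood_ratio,
               res$likelihood_trisomy / res$likelihood_diploid,
               tolerance = 1e-9)
  expect_error(posterior_risk(0, 3, ff_fixed(4), 0.5), "between 0 and 1|degenerate")
  expect_error(posterior_risk(1, 3, ff_fixed(4), 0.5), "between 0 and 1|degenerate")
})

test_that("posterior risk is strictly increasing in z and in the prior", {
  set.seed(7)
  for (ff in list(ff_fixed(4), ff_default())) {
    zs <- sort(runif(25, -3, 10))
    pprs <- vapply(zs, function(z) posterior_risk(0.01, z, ff, 0.5)$ppr, numeric(1))
    expect_true(all(diff(pprs) > 0), label = paste("monotone in z,", ff$kind))
    ps <- sort(runif(25, 1e-5, 1 - 1e-5))
    pprs <- vapply(ps, function(p) posterior_risk(p, 3, ff, 0.5)$ppr, numeric(1))
    expect_true(all(diff(pprs) > 0), label = paste("monotone in prior,", ff$kind))
  }
})

test_that("at half the expected Z the posterior equals the prior", {
  set.seed(11)
  for (rep in 1:50) {
    p <- runif(1, 1e-4, 0.5)
    f <- runif(1, 1, 20)
    cv <- runif(1, 0.2, 1)
    z_neutral <- expected_z(f, cv) / 2
    expect_equal(posterior_risk(p, z_neutral, ff_fixed(f), cv)$ppr, p,
                 tolerance = 1e-12)
  }
})

test_that("posteriors saturate for Z of 6 and above", {
  for (p in c(0.001, 0.01, 0.1)) {
    for (z in c(6, 8, 12)) {
      expect_gt(posterior_risk(p, z, ff_default(), 0.5)$ppr, 0.99)
      expect_gt(posterior_risk(p, z, ff_default(), 0.4)$ppr, 0.99)
    }
  }
})

test_that("sensitivity analytics match their normal-theory anchors", {
  expect_equal(round(100 * nipt_sensitivity(6, 0.5), 2), 99.87)
  expect_equal(round(100 * nipt_sensitivity(4, 0.5), 2), 84.13)
  expect_equal(nipt_sensitivity(3, 0.5, z_threshold = 3), 0.5)  # mean on the cutoff
  # strictly increasing in f until pnorm saturates in double precision
  expect_true(all(diff(nipt_sensitivity(1:8, 0.5)) > 0))
  expect_true(all(diff(nipt_sensitivity(1:20, 0.5)) >= 0))
  expect_gt(nipt_sensitivity(4, 0.3), nipt_sensitivity(4, 0.5))
  expect_gt(nipt_sensitivity(4, 0.5, 2.5), nipt_sensitivity(4, 0.5, 3))

  expect_equal(round(required_cv(4, pnorm(3)), 2), 0.33)
  expect_equal(required_cv(6, pnorm(3)), 0.5)
  # limit: barely-above-chance target needs only the threshold distance
  expect_equal(required_cv(4, 0.5 + 1e-12), (4 / 2) / 3, tolerance = 1e-9)
  expect_error(required_cv(4, 0.4), "0.5")
  # inversion round-trip
  for (target in c(0.9, 0.99, pnorm(3))) {
    cv <- required_cv(5, target)
    expect_equal(nipt_sensitivity(5, cv), target, tolerance = 1e-9)
  }

  expect_equal(round(100 * euploid_central_coverage(3), 1), 99.7)
  expect_equal(euploid_central_coverage(0), 0)
  expect_equal(euploid_central_coverage(qnorm(0.975)), 0.95, tolerance = 1e-6)
})

test_that("clinical display rounds to integer percent with floor and cap", {
  expect_equal(format_ppr(c(0.0004, 0.005, 0.014, 0.36, 0.994, 0.9999)),
               c("<0.1", "<1", "1", "36", "99", "99.9"))
  expect_equal(format_ppr(1), "99.9")   # certainty is never displayed
  expect_equal(format_ppr(0), "<0.1")
  expect_error(format_ppr(1.2), "probabilities")
})

test_that("assay profiles carry per-chromosome defaults and reject unit errors", {
  expect_equal(assay_profile(21)$cv_percent, 0.5)
  expect_equal(assay_profile(13)$cv_percent, 0.4)
  expect_equal(assay_profile(18)$cv_percent, 0.4)
  expect_equal(assay_profile("chr21")$chromosome, 21L)
  expect_error(assay_profile(22), "13, 18, 21")
  expect_error(assay_profile(21, cv_percent = 5), "check units")
  expect_error(assay_profile(21, cv_percent = 0.005 * 100 + 4.5), "check units")
  expect_error(assay_profile(21, z_threshold = -1), "positive")
})
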