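test_that("noiseless 4PL data are recovered and degenerate inputs handled", {
  conc <- 10^seq(-1, 3)
  truth <- list(bottom = 0, top = 80, log10_ec50 = 1, hill = 1)
  y <- plexscreen:::fourpl_curve(log10(conc), truth$bottom, truth$top,
                                 truth$log10_ec50, truth$hill)
  fit <- fit_4pl(conc, y)
  expect_equal(fit$bottom, truth$bottom, tolerance = 1e-4)
  expect_equal(fit$top, truth$top, tolerance = 1e-4)
  expect_equal(fit$log10_ec50, truth$log10_ec50, tolerance = 1e-4)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-4)
  # flat zero responses: degenerate fit with zero slope, DSS 0 downstream
  expect_warning(flat <- fit_4pl(conc, rep(0, 5)), "flat")
  expect_true(flat$flat)
  expect_equal(flat$top, 0)
  expect_equal(dss(flat, c(-1, 3)), 0)
  expect_error(fit_4pl(rev(conc), y), class = "plex_validation_error")
  expect_error(fit_4pl(conc[1:3], y[1:3]), class = "plex_validation_error")
})

test_that("DSS matches a 10,000-point integration oracle and its bounds", {
  conc <- 10^seq(-1, 3)
  fit <- fit_4pl(conc, plexscreen:::fourpl_curve(log10(conc), 0, 80, 1, 1))
  d <- dss(fit, c(-1, 3))
  expect_equal(d, oracle_dss(fit, c(-1, 3)), tolerance = 0.1)
  expect_gte(d, 0); expect_lte(d, 100)
  # a curve pinned at 100 over the whole range scores exactly 100
  sat <- structure(list(bottom = 100, top = 100, log10_ec50 = 0, hill = 0,
                        flat = TRUE), class = "fourpl")
  expect_equal(dss(sat, c(-1, 3)), 100)
  # below-threshold curves score 0
  low <- structure(list(bottom = 5, top = 5, log10_ec50 = 0, hill = 0,
                        flat = TRUE), class = "fourpl")
  expect_equal(dss(low, c(-1, 3)), 0)
  # monotonicity: a uniformly higher curve never scores lower
  f_lo <- fit_4pl(conc, plexscreen:::fourpl_curve(log10(conc), 0, 60, 1, 1))
  f_hi <- fit_4pl(conc, plexscreen:::fourpl_curve(log10(conc), 0, 90, 1, 1))
  expect_gte(dss(f_hi, c(-1, 3)), dss(f_lo, c(-1, 3)))
  # unit invariance: shifting the concentration unit shifts the range only
  fit2 <- fit_4pl(conc * 1000,
                  plexscreen:::fourpl_curve(log10(conc), 0, 80, 1, 1))
  expect_equal(dss(fit2, c(2, 6)), d, tolerance = 1e-3)
})

test_that("percentile cutoffs use the (n-1)p+1 interpolation convention", {
  expect_equal(dss_cutoff(c(1, 2, 3, 4), 75), 3.25)
  expect_equal(dss_cutoff(rep(7, 5), 75), 7)
  expect_equal(dss_cutoff(c(3, 9, 1, 5), 100), 9)
  expect_error(dss_cutoff(numeric(0)), class = "plex_validation_error")
})

test_that("exact rank-sum test reproduces the complete-separation p-value", {
  # 3 vs 5, every a above every b: 2/56
  res <- exact_wilcoxon(c(10, 11, 12), c(1, 2, 3, 4, 5))
  expect_equal(res$p, 2 / 56)
  expect_equal(round(res$p, 3), 0.036)
  expect_equal(exact_wilcoxon(1, 2)$p, 1)
})

test_that("exact rank-sum matches full enumeration for all small cases", {
  set.seed(17)
  for (na in 1:4) for (nb in 1:5) {
    a <- rnorm(na); b <- rnorm(nb)               # continuous: no ties
    expect_equal(exact_wilcoxon(a, b)$p, oracle_wilcoxon_p(a, b),
                 info = sprintf("no ties na=%d nb=%d", na, nb))
    a2 <- sample(1:3, na, replace = TRUE)        # heavy ties
    b2 <- sample(1:3, nb, replace = TRUE)
    expect_equal(exact_wilcoxon(a2, b2)$p, oracle_wilcoxon_p(a2, b2),
                 info = sprintf("ties na=%d nb=%d", na, nb))
  }
  # agreement with the classical distribution where R is exact
  w <- wilcox.test(c(9, 12, 14), c(1, 3, 5, 7), exact = TRUE)
  expect_equal(exact_wilcoxon(c(9, 12, 14), c(1, 3, 5, 7))$p, w$p.value)
})

test_that("group DSS comparison averages the drug subset per sample", {
  m <- matrix(c(20, 22, 24, 21, 23, 25, 5, 6, 7, 4, 8, 9, 3, 7, 8, 2),
              2, 8, dimnames = list(c("egfri1", "egfri2"), paste0("s", 1:8)))
  labs <- setNames(rep(c("high", "low"), c(3, 5)), paste0("s", 1:8))
  res <- group_dss_comparison(m, labs, c("egfri1", "egfri2"))
  expect_equal(res$sample_means, colMeans(m))
  # 3 high samples all above the 5 low ones: the 0.036 configuration
  expect_equal(round(res$p, 3), 0.036)
  # identical groups give p = 1 under mid-ranks
  m2 <- matrix(5, 2, 4, dimnames = list(c("d1", "d2"), paste0("s", 1:4)))
  labs2 <- setNames(rep(c("x", "y"), 2), paste0("s", 1:4))
  expect_equal(group_dss_comparison(m2, labs2, c("d1", "d2"))$p, 1)
  # single-drug subset mean equals that drug's DSS
  res1 <- group_dss_comparison(m, labs, "egfri1")
  expect_equal(res1$sample_means, m["egfri1", ])
  expect_error(group_dss_comparison(m, labs, character()),
               class = "plex_validation_error")
})

test_that("dss_matrix fits and integrates a generated panel", {
  drugs <- c("drugA", "drugB")
  tr <- make_fourpl_truths(drugs, seed = 2)
  panel <- generate_dose_response(tr, noise_sd = 0, seed = 1)
  m <- dss_matrix(panel)
  expect_equal(dim(m), c(2, 1))
  # noiseless panel: DSS equals the truth curve's oracle area
  for (i in 1:2) {
    fit <- structure(list(bottom = tr$bottom[i], top = tr$top[i],
                          log10_ec50 = tr$log10_ec50[i], hill = tr$hill[i],
                          flat = FALSE), class = "fourpl")
    expect_equal(m[drugs[i], 1], oracle_dss(fit, c(-1, 3)), tolerance = 0.5)
  }
})
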