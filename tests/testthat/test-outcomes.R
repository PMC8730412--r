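test_that("rank-sum comparison matches exact enumeration and handles identity", {
  cc <- compare_continuous(c(1, 2, 3), c(10, 11, 12))
  expect_equal(cc$p, 0.1)                      # 2 / C(6,3) extreme arrangements
  expect_equal(cc$p, ranksum_exact_oracle(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(cc$median_A, 2)
  expect_equal(cc$iqr_B, unname(quantile(c(10, 11, 12), c(0.25, 0.75))))

  same <- compare_continuous(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(same$p, 0.9)
  expect_error(compare_continuous(c(NA_real_, NA_real_), 1:3), "non-missing")
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(41)
  a <- rnorm(30, 0, 1)
  b <- rnorm(25, 0.7, 1)
  p0 <- compare_continuous(a, b)$p
  expect_equal(compare_continuous(exp(a), exp(b))$p, p0)
  expect_equal(compare_continuous(a^3, b^3)$p, p0)
})

test_that("rank-sum rejection rate under a 1-SD shift tracks a side-by-side simulation", {
  set.seed(42)
  n_rep <- 400
  rej <- rej_oracle <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- rnorm(30)
    b <- rnorm(30, 1)
    rej[r] <- compare_continuous(a, b)$p < 0.05
    rej_oracle[r] <- wilcox.test(a, b, exact = FALSE)$p.value < 0.05
  }
  expect_lt(abs(mean(rej) - mean(rej_oracle)), 0.05)
  expect_gt(mean(rej), 0.8)  # 1-SD shift at n=30/30 is high power
})

test_that("categorical comparison reproduces the printed cohort p-values", {
  sex <- rbind(c(31, 29), c(28, 7))          # male/female x HIE/CHD
  p_sex <- compare_categorical(sex)
  expect_lt(p_sex, 0.01)
  expect_equal(as.numeric(p_sex), fisher_oracle_2x2(sex), tolerance = 1e-9)
  expect_equal(attr(p_sex, "method"), "fisher")

  inj <- rbind(c(20, 40), c(13, 22))         # injury yes/no x HIE/CHD
  expect_equal(round(as.numeric(compare_categorical(inj)), 2), 0.82)

  flat <- rbind(c(10, 10), c(10, 10))
  expect_equal(as.numeric(compare_categorical(flat)), 1)
  expect_error(compare_categorical(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  tab <- rbind(c(12, 5), c(3, 9))
  p0 <- as.numeric(compare_categorical(tab))
  expect_equal(as.numeric(compare_categorical(t(tab))), p0)
  expect_equal(as.numeric(compare_categorical(tab[2:1, ])), p0)
  expect_equal(as.numeric(compare_categorical(tab[, 2:1])), p0)
})

test_that("count-percentage formatting matches the cohort table conventions", {
  expect_equal(fmt_count_pct(28, 35), "28 (80.0%)")
  expect_equal(fmt_count_pct(31, 60), "31 (51.7%)")
  expect_equal(fmt_count_pct(40, 60), "40 (66.7%)")
  expect_equal(fmt_count_pct(0, 12), "0 (0.0%)")
})

test_that("demographics table compares both cohorts per variable", {
  set.seed(43)
  subj <- data.frame(
    cohort = rep(c("HIE", "CHD"), c(20, 15)),
    male = c(rbinom(20, 1, 0.5), rbinom(15, 1, 0.8)) == 1,
    injury_on_mri = rbinom(35, 1, 0.35) == 1,
    ga_birth = rnorm(35, 39.5, 1),
    ga_mri = rnorm(35, 40.2, 1),
    birth_weight = rnorm(35, 3.3, 0.4))
  tab <- demographics_table(subj)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_match(tab$stat_A[tab$variable == "male"], "^\\d+ \\(\\d+\\.\\d%\\)$")
})

test_that("univariate screen recovers noiseless slopes and reports categorical F tests", {
  d <- data.frame(y = 2 * (1:20) + 1, x = 1:20,
                  grp = factor(rep(c("a", "b", "c", "d"), 5)))
  sc <- suppressWarnings(univariate_screen(d, "y", c("x", "grp")))  # perfect fit warns
  xrow <- sc[sc$predictor == "x", ]
  expect_equal(xrow$estimate, 2, tolerance = 1e-10)
  expect_lt(xrow$p, 1e-10)
  expect_true("x" %in% attr(sc, "selected"))
  grows <- sc[sc$predictor == "grp", ]
  expect_equal(nrow(grows), 3)                   # k-1 dummy terms
  expect_length(unique(grows$overall_p), 1)      # one overall F p
  # constant predictor skipped with warning (noisy outcome so the only
  # warning is the skip itself)
  set.seed(48)
  dn <- data.frame(y = rnorm(20), x = rnorm(20), z = 1)
  expect_warning(univariate_screen(dn, "y", c("x", "z")), "constant")
})

test_that("screen at p<0.1 selects an independent predictor about 10% of the time", {
  set.seed(44)
  hits <- vapply(1:500, function(r) {
    d <- data.frame(y = rnorm(40), x = rnorm(40))
    "x" %in% attr(univariate_screen(d, "y", "x"), "selected")
  }, logical(1))
  expect_gt(mean(hits), 0.06)
  expect_lt(mean(hits), 0.145)
})

test_that("multivariate model recovers noiseless coefficients exactly and drops GA at birth", {
  set.seed(45)
  n <- 50
  d <- data.frame(lge = rnorm(n, -1.7, 0.1), ga_mri = rnorm(n, 40, 1),
                  sexf = rbinom(n, 1, 0.5))
  d$ga_birth <- d$ga_mri - 0.7
  d$y <- 170 + 43.7 * d$lge + 7 * d$sexf - 1 * d$ga_mri
  expect_message(
    mm <- suppressWarnings(multivariate_metric_model(
      d, "y", "lge", covariates = c("sexf", "ga_birth"))),
    "collinear with corrected gestational age")
  expect_equal(mm$estimate[mm$term == "lge"], 43.7, tolerance = 1e-8)
  expect_false("ga_birth" %in% mm$term)
  expect_true("ga_mri" %in% mm$term)
  expect_true(all(mm$ci_low <= mm$estimate & mm$estimate <= mm$ci_high))

  # duplicated column => rank deficiency names the culprit
  d$lge2 <- d$lge
  expect_error(multivariate_metric_model(d, "y", "lge", covariates = "lge2"),
               "collinear")
})

test_that("slope equivariance under affine predictor rescaling", {
  set.seed(46)
  d <- data.frame(x = rnorm(30), e = rnorm(30))
  d$y <- 3 * d$x + d$e
  s1 <- univariate_screen(d, "y", "x")$estimate[1]
  d$x10 <- 10 * d$x + 5
  s10 <- univariate_screen(d, "y", "x10")$estimate[1]
  expect_equal(s10, s1 / 10, tolerance = 1e-10)
})

test_that("tract regression grid has the 5 x 4 shape and flags constant scores", {
  set.seed(47)
  n <- 30
  d <- data.frame(SLF1 = rnorm(n, 0.3, 0.03), SLF2 = rnorm(n, 0.25, 0.03),
                  SLF3 = rnorm(n, 0.27, 0.03), ILF = rnorm(n, 0.2, 0.03),
                  AF = rnorm(n, 0.25, 0.03),
                  language_12_18 = rnorm(n, 100, 12),
                  language_30 = rnorm(n, 98, 12),
                  expressive_30 = rnorm(n, 10, 3),
                  receptive_30 = rnorm(n, 10, 3))
  gr <- tract_regressions(d)
  expect_equal(nrow(gr), 20)
  expect_true(all(gr$estimable))
  d$SLF1 <- 0.3
  gr2 <- tract_regressions(d)
  expect_false(any(gr2$estimable[gr2$tract == "SLF1"]))
  expect_true(all(is.na(gr2$estimate[gr2$tract == "SLF1"])))
})

test_that("planted negative SLF2-expressive effect is recovered in direction", {
  # scaled-up cohorts: at the study's follow-up size the per-replicate power
  # for sign recovery of a -5.2 point/FA-unit effect is only ~0.65. The
  # direct cohort effect on expressive language is zeroed so the univariate
  # regression measures the planted tract effect rather than its sum with
  # cohort confounding (CHD scans earlier, hence lower SLF2 FA).
  cfg <- default_scenario()
  cfg$n_hie <- 1200L
  cfg$n_chd <- 800L
  cfg$followup_frac_12_18 <- c(hie = 1, chd = 1)
  cfg$followup_frac_30 <- c(hie = 1, chd = 1)
  cfg$outcome_model$coef_cohort_expressive <- 0
  neg <- vapply(1:10, function(r) {
    sim <- simulate_cohort(cfg, seed = 5000 + r)
    ts <- tract_score_table(sim$connectomes)
    oc30 <- sim$outcomes[sim$outcomes$timepoint == "30 months",
                         c("subject_id", "expressive")]
    names(oc30)[2] <- "expressive_30"
    d <- merge(ts, oc30, by = "subject_id")
    gr <- tract_regressions(d, outcomes = "expressive_30")
    gr$estimate[gr$tract == "SLF2"] < 0
  }, logical(1))
  expect_gte(mean(neg), 0.9)
})

test_that("noiseless screens warn about perfect fits without breaking output", {
  d <- data.frame(y = 2 * (1:20) + 1, x = 1:20)
  w <- capture_warnings(sc <- univariate_screen(d, "y", "x"))
  expect_match(w, "perfect", all = FALSE)
  expect_equal(sc$estimate[1], 2, tolerance = 1e-10)
})
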