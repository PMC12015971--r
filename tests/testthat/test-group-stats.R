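test_that("severity strata follow the NIS-LL bands", {
  g <- c("HC", "ATTRv", "ATTRv", "ATTRv", "ATTRv")
  s <- severity_stratum(g, c(0, 5, 20, 21, 70))
  expect_equal(as.character(s), c("HC", "mild", "mild", "moderate_severe",
                                  "moderate_severe"))
  s4 <- severity_stratum(g, c(0, 5, 20, 21, 70), pool_moderate_severe = FALSE)
  expect_equal(as.character(s4), c("HC", "mild", "mild", "moderate", "severe"))
})

test_that("correlations recover exact monotone relationships", {
  d <- data.frame(x = seq(-2, 2, length.out = 20))
  d$lin <- 2 * d$x + 1
  d$mono <- exp(d$x)
  expect_equal(correlate(d, x, lin)$estimate, 1, tolerance = 1e-12)
  expect_equal(correlate(d, x, mono, method = "spearman")$estimate, 1)
  expect_lt(correlate(d, x, mono, method = "pearson")$estimate, 1)
  d$flat <- 5
  expect_error(correlate(d, x, flat), "Zero variance")
  expect_error(correlate(d[1:3, ], x, lin), "at least 4")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(40)
  maps <- list(function(z) z^3, function(z) exp(z), function(z) atan(z),
               function(z) 5 * z - 2)
  for (i in seq_along(maps)) {
    d <- data.frame(x = rnorm(50), e = rnorm(50))
    d$y <- d$x + 0.5 * d$e
    base <- correlate(d, x, y, method = "spearman")$estimate
    d$y2 <- maps[[i]](d$y)
    expect_equal(correlate(d, x, y2, method = "spearman")$estimate, base)
  }
})

test_that("partial correlation removes a shared covariate signal", {
  set.seed(41)
  n <- 300
  d <- data.frame(age = rnorm(n, 60, 8), sex = sample(c("M", "F"), n, TRUE))
  d$x <- 0.5 * d$age + rnorm(n)
  d$y <- 0.5 * d$age + rnorm(n)
  raw <- correlate(d, x, y)$estimate
  part <- correlate(d, x, y, covariates = c("age", "sex"))$estimate
  expect_gt(raw, 0.8)
  expect_lt(abs(part), 0.15)
})

test_that("adjusted comparison attributes covariate-driven signal correctly", {
  set.seed(42)
  n <- 60
  d <- data.frame(group = rep(c("ATTRv", "HC"), each = n / 2),
                  age = rnorm(n, 60, 8),
                  sex = sample(c("M", "F"), n, TRUE))
  # measure fully explained by age, no group effect
  d$m <- 1 * d$age
  res <- suppressWarnings(adjusted_group_comparison(d, m))
  expect_equal(res$r_model, 1, tolerance = 1e-9)
  expect_lt(abs(res$estimate), 1e-9)

  # equal groups with noise: no significant group term
  d$m2 <- rnorm(n)
  res2 <- adjusted_group_comparison(d, m2)
  expect_gt(res2$p_value, 0.05)

  # singular design is reported, not silently dropped
  d$sex <- "M"
  expect_error(adjusted_group_comparison(d, m2), "Singular design")
})

test_that("with no covariates the adjusted model reduces to the pooled t-test", {
  set.seed(43)
  d <- data.frame(group = rep(c("ATTRv", "HC"), c(12, 15)),
                  m = rnorm(27, 10, 2))
  res <- adjusted_group_comparison(d, m, covariates = character())
  tt <- t.test(m ~ I(group == "HC"), data = d, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(abs(res$estimate), abs(diff(tt$estimate)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("two-sample tests behave at the null and under separation", {
  set.seed(44)
  d <- data.frame(group = rep(c("ATTRv", "HC"), each = 30))
  d$m <- rnorm(60)
  d$m[d$group == "ATTRv"] <- d$m[d$group == "HC"]  # identical groups
  res <- two_sample_tests(d, m)
  expect_gt(res$p_value[res$test == "welch_t"], 0.9)
  u <- res$statistic[res$test == "mann_whitney_u"]
  expect_lt(abs(u - 30 * 30 / 2) / (30 * 30 / 2), 0.1)

  d$m[d$group == "ATTRv"] <- d$m[d$group == "ATTRv"] + 5  # 5 sd shift
  res2 <- two_sample_tests(d, m)
  expect_true(all(res2$p_value < 1e-6))
})

test_that("the one-tailed CSA test has majority power at the study sizes", {
  # truth-level simulation at the calibrated group distributions
  set.seed(45)
  rejections <- vapply(1:1000, function(i) {
    x <- rnorm(18, 49.32, 19.63)
    y <- rnorm(21, 37.89, 12.92)
    t.test(x, y, alternative = "greater")$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("Dunn pairwise statistics match a brute-force rank-sum oracle", {
  brute_dunn_z <- function(x, g, a, b) {
    # midranks by explicit counting
    r <- vapply(x, function(xi) 1 + sum(x < xi) + (sum(x == xi) - 1) / 2,
                numeric(1))
    n <- length(x)
    ties <- 0
    for (v in unique(x)) {
      t <- sum(x == v)
      ties <- ties + (t^3 - t)
    }
    vterm <- (n * (n + 1) / 12 - ties / (12 * (n - 1))) *
      (1 / sum(g == a) + 1 / sum(g == b))
    (sum(r[g == a]) / sum(g == a) - sum(r[g == b]) / sum(g == b)) / sqrt(vterm)
  }
  set.seed(46)
  for (rep in 1:5) {
    sizes <- sample(3:8, 3, replace = TRUE)
    g <- rep(c("A", "B", "C"), sizes)
    x <- round(rnorm(sum(sizes)), 1)  # rounding forces ties
    res <- dunn_test(data.frame(x = x, g = g), x, g)
    expect_equal(res$z[res$contrast == "A - B"], brute_dunn_z(x, g, "A", "B"),
                 tolerance = 1e-12)
    expect_equal(res$z[res$contrast == "B - C"], brute_dunn_z(x, g, "B", "C"),
                 tolerance = 1e-12)
  }
})

test_that("severity analysis separates ordered strata with consistent signs", {
  set.seed(47)
  d <- data.frame(
    severity = factor(rep(c("HC", "mild", "moderate_severe"), each = 12),
                      levels = c("HC", "mild", "moderate_severe")),
    m = c(rnorm(12, 14.74, 0.01), rnorm(12, 17.51, 0.01), rnorm(12, 21.33, 0.01)))
  sev <- severity_anova(d, m)
  expect_lt(sev$omnibus$p_value, 1e-6)
  expect_true(all(sev$pairwise$p_value < 0.05))
  z <- setNames(sev$pairwise$z, sev$pairwise$contrast)
  expect_lt(z[["HC - mild"]], 0)
  expect_lt(z[["HC - moderate_severe"]], 0)
  expect_lt(z[["mild - moderate_severe"]], 0)
  expect_error(severity_anova(d[d$severity != "mild", ], m), "3 non-empty strata")
})

test_that("omnibus p-values are uniform under permuted stratum labels", {
  set.seed(48)
  pvals <- vapply(1:300, function(i) {
    d <- data.frame(severity = sample(rep(c("HC", "mild", "moderate_severe"),
                                          each = 8)),
                    m = rnorm(24))
    severity_anova(d, m)$omnibus$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("exclusions conserve counts and invalid flags are rejected", {
  cohort <- tibble::tibble(subject_id = sprintf("P%03d", 1:20),
                           group = "ATTRv", v = rnorm(20))
  kept <- suppressMessages(exclude_subjects(cohort, c("P003", "P017")))
  expect_equal(nrow(kept), 18)
  expect_equal(nrow(attr(kept, "exclusion_log")), 2)
  none <- suppressMessages(exclude_subjects(cohort, character()))
  expect_equal(nrow(none), nrow(cohort))
  expect_equal(none$subject_id, cohort$subject_id)
  expect_error(exclude_subjects(cohort, "P999"), "Unknown subject")
})

test_that("the full stat report refuses a single-group analysis set", {
  cohort <- tibble::tibble(subject_id = sprintf("C%03d", 1:10), group = "HC")
  expect_error(cohort_stat_report(cohort), "both ATTRv and HC")
})
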