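#' Severity stratum from the NIS-LL score
#'
#' Maps subjects to the severity strata used in the three-group
#' analysis: healthy controls form their own stratum, and patients are
#' banded by NIS-LL as mild (1-20), moderate (21-61) or severe (62-88).
#' By default moderate and severe are pooled into one stratum, matching
#' the study's moderate/severe group.
#'
#' @param group Character vector, `"ATTRv"` or `"HC"` per subject.
#' @param nis_ll Numeric NIS-LL scores (0-88).
#' @param pool_moderate_severe Pool moderate and severe into
#'   `"moderate_severe"` (default `TRUE`).
#' @return Ordered factor of strata.
#' @examples
#' severity_stratum(c("HC", "ATTRv", "ATTRv"), c(0, 10, 40))
#' @export
severity_stratum <- function(group, nis_ll, pool_moderate_severe = TRUE) {
  band <- dplyr::case_when(
    group == "HC" ~ "HC",
    nis_ll <= 20 ~ "mild",
    nis_ll <= 61 ~ "moderate",
    TRUE ~ "severe"
  )
  if (pool_moderate_severe) {
    band[band %in% c("moderate", "severe")] <- "moderate_severe"
    factor(band, levels = c("HC", "mild", "moderate_severe"), ordered = TRUE)
  } else {
    factor(band, levels = c("HC", "mild", "moderate", "severe"), ordered = TRUE)
  }
}

group_factor <- function(g) factor(as.character(g), levels = c("HC", "ATTRv"))

#' Covariate-adjusted two-group comparison
#'
#' Fits `measure ~ group + covariates` by least squares and reports the
#' group effect (ATTRv minus HC), its p-value, the model's multiple
#' correlation coefficient `R = sqrt(R^2)`, and the partial correlation
#' between the measure and group membership given the covariates (both
#' are reported because published "R controlling for ..." values can be
#' either).
#'
#' @param data Cohort tibble with one row per subject.
#' @param measure Measure column (bare name or string).
#' @param covariates Character vector of adjustment covariates
#'   (default `c("age", "sex")`).
#' @param group_col Name of the group column (levels `HC`/`ATTRv`).
#' @return One-row tibble: `measure`, `contrast`, `estimate` (adjusted
#'   ATTRv - HC difference), `statistic`, `p_value`, `r_model`,
#'   `r_partial`, `n`, `covariates`. The fitted `lm` is in
#'   `attr(, "fit")`.
#' @export
adjusted_group_comparison <- function(data, measure,
                                      covariates = c("age", "sex"),
                                      group_col = "group") {
  measure <- as_string(ensym(measure))
  need <- c(measure, group_col, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[need]), need, drop = FALSE]
  d$.group <- group_factor(d[[group_col]])
  if (any(table(d$.group) < 3)) abort("Need at least 3 subjects per group.")
  adj <- if (length(covariates)) covariates else "1"
  for (cv in covariates) {
    if (!is.numeric(d[[cv]]) && length(unique(d[[cv]])) < 2) {
      abort(sprintf("Singular design: covariate '%s' is constant (e.g. single-sex cohort).", cv))
    }
  }
  fml <- stats::reformulate(c(".group", covariates, "1"), response = measure)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    abort("Singular design: a covariate is confounded (e.g. single-sex cohort).")
  }
  sm <- summary(fit)
  row <- grep("^\\.groupATTRv", rownames(sm$coefficients))
  ## partial correlation of measure with group given covariates
  rx <- resid(lm(stats::reformulate(adj, response = measure), data = d))
  d$.g01 <- as.numeric(d$.group == "ATTRv")
  rg <- resid(lm(stats::reformulate(adj, response = ".g01"), data = d))
  out <- tibble(
    measure = measure,
    contrast = "ATTRv - HC",
    estimate = sm$coefficients[row, "Estimate"],
    statistic = sm$coefficients[row, "t value"],
    p_value = sm$coefficients[row, "Pr(>|t|)"],
    r_model = sqrt(sm$r.squared),
    r_partial = cor(rx, rg),
    n = nrow(d),
    covariates = paste(covariates, collapse = "+")
  )
  attr(out, "fit") <- fit
  out
}

#' Welch t and Mann-Whitney U comparison of the two groups
#'
#' Runs both a Welch (unequal-variance) two-sample t-test and a
#' Mann-Whitney U test of ATTRv versus HC on one measure, as the study
#' applied "as appropriate". The alternative is configurable; the
#' study's CSA comparison was one-tailed with patients larger
#' (`alternative = "greater"`).
#'
#' @param data Cohort tibble.
#' @param measure Measure column (bare name or string).
#' @param alternative `"two.sided"`, `"greater"` (ATTRv > HC) or
#'   `"less"`.
#' @param group_col Name of the group column.
#' @return Two-row tibble (one per test): `measure`, `test`,
#'   `estimate` (ATTRv - HC mean difference for the t-test, U statistic
#'   otherwise in `statistic`), `statistic`, `p_value`, `n_attrv`,
#'   `n_hc`, `alternative`.
#' @export
two_sample_tests <- function(data, measure, alternative = "two.sided",
                             group_col = "group") {
  measure <- as_string(ensym(measure))
  g <- group_factor(data[[group_col]])
  x <- data[[measure]][g == "ATTRv"]
  y <- data[[measure]][g == "HC"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("Need at least 2 subjects per group.")
  tt <- t.test(x, y, alternative = alternative, var.equal = FALSE)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative, exact = FALSE))
  tibble(
    measure = measure,
    test = c("welch_t", "mann_whitney_u"),
    estimate = c(unname(tt$estimate[1] - tt$estimate[2]), NA_real_),
    statistic = c(unname(tt$statistic), unname(wt$statistic)),
    p_value = c(tt$p.value, wt$p.value),
    n_attrv = length(x),
    n_hc = length(y),
    alternative = alternative
  )
}

#' Dunn's rank-based pairwise post hoc test
#'
#' Dunn's z-tests on all pairs of groups: pooled mid-ranks, pairwise
#' standardized mean-rank differences with the tie-corrected variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/ni + 1/nj)`, and two-sided
#' normal p-values, optionally Holm-adjusted.
#'
#' @param data Data frame.
#' @param value Numeric outcome column (bare name or string).
#' @param group Grouping column (bare name or string).
#' @param p_adjust `"none"` (default; the study reported unadjusted post
#'   hoc p-values) or `"holm"`.
#' @return Tibble with one row per pair: `contrast`, `z`,
#'   `mean_rank_diff`, `p_value`, `p_adjusted`, `n1`, `n2`.
#' @export
dunn_test <- function(data, value, group, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  value <- as_string(ensym(value))
  group <- as_string(ensym(group))
  d <- data[complete.cases(data[c(value, group)]), c(value, group)]
  g <- factor(d[[group]])
  if (nlevels(g) < 2) abort("Dunn test needs at least 2 non-empty groups.")
  x <- d[[value]]
  n <- length(x)
  r <- rank(x)
  tie_sizes <- table(x)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  mean_ranks <- tapply(r, g, mean)
  sizes <- table(g)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    tibble(contrast = paste(i, "-", j),
           z = z, mean_rank_diff = mean_ranks[[i]] - mean_ranks[[j]],
           p_value = 2 * pnorm(-abs(z)),
           n1 = sizes[[i]], n2 = sizes[[j]])
  }) |> purrr::list_rbind()
  rows$p_adjusted <- if (p_adjust == "holm") p.adjust(rows$p_value, "holm") else rows$p_value
  rows
}

#' Three-stratum severity analysis with post hoc pairwise tests
#'
#' Mirrors the study's severity analysis: a one-way ANOVA of the measure
#' across the strata (controls vs mild vs moderate/severe) for the
#' omnibus F and p, followed by Dunn's rank-based pairwise z-tests for
#' the three pairs. Pairing a parametric omnibus with a rank-based post
#' hoc is heterodox (Dunn's test normally follows Kruskal-Wallis), so
#' both layers are reported side by side and separately auditable.
#'
#' @param data Cohort tibble.
#' @param measure Measure column (bare name or string).
#' @param stratum_col Name of the stratum column (a factor, e.g. from
#'   [severity_stratum()]).
#' @param p_adjust Passed to [dunn_test()].
#' @return Object of class `"severity_anova"` with `omnibus` (one-row
#'   tibble: F, df, p, n) and `pairwise` (the Dunn table). [glance()]
#'   returns the omnibus row, [tidy()] the pairwise table.
#' @export
severity_anova <- function(data, measure, stratum_col = "severity",
                           p_adjust = c("none", "holm")) {
  measure <- as_string(ensym(measure))
  d <- data[complete.cases(data[c(measure, stratum_col)]), c(measure, stratum_col)]
  d$.stratum <- factor(d[[stratum_col]], ordered = FALSE)
  d$.stratum <- droplevels(d$.stratum)
  if (nlevels(d$.stratum) < 3) abort("Need 3 non-empty strata for the severity analysis.")
  if (any(table(d$.stratum) < 2)) abort("Need at least 2 subjects per stratum.")
  fit <- aov(stats::reformulate(".stratum", response = measure), data = d)
  an <- anova(fit)
  omnibus <- tibble(
    measure = measure,
    statistic = an$`F value`[1],
    df1 = an$Df[1], df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1],
    n = nrow(d)
  )
  pairwise <- dunn_test(d, !!rlang::sym(measure), .stratum, p_adjust = p_adjust)
  structure(list(omnibus = omnibus, pairwise = pairwise, fit = fit),
            class = "severity_anova")
}

#' @export
print.severity_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$omnibus$measure, x$omnibus$df1, x$omnibus$df2,
              x$omnibus$statistic, x$omnibus$p_value, x$omnibus$n))
  cat("Dunn post hoc pairs:\n")
  print(x$pairwise)
  invisible(x)
}

#' @rdname severity_anova
#' @param x A `"severity_anova"`.
#' @param ... Unused.
#' @export
tidy.severity_anova <- function(x, ...) x$pairwise

#' @rdname severity_anova
#' @export
glance.severity_anova <- function(x, ...) x$omnibus

#' Plain or partial correlation between two measures
#'
#' Pearson or Spearman correlation with its p-value. When adjustment
#' covariates are supplied, both variables are residualized on the
#' covariates by least squares and the correlation is computed between
#' the residuals (the partial-correlation reading of "controlling for
#' sex and age").
#'
#' @param data Cohort tibble.
#' @param x,y Columns to correlate (bare names or strings).
#' @param method `"pearson"` or `"spearman"`.
#' @param covariates Optional character vector of adjustment covariates.
#' @return One-row tibble: `x`, `y`, `method`, `estimate`, `p_value`,
#'   `n`, `partial`, `covariates`.
#' @examples
#' d <- data.frame(a = 1:10, b = (1:10)^2)
#' correlate(d, a, b, method = "spearman")
#' @export
correlate <- function(data, x, y, method = c("pearson", "spearman"),
                      covariates = NULL) {
  method <- match.arg(method)
  x <- as_string(ensym(x)); y <- as_string(ensym(y))
  need <- c(x, y, covariates)
  d <- data[complete.cases(data[need]), need]
  if (nrow(d) < 4) abort("Need at least 4 complete observations.")
  xv <- as.numeric(d[[x]]); yv <- as.numeric(d[[y]])
  if (sd(xv) == 0 || sd(yv) == 0) abort("Zero variance in a correlated column.")
  if (!is.null(covariates)) {
    dd <- d; dd$.x <- xv; dd$.y <- yv
    xv <- resid(lm(stats::reformulate(covariates, response = ".x"), data = dd))
    yv <- resid(lm(stats::reformulate(covariates, response = ".y"), data = dd))
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble(x = x, y = y, method = method,
         estimate = unname(ct$estimate), p_value = ct$p.value,
         n = nrow(d), partial = !is.null(covariates),
         covariates = if (is.null(covariates)) NA_character_ else paste(covariates, collapse = "+"))
}

#' Drop excluded subjects from a cohort
#'
#' Removes flagged subjects (e.g. scans with substantial motion
#' artifacts) from the analysis set and attaches an exclusion log.
#' Counts are conserved: kept + excluded = enrolled.
#'
#' @param cohort Cohort tibble with a `subject_id` column.
#' @param subject_ids Ids of subjects to exclude.
#' @param reason Reason recorded in the log (recycled).
#' @return The filtered cohort with the exclusion log in
#'   `attr(, "exclusion_log")`.
#' @examples
#' d <- tibble::tibble(subject_id = c("P001", "P002"), v = 1:2)
#' exclude_subjects(d, "P002", "motion artifact")
#' @export
exclude_subjects <- function(cohort, subject_ids, reason = "motion artifact") {
  unknown <- setdiff(subject_ids, cohort$subject_id)
  if (length(unknown)) {
    abort(paste0("Unknown subject id(s) in exclusion flags: ",
                 paste(unknown, collapse = ", ")))
  }
  log <- tibble(subject_id = subject_ids,
                reason = rep_len(reason, length(subject_ids)))
  out <- dplyr::filter(cohort, !.data$subject_id %in% subject_ids)
  stopifnot(nrow(out) + length(subject_ids) == nrow(cohort))
  if (length(subject_ids)) {
    message(sprintf("Excluded %d of %d subjects (%d analyzed).",
                    length(subject_ids), nrow(cohort), nrow(out)))
  }
  attr(out, "exclusion_log") <- log
  out
}

#' Full statistical report for a cohort table
#'
#' Runs the study's inferential battery on a derived cohort table:
#' covariate-adjusted group comparisons of the pT2* measures, two-sample
#' tests of the morphometric measures (CSA one-tailed with patients
#' larger), the three-stratum severity analysis of fascicle pT2* with
#' Dunn post hoc pairs, partial correlations of fascicle pT2* with the
#' clinical scales (controlling for age and sex), and Spearman
#' correlations with the nerve-conduction measures within patients.
#' Rows with missing fields are dropped per analysis with `n` reported.
#'
#' @param cohort Cohort tibble (see [run_cohort()]); needs the derived
#'   imaging measures plus `group`, `age`, `sex` and the clinical/NCS
#'   columns.
#' @param csa_alternative Tail for the CSA t-test (default
#'   `"greater"`).
#' @param p_adjust Dunn adjustment, `"none"` or `"holm"`.
#' @return Tidy tibble, one row per test: `analysis`, `measure`,
#'   `contrast`, `method`, `estimate`, `coefficient`, `p_value`, `n`,
#'   `covariates`.
#' @export
cohort_stat_report <- function(cohort, csa_alternative = "greater",
                               p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!all(c("ATTRv", "HC") %in% cohort$group)) {
    abort("The analysis set must contain both ATTRv and HC subjects.")
  }
  cohort <- dplyr::mutate(cohort,
                          severity = severity_stratum(.data$group, .data$nis_ll))
  rows <- list()

  for (m in c("nerve_pt2star_ms", "fascicle_pt2star_ms", "epineurium_pt2star_ms")) {
    a <- adjusted_group_comparison(cohort, !!rlang::sym(m))
    rows[[length(rows) + 1]] <- tibble(
      analysis = "adjusted_group_comparison", measure = m,
      contrast = a$contrast, method = "lm(group+age+sex)",
      estimate = a$estimate, coefficient = a$r_model,
      p_value = a$p_value, n = a$n, covariates = a$covariates)
  }

  for (m in c("csa_mm2", "fascicular_area_mm2", "epineurium_area_mm2")) {
    alt <- if (m == "csa_mm2") csa_alternative else "two.sided"
    tt <- two_sample_tests(cohort, !!rlang::sym(m), alternative = alt)
    rows[[length(rows) + 1]] <- tibble(
      analysis = "two_sample", measure = m, contrast = "ATTRv - HC",
      method = tt$test, estimate = tt$estimate, coefficient = NA_real_,
      p_value = tt$p_value, n = tt$n_attrv + tt$n_hc,
      covariates = NA_character_)
  }

  sev <- tryCatch(severity_anova(cohort, fascicle_pt2star_ms, p_adjust = p_adjust),
                  error = function(e) e)
  if (inherits(sev, "severity_anova")) {
    rows[[length(rows) + 1]] <- tibble(
      analysis = "severity_anova", measure = "fascicle_pt2star_ms",
      contrast = "HC vs mild vs moderate_severe", method = "one-way ANOVA",
      estimate = sev$omnibus$statistic, coefficient = NA_real_,
      p_value = sev$omnibus$p_value, n = sev$omnibus$n,
      covariates = NA_character_)
    rows[[length(rows) + 1]] <- tibble(
      analysis = "severity_posthoc", measure = "fascicle_pt2star_ms",
      contrast = sev$pairwise$contrast, method = "dunn",
      estimate = sev$pairwise$z, coefficient = NA_real_,
      p_value = sev$pairwise$p_adjusted,
      n = sev$pairwise$n1 + sev$pairwise$n2, covariates = NA_character_)
  } else {
    warn(paste0("Severity analysis skipped: ", conditionMessage(sev)))
    rows[[length(rows) + 1]] <- tibble(
      analysis = "severity_anova", measure = "fascicle_pt2star_ms",
      contrast = "HC vs mild vs moderate_severe",
      method = "one-way ANOVA (insufficient strata)",
      estimate = NA_real_, coefficient = NA_real_, p_value = NA_real_,
      n = nrow(cohort), covariates = NA_character_)
  }

  patients <- dplyr::filter(cohort, .data$group == "ATTRv")
  ## correlations degrade to NA rows when too few complete patients remain
  safe_correlate <- function(...) {
    tryCatch(correlate(...), error = function(e) {
      warn(paste0("Correlation skipped: ", conditionMessage(e)))
      tibble(x = NA_character_, y = NA_character_, method = NA_character_,
             estimate = NA_real_, p_value = NA_real_, n = NA_integer_,
             partial = NA, covariates = NA_character_)
    })
  }
  clin <- list(c("nis", "pearson"), c("nis_ll", "pearson"), c("pnd", "spearman"))
  for (cl in clin) {
    cr <- safe_correlate(patients, fascicle_pt2star_ms, !!rlang::sym(cl[1]),
                         method = cl[2], covariates = c("age", "sex"))
    rows[[length(rows) + 1]] <- tibble(
      analysis = "clinical_correlation", measure = "fascicle_pt2star_ms",
      contrast = cl[1], method = paste0("partial_", cl[2]),
      estimate = NA_real_, coefficient = cr$estimate,
      p_value = cr$p_value, n = cr$n, covariates = cr$covariates)
  }

  cr <- safe_correlate(cohort, fascicular_area_mm2, fascicle_pt2star_ms,
                       method = "spearman")
  rows[[length(rows) + 1]] <- tibble(
    analysis = "morphometry_correlation", measure = "fascicular_area_mm2",
    contrast = "fascicle_pt2star_ms", method = "spearman",
    estimate = NA_real_, coefficient = cr$estimate, p_value = cr$p_value,
    n = cr$n, covariates = NA_character_)

  for (m in c("cmap_peroneal_mv", "cmap_tibial_mv", "snap_sural_uv",
              "ncv_peroneal_ms", "ncv_tibial_ms")) {
    cr <- safe_correlate(patients, fascicle_pt2star_ms, !!rlang::sym(m),
                         method = "spearman")
    rows[[length(rows) + 1]] <- tibble(
      analysis = "ncs_correlation", measure = "fascicle_pt2star_ms",
      contrast = m, method = "spearman",
      estimate = NA_real_, coefficient = cr$estimate, p_value = cr$p_value,
      n = cr$n, covariates = NA_character_)
  }

  purrr::list_rbind(rows)
}
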