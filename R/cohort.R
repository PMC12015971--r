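#' Convert a Spearman target to the latent Pearson correlation
#'
#' For a bivariate Gaussian copula the Spearman rank correlation of the
#' two margins is `rho_s = (6/pi) * asin(r/2)` in the latent Pearson
#' correlation `r`; inverting gives `r = 2*sin(pi*rho_s/6)`, which is
#' what the covariate generator uses.
#'
#' @param rho_s Target Spearman correlation(s) in `[-1, 1]`.
#' @return Latent Pearson correlation(s).
#' @examples
#' spearman_to_pearson(-0.715)
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1)) abort("Spearman targets must lie in [-1, 1].")
  2 * sin(pi * rho_s / 6)
}

truncate_floor <- function(x, floor, what, mean, sd) {
  if (floor > mean + 6 * sd) {
    abort(sprintf("Infeasible truncation for %s: floor %.3g above mean + 6 sd.", what, floor))
  }
  pmax(x, floor)
}

## Transform a latent standard normal to the covariate's marginal.
covariate_quantile <- function(z, def) {
  p <- pnorm(z)
  switch(def$dist,
    normal = {
      x <- qnorm(p, def$mean, def$sd)
      pmin(pmax(x, def$lo %||% -Inf), def$hi %||% Inf)
    },
    lognormal = {
      x <- qlnorm(p, def$meanlog, def$sdlog)
      pmin(pmax(x, def$lo %||% 0), def$hi %||% Inf)
    },
    binary = if (p <= def$p_male) "M" else "F",
    ordinal = def$levels[findInterval(p, def$cum_probs) + 1L],
    constant = def$value,
    abort(sprintf("Unknown covariate distribution '%s'.", def$dist))
  )
}

#' Draw one subject's ground truth
#'
#' Draws the subject-level ground truth (fascicle and epineurium pT2*,
#' whole-nerve CSA, fascicular fraction) from the group's distributions,
#' truncated at positive floors, plus clinical/electrophysiological
#' covariates through a Gaussian copula tied to the fascicle pT2* latent
#' (see [covariate_model()] and [spearman_to_pearson()]). Uses the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param group `"ATTRv"` or `"HC"`.
#' @param dists A [group_distributions()] for that group.
#' @param covmodel A [covariate_model()] for that group.
#' @return One-row tibble with the true nerve properties and covariates.
#' @examples
#' set.seed(1)
#' draw_subject("ATTRv", group_distributions("ATTRv"), covariate_model("ATTRv"))
#' @export
draw_subject <- function(group, dists = group_distributions(group),
                         covmodel = covariate_model(group)) {
  if (!group %in% c("ATTRv", "HC")) {
    abort(sprintf("Unknown group label '%s' (expected 'ATTRv' or 'HC').", group))
  }
  stopifnot(inherits(dists, "vte_group_dist"), dists$group == group)

  z_fasc <- rnorm(1)
  fas <- dists$fascicle_t2star
  fascicle_t2star <- truncate_floor(fas["mean"] + fas["sd"] * z_fasc,
                                    dists$t2star_floor_ms, "fascicle t2*",
                                    fas["mean"], fas["sd"])
  epi <- dists$epineurium_t2star
  epineurium_t2star <- truncate_floor(rnorm(1, epi["mean"], epi["sd"]),
                                      dists$t2star_floor_ms, "epineurium t2*",
                                      epi["mean"], epi["sd"])
  csa <- truncate_floor(rnorm(1, dists$csa["mean"], dists$csa["sd"]),
                        dists$csa_floor_mm2, "CSA",
                        dists$csa["mean"], dists$csa["sd"])
  frac <- dists$fasc_fraction
  fasc_fraction <- min(max(rnorm(1, frac["mean"], frac["sd"]), 0.05), 0.95)

  covs <- purrr::imap(covmodel, function(def, name) {
    r <- spearman_to_pearson(def$rho)
    z <- r * z_fasc + sqrt(1 - r^2) * rnorm(1)
    covariate_quantile(z, def)
  })

  tibble(
    group = group,
    true_fascicle_t2star_ms = unname(fascicle_t2star),
    true_epineurium_t2star_ms = unname(epineurium_t2star),
    true_csa_mm2 = unname(csa),
    true_fasc_fraction = unname(fasc_fraction),
    !!!covs
  )
}

## Deterministic per-subject seeds below 2^31, derived from the master seed.
derive_subject_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

#' Draw the ground truth for a whole cohort
#'
#' Derives one seed per subject deterministically from the master seed,
#' then draws each subject's truth with [draw_subject()]. The returned
#' table is byte-identical across runs with the same seed and
#' configuration.
#'
#' @param n_attrv,n_hc Number of ATTRv patients and healthy controls.
#' @param config A [run_config()] (its `dists`/`covariates` are used).
#' @param seed Master seed; defaults to `config$seed`.
#' @return Tibble with one row per subject: `subject_id`, `group`, true
#'   nerve properties, covariates and the per-subject `seed`.
#' @export
simulate_cohort_truth <- function(n_attrv, n_hc, config = run_config(),
                                  seed = config$seed) {
  if (is.null(seed)) abort("A master seed is required.")
  if (n_attrv < 1 || n_hc < 1) abort("Cohort sizes must be at least 1.")
  groups <- c(rep("ATTRv", n_attrv), rep("HC", n_hc))
  ids <- sprintf("%s%03d", ifelse(groups == "ATTRv", "P", "C"),
                 c(seq_len(n_attrv), seq_len(n_hc)))
  seeds <- derive_subject_seeds(seed, length(groups))
  purrr::pmap(list(ids, groups, seeds), function(id, grp, s) {
    set.seed(s)
    draw_subject(grp, config$dists[[grp]], config$covariates[[grp]]) |>
      dplyr::mutate(subject_id = id, seed = s, .before = 1)
  }) |>
    purrr::list_rbind()
}
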