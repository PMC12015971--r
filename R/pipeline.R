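#' Derived imaging measures for one phantom
#'
#' Runs the analysis stack on a single dual-echo volume and label map:
#' voxelwise pT2* mapping, exclusion of the first and last slices, ROI
#' mean pT2* per structure, and per-slice morphometry aggregated over
#' the analysis slices.
#'
#' @param echoes An [echo_pair()].
#' @param labels A [nerve_label_map()].
#' @param method pT2* ROI summary method, `"voxelwise"` or
#'   `"roi_signal"` (see [roi_mean_pt2star()]).
#' @return One-row tibble: `fascicle_pt2star_ms`, `epineurium_pt2star_ms`,
#'   `nerve_pt2star_ms`, `csa_mm2`, `fascicular_area_mm2`,
#'   `epineurium_area_mm2`, `valid_fraction`.
#' @export
analyze_phantom <- function(echoes, labels,
                            method = c("voxelwise", "roi_signal")) {
  method <- match.arg(method)
  map <- compute_pt2star(echoes)
  slices <- select_analysis_slices(dim(labels$labels)[3])
  roi <- function(st) roi_mean_pt2star(map, labels, st, slices,
                                       method = method, vol = echoes)
  fas <- roi("fascicle"); epi <- roi("epineurium"); nerve <- roi("nerve")
  areas <- aggregate_areas(csa_per_slice(labels), slices)
  area_of <- function(st) areas$area_mm2[areas$structure == st]
  tibble(
    fascicle_pt2star_ms = fas$mean_pt2star_ms,
    epineurium_pt2star_ms = epi$mean_pt2star_ms,
    nerve_pt2star_ms = nerve$mean_pt2star_ms,
    csa_mm2 = area_of("nerve"),
    fascicular_area_mm2 = area_of("fascicle"),
    epineurium_area_mm2 = area_of("epineurium"),
    valid_fraction = nerve$valid_fraction
  )
}

simulate_subject <- function(id, group, seed, config) {
  set.seed(seed)
  truth <- draw_subject(group, config$dists[[group]], config$covariates[[group]])
  phantom <- build_phantom(truth, config$geometry, config$acquisition,
                           config$compartments)
  list(truth = dplyr::mutate(truth, subject_id = id, seed = seed, .before = 1),
       phantom = phantom)
}

#' Simulate and analyze a whole cohort in memory
#'
#' For each subject: derive a per-subject seed from the master seed,
#' draw the ground truth, render the dual-echo phantom, and compute the
#' derived imaging measures with [analyze_phantom()]. This is the
#' simulation engine behind [run_nerve_pipeline()]; nothing is written
#' to disk.
#'
#' @param n_attrv,n_hc Cohort sizes.
#' @param config A [run_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return Object of class `"nerve_cohort"`: a list with `cohort` (one
#'   row per subject: ground truth, covariates and measured imaging
#'   values), `config` and `seed`. [glance()] summarizes measured means
#'   per group.
#' @examples
#' \donttest{
#' cc <- run_cohort(4, 4, seed = 1)
#' dplyr::select(cc$cohort, subject_id, group, fascicle_pt2star_ms, csa_mm2)
#' }
#' @export
run_cohort <- function(n_attrv, n_hc, config = run_config(), seed = config$seed) {
  if (is.null(seed)) abort("A master seed is required.")
  groups <- c(rep("ATTRv", n_attrv), rep("HC", n_hc))
  ids <- sprintf("%s%03d", ifelse(groups == "ATTRv", "P", "C"),
                 c(seq_len(n_attrv), seq_len(n_hc)))
  seeds <- derive_subject_seeds(seed, length(groups))
  rows <- purrr::pmap(list(ids, groups, seeds), function(id, grp, s) {
    sub <- simulate_subject(id, grp, s, config)
    measures <- analyze_phantom(sub$phantom$echoes, sub$phantom$labels,
                                method = config$pt2star_method)
    dplyr::bind_cols(sub$truth, measures)
  })
  structure(list(cohort = purrr::list_rbind(rows), config = config, seed = seed),
            class = "nerve_cohort")
}

#' @export
print.nerve_cohort <- function(x, ...) {
  counts <- table(x$cohort$group)
  cat(sprintf("Simulated vTE cohort: %d ATTRv, %d HC (master seed %d)\n",
              counts[["ATTRv"]], counts[["HC"]], x$seed))
  print(glance(x))
  invisible(x)
}

#' @rdname run_cohort
#' @param x A `"nerve_cohort"`.
#' @param ... Unused.
#' @export
glance.nerve_cohort <- function(x, ...) {
  x$cohort |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      fascicle_pt2star_ms = mean(.data$fascicle_pt2star_ms),
      nerve_pt2star_ms = mean(.data$nerve_pt2star_ms),
      csa_mm2 = mean(.data$csa_mm2),
      fascicular_area_mm2 = mean(.data$fascicular_area_mm2),
      .groups = "drop")
}

#' @rdname run_cohort
#' @export
tidy.nerve_cohort <- function(x, ...) x$cohort

#' Write a simulated cohort to disk
#'
#' Writes, for every subject, the two echo volumes and the ground-truth
#' label map as NIfTI-1 `.nii.gz`, plus one `truth.csv` for the cohort
#' with stable column names. Re-running with the same seed and
#' configuration reproduces a byte-identical truth table.
#'
#' @inheritParams run_cohort
#' @param out_dir Output directory (created if missing).
#' @return Tibble with one row per subject listing the written files,
#'   invisibly; the truth table is at `file.path(out_dir, "truth.csv")`.
#' @export
generate_cohort <- function(n_attrv, n_hc, config = run_config(),
                            seed = config$seed, out_dir) {
  if (is.null(seed)) abort("A master seed is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c(rep("ATTRv", n_attrv), rep("HC", n_hc))
  ids <- sprintf("%s%03d", ifelse(groups == "ATTRv", "P", "C"),
                 c(seq_len(n_attrv), seq_len(n_hc)))
  seeds <- derive_subject_seeds(seed, length(groups))
  truth <- vector("list", length(ids))
  files <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- simulate_subject(ids[i], groups[i], seeds[i], config)
    p <- file.path(out_dir, ids[i])
    f <- c(echo1 = paste0(p, "_echo1.nii.gz"),
           echo2 = paste0(p, "_echo2.nii.gz"),
           labels = paste0(p, "_labels.nii.gz"))
    write_echo_pair(sub$phantom$echoes, f[["echo1"]], f[["echo2"]])
    write_label_map(sub$phantom$labels, f[["labels"]])
    truth[[i]] <- sub$truth
    files[[i]] <- tibble(subject_id = ids[i], !!!as.list(f))
  }
  truth <- purrr::list_rbind(truth)
  truth <- truth[, c("subject_id", "group", "true_fascicle_t2star_ms",
                     "true_epineurium_t2star_ms", "true_csa_mm2",
                     "true_fasc_fraction", "age", "sex", "nis", "nis_ll",
                     "pnd", "cmap_peroneal_mv", "cmap_tibial_mv",
                     "snap_sural_uv", "ncv_peroneal_ms", "ncv_tibial_ms",
                     "seed")]
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  invisible(purrr::list_rbind(files))
}

#' Analyze one subject's volumes from files
#'
#' File-based counterpart of [analyze_phantom()], so that real
#' (non-synthetic) acquisitions can be substituted for the generator's
#' output: reads two echo NIfTI volumes and a label map, computes the
#' pT2* map (optionally persisting it) and returns the derived measures.
#'
#' @param echo1_path,echo2_path,labels_path Input NIfTI paths.
#' @param te1,te2 Echo times in ms.
#' @param method `"voxelwise"` or `"roi_signal"`.
#' @param map_out Optional path prefix; if given, writes
#'   `<map_out>_pt2star.nii.gz` and `<map_out>_valid.nii.gz`.
#' @return One-row tibble of derived measures (see [analyze_phantom()]).
#' @export
analyze_subject_files <- function(echo1_path, echo2_path, labels_path,
                                  te1 = 1.05, te2 = 5.37,
                                  method = c("voxelwise", "roi_signal"),
                                  map_out = NULL) {
  method <- match.arg(method)
  vol <- read_echo_pair(echo1_path, echo2_path, te1, te2)
  labels <- read_label_map(labels_path)
  if (!is.null(map_out)) {
    map <- compute_pt2star(vol)
    write_pt2star_map(map, paste0(map_out, "_pt2star.nii.gz"),
                      paste0(map_out, "_valid.nii.gz"))
  }
  analyze_phantom(vol, labels, method = method)
}

#' Two-rater reliability stage on a simulated cohort
#'
#' Simulates a second rater for each subject by perturbing the
#' ground-truth mask boundaries at the configured flip rate, then
#' reports per-structure Dice coefficients (averaged over subjects) and
#' the ICC of the derived measures (CSA and fascicle pT2*) between the
#' two "raters".
#'
#' @param cohort_run A `"nerve_cohort"` from [run_cohort()].
#' @param flip_rate Boundary flip rate in `[0, 0.5]`.
#' @param icc_type `"agreement"` or `"consistency"`.
#' @return List with `dice` (tibble: structure, mean dice, n) and `icc`
#'   (tibble: measure, icc, icc_variant, n).
#' @export
reliability_stage <- function(cohort_run, flip_rate = 0.15,
                              icc_type = c("agreement", "consistency")) {
  icc_type <- match.arg(icc_type)
  cfg <- cohort_run$config
  rows <- purrr::pmap(list(cohort_run$cohort$subject_id,
                           cohort_run$cohort$group,
                           cohort_run$cohort$seed),
                      function(id, grp, s) {
    sub <- simulate_subject(id, grp, s, cfg)
    set.seed(s + 1L)  # independent stream for the second rater
    rater2 <- perturb_mask(sub$phantom$labels, flip_rate)
    m1 <- analyze_phantom(sub$phantom$echoes, sub$phantom$labels,
                          method = cfg$pt2star_method)
    m2 <- analyze_phantom(sub$phantom$echoes, rater2,
                          method = cfg$pt2star_method)
    tibble(
      subject_id = id,
      dice_nerve = dice_coefficient(sub$phantom$labels, rater2, "nerve"),
      dice_fascicle = dice_coefficient(sub$phantom$labels, rater2, "fascicle"),
      dice_epineurium = dice_coefficient(sub$phantom$labels, rater2, "epineurium"),
      csa_r1 = m1$csa_mm2, csa_r2 = m2$csa_mm2,
      fas_r1 = m1$fascicle_pt2star_ms, fas_r2 = m2$fascicle_pt2star_ms)
  }) |> purrr::list_rbind()
  dice <- tibble(
    structure = c("nerve", "fascicle", "epineurium"),
    dice = c(mean(rows$dice_nerve), mean(rows$dice_fascicle),
             mean(rows$dice_epineurium)),
    n = nrow(rows))
  iccs <- purrr::map(list(c("csa_mm2", "csa_r1", "csa_r2"),
                          c("fascicle_pt2star_ms", "fas_r1", "fas_r2")),
                     function(spec) {
    fit <- icc_two_rater(rows, !!rlang::sym(spec[2]), !!rlang::sym(spec[3]),
                         type = icc_type)
    dplyr::mutate(glance(fit), measure = spec[1], .before = 1)
  }) |> purrr::list_rbind()
  list(dice = dice, icc = iccs, per_subject = rows)
}

#' Run the full pipeline: simulate, map, morph, reliability, stats
#'
#' Executes every stage on a configured synthetic cohort and persists
#' all intermediates under `out_dir`: per-subject NIfTI volumes, label
#' maps and pT2* maps; the ground-truth table; per-slice and aggregate
#' morphometry CSVs; the cohort table joining truth, covariates and
#' derived measures; the reliability JSON; the statistics report CSV;
#' and a run manifest with MD5 checksums of every output so that
#' reruns with the same configuration can be verified byte-identical
#' (deterministic stages) from the manifest alone.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()]; must carry a master seed.
#' @param out_dir Output directory.
#' @param seed Optional override of `config$seed`.
#' @return The manifest as a list (also written to `manifest.json`).
#' @export
run_nerve_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "vte_run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) abort("A master seed is required (config or `seed`).")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: simulate
  files <- generate_cohort(config$n_attrv, config$n_hc, config,
                           config$seed, out_dir = file.path(out_dir, "images"))
  truth_csv <- file.path(out_dir, "images", "truth.csv")
  truth <- readr::read_csv(truth_csv, show_col_types = FALSE)

  ## stage 2 + 3: pT2* mapping and morphometry from the written files
  acq <- config$acquisition
  measures <- purrr::pmap(files, function(subject_id, echo1, echo2, labels) {
    m <- analyze_subject_files(echo1, echo2, labels, acq$te1, acq$te2,
                               method = config$pt2star_method,
                               map_out = file.path(out_dir, "images", subject_id))
    dplyr::mutate(m, subject_id = subject_id, .before = 1)
  }) |> purrr::list_rbind()
  per_slice <- purrr::pmap(files, function(subject_id, echo1, echo2, labels) {
    csa_per_slice(read_label_map(labels)) |>
      dplyr::mutate(subject_id = subject_id, .before = 1)
  }) |> purrr::list_rbind()
  readr::write_csv(per_slice, file.path(out_dir, "areas_per_slice.csv"))

  cohort <- dplyr::left_join(truth, measures, by = "subject_id")
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))

  ## stage 4: reliability (second synthetic rater)
  rel <- reliability_stage(
    structure(list(cohort = cohort, config = config, seed = config$seed),
              class = "nerve_cohort"),
    flip_rate = config$rater_flip_rate, icc_type = config$icc_type)
  jsonlite::write_json(list(dice = rel$dice, icc = rel$icc),
                       file.path(out_dir, "reliability.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  ## stage 5: statistics on the analysis set
  analysis_set <- exclude_subjects(cohort, config$excluded_subjects)
  stats_report <- cohort_stat_report(analysis_set,
                                     csa_alternative = config$csa_alternative,
                                     p_adjust = config$p_adjust)
  readr::write_csv(stats_report, file.path(out_dir, "stats_report.csv"))

  ## manifest
  outputs <- c(truth_csv, file.path(out_dir, "areas_per_slice.csv"),
               file.path(out_dir, "cohort.csv"),
               file.path(out_dir, "reliability.json"),
               file.path(out_dir, "stats_report.csv"))
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(serializable_config(config), cfg_file)
  manifest <- list(
    package_version = as.character(packageVersion("vtenerve")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_enrolled = nrow(cohort),
    n_analyzed = nrow(analysis_set),
    n_excluded = length(config$excluded_subjects),
    checksums = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

## Flatten a run config into plain lists for hashing / YAML round-trip.
serializable_config <- function(config) {
  rapply(unclass(config), f = function(x) x, how = "replace")
}
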