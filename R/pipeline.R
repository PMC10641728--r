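#' Run the simulate-or-analyze qEEG pipeline end to end
#'
#' In `simulate` mode: build the group profiles (band fractions plus
#' optional feature calibration), synthesize the cohort, extract the
#' per-subject qEEG features and produce the group comparison table. In
#' `analyze` mode: read EDF recordings listed in a manifest and run the
#' same extraction and comparison. When `out_dir` is set, writes
#' `features.csv`, `comparison.csv`, `comparison.json` and `run.json`
#' (config, seed, package and R versions); outputs are deterministic given
#' the config, so reruns are byte-identical.
#'
#' @param config A named list, or path to a YAML file, with fields:
#'   * `mode`: `"simulate"` or `"analyze"`.
#'   * `seed`: integer cohort seed (simulate mode).
#'   * `duration_s`, `fs`: recording length / sampling rate (simulate).
#'   * `groups`: for simulate, a list of group blocks, each with `label`,
#'     `n`, `fractions` (four band proportions), optional `amplitude`
#'     (uV RMS), optional `calibrate` (list of `feature`, `target`),
#'     optional `dispersion` (list of `fractions`, `amplitude`,
#'     `subdelta`).
#'   * `input_dir`: for analyze, a directory containing EDF files plus a
#'     `manifest.csv` with columns `file`, `subject_id`, `group_label`.
#'   * `out_dir`: optional output directory.
#'   * `write_edf`: optionally write one EDF per simulated subject to
#'     `out_dir` (plus the cohort `manifest.csv`).
#'   * `features`: optional overrides passed to [feature_config()].
#' @return A list with `features` (per-subject tibble), `comparison`
#'   (a `qeeg_comparison`) and `paths` (written files), invisibly
#'   classed `qeeg_run`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config) && !is.null(config$mode), "config needs a 'mode' field")
  assert_that(config$mode %in% c("simulate", "analyze"),
              "mode must be 'simulate' or 'analyze'")
  assert_that(xor(is.null(config$input_dir), config$mode == "analyze") ||
                config$mode == "simulate",
              "exactly one input source: groups (simulate) or input_dir (analyze)")
  fcfg <- do.call(feature_config, config$features %||% list())

  if (config$mode == "simulate") {
    assert_that(!is.null(config$groups), "simulate mode needs a 'groups' block")
    groups <- purrr::map_dfr(config$groups, function(g) {
      # YAML 1.1 reads a bare `n:` key as the boolean FALSE; accept both it
      # and the unambiguous `n_subjects:` spelling
      names(g)[names(g) %in% c("FALSE", "n_subjects")] <- "n"
      assert_that(!is.null(g$n) && !is.null(g$label) && !is.null(g$fractions),
                  "each group needs label, n (or n_subjects) and fractions")
      prof <- make_band_profile(
        unlist(g$fractions) / sum(unlist(g$fractions)),
        amplitude_scale = g$amplitude %||% 7)
      if (!is.null(g$calibrate)) {
        prof <- calibrate_profile(prof, g$calibrate$feature,
                                  g$calibrate$target, fcfg)
      }
      disp <- do.call(profile_dispersion,
                      purrr::map(g$dispersion %||% list(), unlist))
      tibble::tibble(label = g$label, n = as.integer(g$n),
                     profile = list(prof), dispersion = list(disp))
    })
    spec <- cohort_spec(groups,
                        duration_s = config$duration_s %||% 120,
                        fs = config$fs %||% 256,
                        seed = config$seed %||% 1L)
    cohort <- synthesize_cohort(spec)
    features <- cohort_features(cohort, fcfg)
  } else {
    dir <- config$input_dir
    manifest_path <- file.path(dir, "manifest.csv")
    assert_that(file.exists(manifest_path),
                sprintf("analyze mode needs %s", manifest_path))
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    cohort <- purrr::map(seq_len(nrow(manifest)), function(i) {
      rec <- tryCatch(read_edf(file.path(dir, manifest$file[i])),
                      error = function(e) stop(sprintf(
                        "failed on subject '%s': %s", manifest$subject_id[i],
                        conditionMessage(e)), call. = FALSE))
      rec$subject_id <- manifest$subject_id[i]
      rec$group_label <- manifest$group_label[i]
      rec
    })
    features <- cohort_features(cohort, fcfg)
  }

  comparison <- summarize_groups(features)
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p_feat <- file.path(config$out_dir, "features.csv")
    utils::write.csv(features, p_feat, row.names = FALSE)
    p_comp <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(tidy(comparison), p_comp, row.names = FALSE)
    p_json <- file.path(config$out_dir, "comparison.json")
    jsonlite::write_json(tidy(comparison), p_json, digits = NA, auto_unbox = TRUE)
    p_run <- file.path(config$out_dir, "run.json")
    jsonlite::write_json(
      list(config = config,
           package_version = as.character(utils::packageVersion("qeegicu")),
           r_version = R.version.string),
      p_run, auto_unbox = TRUE, null = "null")
    paths <- c(features = p_feat, comparison = p_comp,
               comparison_json = p_json, run = p_run)
    if (isTRUE(config$write_edf) && config$mode == "simulate") {
      man <- cohort_manifest(cohort)
      man$file <- paste0(man$subject_id, ".edf")
      for (i in seq_along(cohort)) {
        write_edf(cohort[[i]], file.path(config$out_dir, man$file[i]))
      }
      p_man <- file.path(config$out_dir, "manifest.csv")
      utils::write.csv(man, p_man, row.names = FALSE)
      paths <- c(paths, manifest = p_man)
    }
  }
  invisible(structure(list(features = features, comparison = comparison,
                           paths = paths),
                      class = "qeeg_run"))
}

#' Reproduce the calibrated reference-study scenarios
#'
#' Runs the two study-emulation scenarios end to end on synthetic cohorts
#' calibrated to the reference group summaries (see
#' [reference_group_summaries()]): the surgery comparison (cardiac n = 24
#' vs non-cardiac n = 22) and the delirium comparison within the cardiac
#' arm (n = 10 vs 14). Each arm's profile uses the published band
#' fractions, its amplitude is calibrated to the published aEEG upper
#' limit, and between-subject dispersion is matched to the published SEMs.
#'
#' @param seed Cohort seed.
#' @param out_dir Optional output directory (one subdirectory per
#'   scenario).
#' @param duration_s,fs Recording length and sampling rate.
#' @param dispersion Apply SEM-matched between-subject dispersion
#'   (default TRUE).
#' @return Named list of two `qeeg_run` results (`surgery`, `delirium`).
#' @export
reproduce_tables <- function(seed = 1L, out_dir = NULL, duration_s = 120,
                             fs = 256, dispersion = TRUE) {
  scenario <- function(tab, labels, sub_seed) {
    summ <- reference_group_summaries(tab)
    groups <- purrr::map_dfr(labels, function(lb) {
      s <- summ[summ$group == lb, ]
      prof <- reference_group_profile(lb)
      prof <- calibrate_profile(prof, "aeeg_upper",
                                s$mean[s$feature == "aeeg_upper_uv"])
      disp <- if (dispersion) reference_group_dispersion(lb) else profile_dispersion()
      tibble::tibble(label = lb, n = s$n[1], profile = list(prof),
                     dispersion = list(disp))
    })
    spec <- cohort_spec(groups, duration_s = duration_s, fs = fs, seed = sub_seed)
    features <- cohort_features(synthesize_cohort(spec))
    comparison <- summarize_groups(features)
    paths <- character(0)
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, tab)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(features, file.path(d, "features.csv"), row.names = FALSE)
      utils::write.csv(tidy(comparison), file.path(d, "comparison.csv"),
                       row.names = FALSE)
      paths <- c(features = file.path(d, "features.csv"),
                 comparison = file.path(d, "comparison.csv"))
    }
    structure(list(features = features, comparison = comparison, paths = paths),
              class = "qeeg_run")
  }
  list(
    surgery = scenario("surgery", c("cardiac", "non_cardiac"), seed),
    delirium = scenario("delirium", c("delirium", "non_delirium"), seed + 1L)
  )
}

#' @export
print.qeeg_run <- function(x, ...) {
  cat("<qeeg_run> ", nrow(x$features), " subjects, ",
      length(unique(x$features$group_label)), " groups\n", sep = "")
  print(x$comparison)
  invisible(x)
}
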