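# One-call orchestration: simulate (or read) -> screen -> d' -> psychometric
# -> permutation tests -> reaction-time tables, written as long-format CSVs
# plus a JSON manifest. The pipeline is a pure dataflow: identical
# configuration yields byte-identical outputs.

#' Pipeline run configuration
#'
#' @param input either a [cohort_spec()] (the trials are simulated) or a
#'   path to a trials CSV.
#' @param out_dir output directory (created if absent).
#' @param trial_seed seed for trial simulation (ignored for CSV input).
#' @param resampling_seed base seed for the permutation stages.
#' @param n_sims Monte Carlo simulations per permutation test.
#' @param asynchrony_class classes at which the permutation tests run
#'   (default `"pooled"`, the aggregate entries).
#' @param run_rt,run_correlations flags for the optional reaction-time and
#'   rank-correlation stages.
#' @return a `toj_run_config` list.
#' @export
pipeline_config <- function(input = cohort_spec(), out_dir,
                            trial_seed = 2L, resampling_seed = 3L,
                            n_sims = 10000L, asynchrony_class = "pooled",
                            run_rt = TRUE, run_correlations = TRUE) {
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  if (!inherits(input, "toj_cohort_spec") &&
      !(is.character(input) && length(input) == 1)) {
    stop("input must be a cohort_spec or a file path", call. = FALSE)
  }
  structure(list(
    input = input, out_dir = out_dir, trial_seed = as.integer(trial_seed),
    resampling_seed = as.integer(resampling_seed), n_sims = as.integer(n_sims),
    asynchrony_class = asynchrony_class, run_rt = run_rt,
    run_correlations = run_correlations
  ), class = "toj_run_config")
}

write_stage <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  df <- tibble::as_tibble(df)
  class(df) <- class(tibble::tibble())
  readr::write_csv(df, path)
  path
}

#' Run the full TOJ analysis pipeline
#'
#' Stages, in order: obtain trials (simulation or CSV), inclusion screening,
#' per-participant d' tables, group psychometric fits with 75% JND
#' thresholds, pairwise-group and 2x2-interaction permutation tests, and
#' (optionally) reaction-time medians/differences and rank-correlation
#' tables. Every stage's output lands in `out_dir` as a long-format CSV;
#' `manifest.json` records the package version, all seeds, per-stage row
#' counts, and MD5 digests of every file.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "toj_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)

  if (inherits(config$input, "toj_cohort_spec")) {
    say("simulate: cohort seed %d, trial seed %d", config$input$seed,
        config$trial_seed)
    observers <- sample_cohort(config$input)
    trials <- simulate_trials(observers, seed = config$trial_seed)
    files["trials"] <- write_stage(trials, config$out_dir, "trials.csv")
    input_desc <- list(kind = "simulated", cohort_seed = config$input$seed,
                       trial_seed = config$trial_seed)
  } else {
    say("read: %s", config$input)
    trials <- read_trials(config$input)
    input_desc <- list(kind = "file", path = config$input,
                       md5 = unname(tools::md5sum(config$input)))
  }
  say("trials: %d rows, %d participants", nrow(trials),
      length(unique(trials$participant_id)))

  report <- screen_cohort(trials)
  files["inclusion"] <- write_stage(report, config$out_dir, "inclusion.csv")
  files["inclusion_groups"] <- write_stage(attr(report, "group_summary"),
                                           config$out_dir,
                                           "inclusion_groups.csv")
  trials_in <- included_trials(trials, report)
  say("screen: %d/%d participants included", sum(report$included),
      nrow(report))
  if (sum(report$included) == 0) {
    stop("pipeline aborted at stage 'screen': no participant passed the ",
         "inclusion criterion", call. = FALSE)
  }

  dp <- dprime_table(trials_in)
  files["dprime"] <- write_stage(dp, config$out_dir, "dprime.csv")
  say("dprime: %d entries", nrow(dp))

  fits <- fit_psychometric(trials_in)
  files["fits"] <- write_stage(dplyr::select(fits, -"fit"), config$out_dir,
                               "fits.csv")
  say("psychometric: %d curves fitted", nrow(fits))

  groups_present <- unique(dp$group)
  if (length(groups_present) >= 2) {
    mc_pair <- pairwise_group_tests(dp,
                                    asynchrony_class = config$asynchrony_class,
                                    n_sims = config$n_sims,
                                    seed = config$resampling_seed)
    files["mc_pairwise"] <- write_stage(mc_pair, config$out_dir,
                                        "mc_pairwise.csv")
    say("mc: %d pairwise tests", nrow(mc_pair))
  } else {
    warning("fewer than two groups after screening; pairwise tests skipped",
            call. = FALSE)
    mc_pair <- NULL
  }
  mc_int <- interaction_tests(dp, asynchrony_class = config$asynchrony_class,
                              n_sims = config$n_sims,
                              seed = config$resampling_seed)
  files["mc_interaction"] <- write_stage(mc_int, config$out_dir,
                                         "mc_interaction.csv")
  say("mc: %d interaction tests", nrow(mc_int))

  if (config$run_rt) {
    rt <- rt_medians(trials_in)
    files["rt_participants"] <- write_stage(rt, config$out_dir,
                                            "rt_participants.csv")
    files["rt_groups"] <- write_stage(group_rt_medians(rt), config$out_dir,
                                      "rt_groups.csv")
    if (length(groups_present) >= 2) {
      diffs <- group_rt_differences(rt)
      files["rt_differences"] <- write_stage(diffs, config$out_dir,
                                             "rt_differences.csv")
      files["rt_differences_cells"] <- write_stage(attr(diffs, "cellwise"),
                                                   config$out_dir,
                                                   "rt_differences_cells.csv")
    }
    say("rt: medians for %d participants",
        length(unique(rt$participant_id)))
  }

  if (config$run_correlations) {
    rtdp <- rt_dprime_rank_correlations(trials_in, dp)
    files["rt_dprime_correlations"] <- write_stage(
      rtdp$correlations, config$out_dir, "rt_dprime_correlations.csv")
    dp_pooled <- dplyr::filter(dp, .data$asynchrony_class == "pooled")
    files["rank_cor_dprime"] <- write_stage(
      condition_rank_cor_matrix(dp_pooled, "dprime"),
      config$out_dir, "rank_cor_dprime.csv")
    if (config$run_rt) {
      rt_cond <- trials_in |>
        analysis_trials() |>
        dplyr::group_by(.data$participant_id, .data$group, .data$motion_type,
                        .data$initial_directions) |>
        dplyr::summarise(rt_median_ms = median(.data$rt_ms),
                         .groups = "drop")
      files["rank_cor_rt"] <- write_stage(
        condition_rank_cor_matrix(rt_cond, "rt_median_ms"),
        config$out_dir, "rank_cor_rt.csv")
    }
    say("correlations: done")
  }

  manifest <- list(
    package = "tojlab",
    version = as.character(utils::packageVersion("tojlab")),
    input = input_desc,
    seeds = list(trial = config$trial_seed,
                 resampling = config$resampling_seed),
    n_sims = config$n_sims,
    asynchrony_class = config$asynchrony_class,
    n_participants_total = nrow(report),
    n_participants_included = sum(report$included),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("manifest: %s", file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
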