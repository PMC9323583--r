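#' Configuration of an end-to-end study run
#'
#' Exactly one of `input_dir` (a directory with `metadata.csv` plus PNG
#' angiograms, see [read_cohort()]) or `simulate` (parameters forwarded to
#' [generate_cohort()]) must be given.
#'
#' @param input_dir directory of pre-acquired images, or `NULL`.
#' @param simulate list with optional `n_participants`, `vessel`, `intra`,
#'   `inter` entries, or `NULL`.
#' @param threshold binarisation threshold in \[0, 1\].
#' @param mesh `"auto"` (dyadic schedule per image) or an explicit
#'   decreasing integer vector of mesh sizes.
#' @param icc_model `"ICC_2_1"`, `"ICC_1_1"` or `"ICC_3_1"`.
#' @param seed master seed for simulation.
#' @param output_dir where the report bundle is written; `NULL` keeps
#'   everything in memory.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulate = list(),
                       threshold = 0.5, mesh = "auto",
                       icc_model = c("ICC_2_1", "ICC_1_1", "ICC_3_1"),
                       seed = 1L, output_dir = NULL) {
  icc_model <- match.arg(icc_model)
  if (!is.null(input_dir) && length(simulate) > 0)
    stop_config("give either input_dir or simulate parameters, not both")
  if (threshold < 0 || threshold > 1)
    stop_config("threshold must lie in [0, 1]")
  structure(list(input_dir = input_dir, simulate = simulate,
                 threshold = threshold, mesh = mesh, icc_model = icc_model,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()]; `simulate` sub-keys `vessel`, `intra` and `inter` are
#'   forwarded to [vessel_tree_params()] and [scan_perturbation()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$vessel))
      y$simulate$vessel <- do.call(vessel_tree_params, y$simulate$vessel)
    if (!is.null(y$simulate$intra))
      y$simulate$intra <- do.call(scan_perturbation, y$simulate$intra)
    if (!is.null(y$simulate$inter))
      y$simulate$inter <- do.call(scan_perturbation, y$simulate$inter)
  }
  do.call(run_config, y)
}

#' Per-image fractal-dimension measurements for a cohort
#'
#' Runs the binarise/skeletonise/box-count pipeline over every image of a
#' cohort and returns the long measurement table.
#'
#' @param cohort list with `images` and `metadata` ([generate_cohort()] /
#'   [read_cohort()] layout).
#' @param threshold binarisation threshold.
#' @param sizes_px explicit mesh sizes or `NULL` for the dyadic schedule.
#' @return data frame: metadata columns plus `fd`, `r_squared`,
#'   `n_scales`, `threshold_used`.
#' @export
measure_cohort <- function(cohort, threshold = 0.5, sizes_px = NULL) {
  meta <- cohort$metadata
  fd <- rsq <- numeric(nrow(meta)); nsc <- integer(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    res <- estimate_fd(cohort$images[[meta$image_key[i]]],
                       threshold = threshold, sizes_px = sizes_px)
    fd[i] <- res$fd; rsq[i] <- res$r_squared; nsc[i] <- res$n_scales
  }
  cbind(meta[, setdiff(names(meta), "image_key"), drop = FALSE],
        data.frame(fd = fd, r_squared = rsq, n_scales = nsc,
                   threshold_used = threshold))
}

reliability_row <- function(tab, plexus, comparison, icc_model) {
  Y <- pivot_measurements(tab)
  ic <- icc(tab, model = icc_model)
  ba <- bland_altman(Y[, 1], Y[, 2])
  tt <- paired_t(Y[, 1], Y[, 2])
  cvs <- cv(Y)  # per-subject CV across the two paired ratings
  data.frame(plexus = plexus, comparison = comparison,
             icc = ic$estimate, ci_low = ic$ci_low, ci_high = ic$ci_high,
             model = ic$model, label = ic$label,
             cv_percent = cvs$cv_percent,
             bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
             t = tt$t, p = tt$p, n = nrow(Y))
}

#' Run a complete repeatability/reproducibility study
#'
#' Orchestrates the full pipeline: obtain the cohort (simulate or read),
#' measure the fractal dimension of every image, assemble the
#' repeatability (scans 2 vs 3, observer 2) and reproducibility (scan 1,
#' observer 1 vs scan 2, observer 2) tables per plexus, and compute the
#' agreement statistics. With `output_dir` set, writes `fd.csv`
#' (per-image measurements), `reliability.csv` and `reliability.json`,
#' `bland_altman_pairs.csv`, a demographic `table1.csv`, a per-observer
#' FD summary `table2.csv`, and `config.yaml` (the resolved configuration,
#' for provenance). Identical config + seed gives byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `measurements`, `reliability`,
#'   `bland_altman_pairs`, `table1`, `table2`, `config`.
#' @export
run_study <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    args <- config$simulate
    args$seed <- config$seed
    do.call(generate_cohort, args)
  }
  sizes <- if (identical(config$mesh, "auto")) NULL else config$mesh
  meas <- measure_cohort(cohort, threshold = config$threshold,
                         sizes_px = sizes)
  comps <- assemble_comparisons(meas)
  rel <- list(); pairs <- list()
  for (plx in names(comps)) {
    for (cmp in c("repeatability", "reproducibility")) {
      tab <- comps[[plx]][[cmp]]
      row <- reliability_row(tab, plx, cmp, config$icc_model)
      rel[[length(rel) + 1L]] <- row
      Y <- pivot_measurements(tab)
      ba <- bland_altman(Y[, 1], Y[, 2])
      pairs[[length(pairs) + 1L]] <-
        cbind(data.frame(plexus = plx, comparison = cmp,
                         participant_id = rownames(Y)), ba$pairs)
    }
  }
  rel <- do.call(rbind, rel)
  pairs <- do.call(rbind, pairs)

  # Table-1-style demographics and Table-2-style per-observer FD summary
  first <- meas[!duplicated(meas$participant_id), ]
  age <- 2018 - first$birth_year   # study visits dated 2017-2018
  t1 <- data.frame(
    characteristic = c("Age, years", "Study eye, right", "Participants, n"),
    value = c(summarize_values(age, digits = 1)$formatted,
              format_count_percent(sum(first$eye == "right"),
                                   nrow(first))$formatted,
              as.character(nrow(first))))
  t2 <- do.call(rbind, lapply(split(meas, meas[c("plexus", "observer_id")]),
    function(g) {
      s <- summarize_values(g$fd, digits = 3)
      percv <- split(g$fd, g$participant_id)
      percv <- percv[vapply(percv, length, 1L) >= 2L]
      data.frame(plexus = g$plexus[1], observer_id = g$observer_id[1],
                 mean_fd = s$mean, sd_fd = s$sd, formatted = s$formatted,
                 cv_percent = if (length(percv))
                   cv(percv)$cv_percent else NA_real_)
    }))
  rownames(t2) <- NULL

  out <- list(measurements = meas, reliability = rel,
              bland_altman_pairs = pairs, table1 = t1, table2 = t2,
              config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) write.csv(df, file.path(config$output_dir, f),
                                    row.names = FALSE)
    wr(meas, "fd.csv"); wr(rel, "reliability.csv")
    wr(pairs, "bland_altman_pairs.csv")
    wr(t1, "table1.csv"); wr(t2, "table2.csv")
    jsonlite::write_json(rel, file.path(config$output_dir,
                                        "reliability.json"),
                         dataframe = "rows", digits = NA)
    yaml::write_yaml(unclass(config)[c("threshold", "mesh", "icc_model",
                                       "seed")],
                     file.path(config$output_dir, "config.yaml"))
  }
  invisible(out)
}
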