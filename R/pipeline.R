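# Orchestration: simulate -> extract -> stats with a JSON config, seed
# fan-out and reproducible run manifests.

#' Default run configuration
#'
#' A nested list holding every tunable of the pipeline: simulation
#' parameters, fitting options and statistics options, plus the master
#' seed. Serializes round-trip-stably to JSON via [write_config()] /
#' [read_config()]; unknown keys in a config file are rejected.
#'
#' @param seed master seed; all per-subject randomness derives from it via
#'   [subject_seed()].
#' @return List of class `"run_config"`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulation = list(
      n_subjects = 93L,
      protocol_mix = 16 / 93,
      effect = unclass(cohort_effect()),
      pain_model = unclass(pain_link()),
      population = unclass(cohort_population()),
      moment_mode = "sampled",
      grid_shape = c(16L, 16L, 6L),
      voxel_size = c(4, 4, 6)
    ),
    fitting = list(
      gain = 5,
      fit_vp = TRUE,
      bounds = list(ktrans = c(0, 5), ve = c(1e-3, 1), vp = c(0, 0.5)),
      n_polish = 3L
    ),
    stats = list(
      mode = "pooled",
      conf_level = 0.95
    )
  ), class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' `read_config` validates the file against the [default_config()] schema
#' and rejects unknown keys; missing keys fall back to the defaults.
#'
#' @param config a `run_config` list.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  merged <- .merge_config(unclass(default_config()), raw, "config")
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "run_config")
}

.merge_config <- function(template, supplied, where) {
  if (!is.list(template)) return(supplied)
  unknown <- setdiff(names(supplied), names(template))
  if (length(unknown))
    stop("unknown config key(s) under ", where, ": ", paste(unknown, collapse = ", "))
  for (nm in names(supplied)) {
    template[[nm]] <- if (is.list(template[[nm]]))
      .merge_config(template[[nm]], supplied[[nm]], paste0(where, "$", nm))
    else supplied[[nm]]
  }
  template
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

.sim_objects <- function(config) {
  sim <- config$simulation
  simulate_cohort(
    n_subjects = sim$n_subjects,
    effect = do.call(cohort_effect, sim$effect),
    pain_model = do.call(pain_link, sim$pain_model),
    population = do.call(cohort_population, sim$population),
    protocol_mix = sim$protocol_mix,
    seed = config$seed,
    moment_mode = sim$moment_mode)
}

#' Simulate a cohort and write its images and tables
#'
#' Generates the synthetic cohort of the configuration and writes, per
#' subject-visit, the 4D dynamic NIfTI series and ROI mask, plus
#' `clinical.csv` and `truth.csv`. The configured voxel size must be coarse
#' enough for the largest synovium to fit the configured grid.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @return The `dce_cohort`, invisibly; files land in `out_dir`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  cohort <- .sim_objects(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- config$simulation
  for (s in cohort$subjects) {
    for (visit in c("baseline", "followup"))
      render_4d_volume(s, visit, grid_shape = sim$grid_shape,
                       voxel_size = sim$voxel_size, out_dir = out_dir)
  }
  write_cohort_tables(cohort, out_dir)
  invisible(cohort)
}

#' Extract the cohort table from dynamic images, masks and a clinical table
#'
#' For every subject-visit pair found in the clinical table, reads
#' `{subject}_{visit}_dyn.nii.gz` and `{subject}_{visit}_mask.nii.gz`,
#' computes the voxelwise parameters, aggregates medians over the ROI and
#' the synovial volume, and assembles the long cohort table. Subjects with
#' missing or unreadable files are excluded and listed in the exclusions
#' report; the run continues.
#'
#' @param image_dir directory with the dynamic series.
#' @param mask_dir directory with the masks (may equal `image_dir`).
#' @param clinical_csv clinical table CSV with columns
#'   `subject_id, visit, protocol, koos_pain`.
#' @param config a `run_config` (fitting options and protocols).
#' @param out_file optional path for the cohort CSV.
#' @return The `cohort_table`; exclusions are in `attr(, "exclusions")` and,
#'   per subject-visit, voxel counts in `attr(, "voxel_log")`.
#' @export
run_extract <- function(image_dir, mask_dir = image_dir, clinical_csv, config,
                        out_file = NULL) {
  stopifnot(inherits(config, "run_config"))
  clinical <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "protocol", "koos_pain")
  if (!all(need %in% names(clinical)))
    stop("clinical table missing columns: ",
         paste(setdiff(need, names(clinical)), collapse = ", "))
  protos <- list(standard = dce_protocol("standard"), ltr = dce_protocol("ltr"))
  aifs <- lapply(protos, function(p) make_population_aif(aif_params(), p))
  fitcfg <- config$fitting

  rows <- list(); log_rows <- list(); failures <- list()
  for (r in seq_len(nrow(clinical))) {
    sid <- clinical$subject_id[r]; visit <- clinical$visit[r]
    pname <- clinical$protocol[r]
    dyn_f <- file.path(image_dir, sprintf("%s_%s_dyn.nii.gz", sid, visit))
    msk_f <- file.path(mask_dir, sprintf("%s_%s_mask.nii.gz", sid, visit))
    res <- tryCatch({
      if (!file.exists(dyn_f) || !file.exists(msk_f))
        stop("missing image or mask file")
      if (!pname %in% names(protos)) stop("unknown protocol '", pname, "'")
      pr <- protos[[pname]]
      dyn <- RNifti::readNifti(dyn_f)
      msk_img <- RNifti::readNifti(msk_f)
      vs <- RNifti::pixdim(msk_img)[1:3]
      mask <- roi_mask(array(as.numeric(msk_img) != 0, dim = dim(msk_img)[1:3]), vs)
      vm <- suppressMessages(voxelwise_maps(
        array(as.numeric(dyn), dim = dim(dyn)), mask, pr, aif = aifs[[pname]],
        gain = fitcfg$gain, bounds = fitcfg$bounds, fit_vp = fitcfg$fit_vp,
        n_polish = fitcfg$n_polish))
      ev <- vm$evaluable
      data.frame(
        subject_id = sid, visit = visit,
        volume_mm3 = synovial_volume(mask),
        rer = median_over_roi(vm$rer, ev),
        re_late = median_over_roi(vm$re_late, ev),
        re_max = median_over_roi(vm$re_max, ev),
        ktrans = median_over_roi(vm$ktrans, ev),
        ve = median_over_roi(vm$ve, ev),
        n_voxels = nrow(vm), n_evaluable = sum(ev),
        n_converged = sum(vm$converged, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        subject_id = sid, visit = visit, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no subject-visit could be extracted")
  imaging <- do.call(rbind, rows)
  voxel_log <- imaging[c("subject_id", "visit", "n_voxels", "n_evaluable", "n_converged")]
  imaging <- imaging[setdiff(names(imaging), c("n_voxels", "n_evaluable", "n_converged"))]
  tab <- suppressMessages(build_cohort_table(imaging, clinical))
  excl <- attr(tab, "exclusions")
  if (length(failures)) {
    fail_df <- do.call(rbind, failures)
    excl <- rbind(excl, fail_df[c("subject_id", "reason")])
  }
  attr(tab, "exclusions") <- unique(excl)
  attr(tab, "voxel_log") <- voxel_log
  if (nrow(attr(tab, "exclusions")))
    message(nrow(attr(tab, "exclusions")), " exclusion record(s); see attr(, 'exclusions')")
  if (!is.null(out_file)) {
    utils::write.csv(as.data.frame(tab), out_file, row.names = FALSE)
    excl_file <- file.path(dirname(out_file), "exclusions.csv")
    utils::write.csv(attr(tab, "exclusions"), excl_file, row.names = FALSE)
  }
  tab
}

#' Run the responsiveness and association statistics on a cohort table
#'
#' @param cohort a `cohort_table` or path to a cohort CSV.
#' @param config a `run_config`.
#' @param out_dir optional directory for `standardized_change.csv`,
#'   `associations.csv` and `manifest.json`.
#' @return List with `standardized_change` and `associations`.
#' @export
run_stats <- function(cohort, config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  sc <- standardized_change_panel(cohort, mode = config$stats$mode,
                                  conf_level = config$stats$conf_level)
  if (length(unique(cohort$subject_id)) >= 4L) {
    assoc <- association_table(cohort, conf_level = config$stats$conf_level)
  } else {
    message("fewer than 4 subjects: association analysis skipped")
    assoc <- NULL
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(as.data.frame(sc),
                     file.path(out_dir, "standardized_change.csv"), row.names = FALSE)
    if (!is.null(assoc))
      utils::write.csv(assoc, file.path(out_dir, "associations.csv"), row.names = FALSE)
    manifest <- list(seed = config$seed,
                     config_hash = .config_hash(config),
                     package_version = as.character(utils::packageVersion("synovadce")),
                     r_version = R.version.string,
                     stats_options = config$stats,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(standardized_change = sc, associations = assoc)
}

#' Run the full pipeline: simulate, extract, analyse
#'
#' @param config a `run_config`.
#' @param out_dir results directory; images land in `out_dir/images`,
#'   tables and the manifest in `out_dir`.
#' @return List with `cohort` (extracted `cohort_table`),
#'   `standardized_change`, `associations`, and `manifest` path.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  img_dir <- file.path(out_dir, "images")
  step <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  step("simulate", run_simulate(config, img_dir))
  tab <- step("extract", run_extract(img_dir, img_dir,
                                     file.path(img_dir, "clinical.csv"), config,
                                     out_file = file.path(out_dir, "cohort.csv")))
  res <- step("stats", run_stats(tab, config, out_dir))
  c(list(cohort = tab), res,
    list(manifest = file.path(out_dir, "manifest.json")))
}
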