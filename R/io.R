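#' Write / read a grid-aligned volume as NIfTI
#'
#' Doses are stored in Gy as floats, masks as 0/1 integers; the voxel
#' spacing is carried in the NIfTI header.
#'
#' @param x a [dose_grid()] or [structure_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  if (inherits(x, "dose_grid")) {
    arr <- x$values
    grid <- x$grid
  } else if (inherits(x, "structure_mask")) {
    arr <- array(as.integer(x$voxels), dim = x$grid$shape)
    grid <- x$grid
  } else stop("'x' must be a dose_grid or structure_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param as one of `"dose"` or `"mask"`.
#' @param name structure name when reading a mask.
#' @export
read_volume_nifti <- function(path, as = c("dose", "mask"),
                              name = "structure") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  grid <- voxel_grid(dim(img)[1:3], RNifti::pixdim(img)[1:3])
  arr <- array(as.numeric(img), dim = grid$shape)
  if (as == "dose") dose_grid(arr, grid)
  else structure_mask(name, arr > 0.5, grid)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML or JSON configuration and fills defaults: the default
#' phantom geometry, the 69.96/60.06 Gy in 33-fraction prescriptions,
#' the default per-condition perturbations and the default PQM table.
#' Recognised fields: `n_patients`, `master_seed`, `output_dir`,
#' `phantom` (arguments of [phantom_spec()]), `perturbations` (named
#' lists of [perturbation_params()] arguments for `B15_RECAL` /
#' `B15_REOPT`), `pqm_table_path`. All validation failures are
#' collected and reported together.
#'
#' @param path configuration file, or `NULL` for all defaults.
#' @param overrides named list overriding top-level fields.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list()
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  raw[names(overrides)] <- overrides

  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  n_patients <- raw$n_patients %||% 10L
  if (!is.numeric(n_patients) || n_patients < 1)
    note("'n_patients' must be a positive integer")
  master_seed <- raw$master_seed %||% 1L
  if (!is.numeric(master_seed)) note("'master_seed' must be an integer")

  phantom <- tryCatch(
    do.call(phantom_spec, raw$phantom %||% list()),
    error = function(e) {
      note(paste("phantom:", conditionMessage(e)))
      NULL
    })

  perts <- list(B15_RECAL = default_perturbation_params("B15_RECAL"),
                B15_REOPT = default_perturbation_params("B15_REOPT"))
  for (cond in names(raw$perturbations %||% list())) {
    if (!cond %in% names(perts)) {
      note(paste0("perturbations: unknown condition '", cond, "'"))
      next
    }
    perts[[cond]] <- tryCatch(
      do.call(perturbation_params, raw$perturbations[[cond]]),
      error = function(e) {
        note(paste0("perturbations$", cond, ": ", conditionMessage(e)))
        perts[[cond]]
      })
  }

  table <- if (!is.null(raw$pqm_table_path)) {
    if (!file.exists(raw$pqm_table_path)) {
      note(paste("pqm_table_path does not exist:", raw$pqm_table_path))
      NULL
    } else tryCatch(read_pqm_table(raw$pqm_table_path),
                    error = function(e) {
                      note(paste("pqm_table:", conditionMessage(e)))
                      NULL
                    })
  } else default_pqm_table()

  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(list(n_patients = as.integer(n_patients),
                 master_seed = as.integer(master_seed),
                 output_dir = raw$output_dir %||% "mrplanqa_out",
                 phantom = phantom,
                 perturbations = perts,
                 pqm_table = table,
                 dose_params = do.call(dose_model_params,
                                       raw$dose_model %||% list())),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> derive shells -> metrics -> PQM scores -> paired
#' comparison -> dose-difference maps, writing the artifact tree under
#' `config$output_dir`: per-patient NIfTI volumes (every structure mask
#' and condition dose), `metrics.csv`, `scores.csv`, `comparison.csv`,
#' difference-map NIfTIs and a JSON manifest with per-file MD5
#' checksums. Idempotent for a fixed master seed.
#'
#' @param config a [load_config()] result.
#' @param write_volumes write the (large) per-patient NIfTI volumes;
#'   tables and maps are always written.
#' @return The manifest, invisibly (list with `files`, a data frame of
#'   path/checksum records).
#' @export
run_pipeline <- function(config, write_volumes = FALSE) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  stage <- "simulate"
  manifest_files <- character()
  cohort <- tryCatch(
    generate_cohort(config$n_patients, config$master_seed,
                    base_spec = config$phantom,
                    perturbations = config$perturbations,
                    dose_params = config$dose_params),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))

  if (write_volumes) {
    stage <- "volumes"
    for (pat in cohort) {
      pdir <- file.path(out, sprintf("patient_%02d", pat$patient))
      dir.create(pdir, showWarnings = FALSE)
      for (nm in names(pat$structs$masks)) {
        p <- file.path(pdir, paste0("mask_", nm, ".nii.gz"))
        write_volume_nifti(pat$structs$masks[[nm]], p)
        manifest_files <- c(manifest_files, p)
      }
      for (cond in names(pat$doses)) {
        p <- file.path(pdir, paste0("dose_", cond, ".nii.gz"))
        write_volume_nifti(pat$doses[[cond]], p)
        manifest_files <- c(manifest_files, p)
      }
    }
  }

  stage <- "metrics"
  metrics_df <- cohort_metrics(cohort)
  mpath <- file.path(out, "metrics.csv")
  utils::write.csv(metrics_df, mpath, row.names = FALSE)

  stage <- "score"
  scores_df <- cohort_scores(metrics_df, config$pqm_table)
  spath <- file.path(out, "scores.csv")
  utils::write.csv(scores_df, spath, row.names = FALSE)

  stage <- "compare"
  cmp_in <- cbind(metrics_df[c("patient", "condition")],
                  metrics_df[setdiff(names(metrics_df),
                                     c("patient", "condition"))],
                  total_pqm = scores_df$total)
  comparison <- paired_difference_table(cmp_in)
  cpath <- file.path(out, "comparison.csv")
  utils::write.csv(comparison, cpath, row.names = FALSE)

  stage <- "diffmap"
  dpaths <- character()
  for (pat in cohort) {
    for (cond in setdiff(names(pat$doses), "B0")) {
      dm <- dose_difference_map(pat$doses$B0, pat$doses[[cond]])
      p <- file.path(out, sprintf("diff_%s_minus_B0_patient_%02d.nii.gz",
                                  cond, pat$patient))
      # signed cGy map, written directly (dose_grid would reject < 0)
      img <- RNifti::asNifti(dm$cgy_raw)
      RNifti::pixdim(img) <- dm$grid$spacing_mm
      RNifti::writeNifti(img, p)
      dpaths <- c(dpaths, p)
    }
  }
  manifest_files <- c(manifest_files, mpath, spath, cpath, dpaths)

  stage <- "manifest"
  files <- data.frame(path = manifest_files,
                      md5 = unname(tools::md5sum(manifest_files)),
                      stringsAsFactors = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("mrplanqa")),
                   master_seed = config$master_seed,
                   n_patients = config$n_patients,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   files = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(manifest)
}

#' Verify a pipeline output tree against its manifest
#'
#' @param out_dir directory containing `manifest.json`.
#' @return `TRUE` if every file exists with a matching checksum;
#'   otherwise an error naming the offending files.
#' @export
verify_manifest <- function(out_dir) {
  man <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"))
  files <- man$files
  missing <- files$path[!file.exists(files$path)]
  if (length(missing))
    stop("manifest check failed; missing files: ",
         paste(missing, collapse = ", "))
  now <- unname(tools::md5sum(files$path))
  bad <- files$path[now != files$md5]
  if (length(bad))
    stop("manifest check failed; checksum mismatch: ",
         paste(bad, collapse = ", "))
  TRUE
}
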