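#!/usr/bin/env Rscript
# Thin command-line driver over the mrplanqa package.
#
#   Rscript scripts/mrplanqa.R run      [--config FILE] [--seed S]
#                                       [--n-patients N] [--out DIR]
#                                       [--volumes]
#   Rscript scripts/mrplanqa.R score    --metrics FILE [--table FILE]
#                                       --out FILE
#   Rscript scripts/mrplanqa.R diffmap  --a A.nii --b B.nii --out D.nii
#
# Exit codes: 0 success, 1 validation error, 2 runtime error.

suppressPackageStartupMessages(library(mrplanqa))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) {
  cat("usage: mrplanqa.R <run|score|diffmap> [options]\n")
  quit(status = 1)
}
cmd <- argv[1]
opts <- argv[-1]
get_opt <- function(flag, default = NULL) {
  i <- match(flag, opts)
  if (is.na(i) || i == length(opts)) default else opts[i + 1]
}
has_flag <- function(flag) flag %in% opts

run_guarded <- function(expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    cat("error:", msg, "\n", file = stderr())
    quit(status = if (grepl("invalid configuration|must be|lacks", msg))
      1 else 2)
  })
}

if (cmd == "run") {
  run_guarded({
    overrides <- list()
    if (!is.null(get_opt("--seed")))
      overrides$master_seed <- as.integer(get_opt("--seed"))
    if (!is.null(get_opt("--n-patients")))
      overrides$n_patients <- as.integer(get_opt("--n-patients"))
    if (!is.null(get_opt("--out")))
      overrides$output_dir <- get_opt("--out")
    cfg <- load_config(get_opt("--config"), overrides)
    man <- run_pipeline(cfg, write_volumes = has_flag("--volumes"))
    cat("pipeline complete:", nrow(man$files), "artifacts in",
        cfg$output_dir, "\n")
  })
} else if (cmd == "score") {
  run_guarded({
    metrics <- utils::read.csv(get_opt("--metrics"))
    tab <- if (is.null(get_opt("--table"))) default_pqm_table()
    else read_pqm_table(get_opt("--table"))
    out <- get_opt("--out", "scores.csv")
    utils::write.csv(cohort_scores(metrics, tab), out, row.names = FALSE)
    cat("wrote", out, "\n")
  })
} else if (cmd == "diffmap") {
  run_guarded({
    a <- read_volume_nifti(get_opt("--a"), "dose")
    b <- read_volume_nifti(get_opt("--b"), "dose")
    dm <- dose_difference_map(a, b)
    img <- RNifti::asNifti(dm$cgy_raw)
    RNifti::pixdim(img) <- dm$grid$spacing_mm
    RNifti::writeNifti(img, get_opt("--out", "diff.nii.gz"))
    cat("wrote", get_opt("--out", "diff.nii.gz"), "\n")
  })
} else {
  cat("unknown command '", cmd, "'\n", sep = "")
  quit(status = 1)
}
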