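# Run configuration (YAML), fixture generation, and the lambda sweep.
# The command-line entry point (inst/cli/mdftn.R) is a thin wrapper over
# these functions and the exported module surfaces.

run_config_schema <- list(
  simulate = c("n_sources", "n_pairs_per_source", "size", "n_ellipses",
               "hu_background", "hu_offsets", "body_radius_fraction",
               "I0", "sigma_e", "filter", "n_angles", "n_detectors",
               "seed", "format"),
  model = c("n_sources", "base_channels", "bottleneck_channels", "n_ftm",
            "use_ftm", "use_sekg", "backbone", "in_channels", "sekg_kernel",
            "red_channels"),
  train = c("epochs", "batch_size", "patch_size", "initial_lr", "lr_decay",
            "lr_period", "alpha", "lambda", "seed", "steps_per_epoch"),
  eval = c("split", "which"),
  io = c("corpus_dir", "out_dir", "manifest")
)

#' Load and validate a run configuration
#'
#' Reads a YAML file with the nested sections `simulate`, `model`, `train`,
#' `eval`, `io`. Unknown sections or keys are rejected before any work
#' starts; missing keys fall back to package defaults. Every pipeline run
#' writes its fully resolved configuration next to its outputs.
#'
#' @param path Path to a YAML file, or a named list with the same shape.
#' @return A validated list of class `mdftn_run_config`.
#' @export
mdftn_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("run config must be a YAML mapping")
  bad_sec <- setdiff(names(cfg), names(run_config_schema))
  if (length(bad_sec))
    stop(sprintf("unknown config section(s): %s", paste(bad_sec, collapse = ", ")))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), run_config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "mdftn_run_config")
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg An `mdftn_run_config` (or plain list).
#' @param out_dir Output directory.
#' @return The written path, invisibly.
#' @export
write_resolved_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(out_dir, "resolved_config.yaml")
  meta <- list(package_version = as.character(utils::packageVersion("mdftn")))
  yaml::write_yaml(c(unclass(cfg), list(version = meta)), p)
  invisible(p)
}

config_profiles <- function(sim) {
  size <- sim$size %||% 256L
  n_sources <- sim$n_sources %||% 3L
  defaults <- default_source_profiles(size)
  I0 <- sim$I0 %||% vapply(defaults, `[[`, numeric(1), "I0")
  sig <- sim$sigma_e %||% vapply(defaults, `[[`, numeric(1), "sigma_e")
  filt <- sim$filter %||% vapply(defaults, `[[`, character(1), "filter")
  g <- ct_geometry(sim$n_angles %||% defaults[[1]]$geometry$n_angles,
                   sim$n_detectors %||% defaults[[1]]$geometry$n_detectors)
  lapply(seq_len(n_sources), function(k)
    source_profile(LETTERS[k], I0 = rep_len(I0, n_sources)[k],
                   sigma_e = rep_len(sig, n_sources)[k],
                   filter = rep_len(filt, n_sources)[k], geometry = g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation section of a config
#'
#' @param cfg An `mdftn_run_config`.
#' @param out_dir Corpus output directory (overrides `io$corpus_dir`).
#' @return The corpus manifest, invisibly.
#' @export
run_simulate <- function(cfg, out_dir = NULL) {
  sim <- cfg$simulate %||% list()
  out_dir <- out_dir %||% cfg$io$corpus_dir %||% stop("no corpus_dir given")
  spec <- phantom_spec(size = sim$size %||% 256L,
                       n_ellipses = sim$n_ellipses %||% 8L,
                       hu_background = sim$hu_background %||% 0,
                       hu_offsets = sim$hu_offsets %||% c(-150, 250),
                       body_radius_fraction = sim$body_radius_fraction %||% 0.85)
  man <- build_multisource_corpus(
    out_dir, n_pairs_per_source = sim$n_pairs_per_source %||% 200L,
    profiles = config_profiles(sim), phantom = spec,
    rng_seed = sim$seed %||% 17L, format = sim$format %||% "rds")
  write_resolved_config(cfg, out_dir)
  invisible(man)
}

#' Generate the bundled miniature multisource corpus
#'
#' A three-source corpus of 10 pairs per source at 64 x 64 used by the unit
#' tests and examples; fully deterministic given `seed` and generated
#' programmatically (no downloads, no stored data).
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @param n_pairs Pairs per source (default 10).
#' @param size Image side length (default 64).
#' @return The corpus manifest, invisibly.
#' @export
make_test_fixtures <- function(dir = file.path(tempdir(), "mdftn_fixtures"),
                               seed = 42L, n_pairs = 10L, size = 64L) {
  build_multisource_corpus(
    dir, n_pairs_per_source = n_pairs,
    profiles = low_dose_study_profiles(size),
    phantom = phantom_spec(size = size, n_ellipses = 6L),
    rng_seed = seed, format = "rds")
}

#' Sweep the SSIM loss weight
#'
#' Trains one model per candidate SSIM weight (default the study grid
#' `{0, 1, 0.1, 0.01, 0.005, 0.001, 0.0001}`) under an identical budget and
#' seed and reports the per-source test metrics side by side.
#'
#' @param manifest Corpus manifest (data frame or path).
#' @param lambdas Numeric vector of SSIM weights.
#' @param model [mdftn_config()].
#' @param train [train_config()]; its `lambda` is overridden per run.
#' @param data_dir Base directory for manifest paths.
#' @param verbose Passed to [mdftn()].
#' @return Data frame: one row per (lambda, source) with the metric summary.
#' @export
lambda_sweep <- function(manifest,
                         lambdas = c(0, 1, 0.1, 0.01, 0.005, 0.001, 0.0001),
                         model = mdftn_config(), train = train_config(),
                         data_dir = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(data_dir)) data_dir <- attr(manifest, "dir")
  rows <- list()
  for (lam in lambdas) {
    tr <- train
    tr$lambda <- lam
    fit <- mdftn(manifest, model = model, train = tr, data_dir = data_dir,
                 verbose = verbose)
    s <- evaluate_dataset(fit, manifest, data_dir = data_dir)$summary
    rows[[length(rows) + 1L]] <- cbind(lambda = lam, s, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
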