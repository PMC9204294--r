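#' Read a run configuration
#'
#' YAML configuration with per-command sections (`crop`, `clip`, `arch`,
#' `train`, `simulate`, `grid`).  Unknown top-level keys are an error so
#' that typos fail loudly.  The packaged default
#' (`system.file("extdata", "default_config.yaml", package = "recnn")`)
#' pre-fills the published protocol: the MNI hippocampal crop, the
#' \[-1, 2.5\] clip, the 8-16-32-64-128 backbone and the Adam schedule.
#'
#' @param path Path to a YAML file; `NULL` loads the packaged default.
#' @return Named list of configuration sections.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml", package = "recnn")
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("crop", "clip", "arch", "train", "simulate", "grid")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  cfg
}

.config_control <- function(tr) {
  recnn_control(
    lr_base = tr$lr_base %||% 5e-4,
    batch_size = tr$batch_size %||% 32L,
    epochs = tr$epochs %||% 120L,
    warmup_epochs = tr$warmup_epochs %||% 2L,
    decay_every = tr$decay_every %||% 40L,
    decay_factor = tr$decay_factor %||% 5,
    train_fraction = tr$train_fraction %||% 0.8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
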