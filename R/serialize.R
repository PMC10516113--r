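# On-disk containers.  A dataset or checkpoint is a single RDS archive of
# named arrays plus a JSON sidecar-free metadata list (config, seed, and a
# content hash) embedded in the object itself, so every artifact is
# self-describing and a run is reconstructible from its outputs.

artifact_meta <- function(seed, config = NULL) {
  list(package = "odinflow",
       version = as.character(utils::packageVersion("odinflow")),
       seed = seed,
       config_hash = if (!is.null(config)) config_hash(config),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# Small stable hash of a configuration list (FNV-1a over its serialized
# JSON), used to tag artifacts and detect sweep-cell reuse.
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save a spike dataset or ground-truth system to disk
#'
#' @param x a `spike_dataset` or `ground_truth_system`.
#' @param path output file path (RDS archive).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(x, path) {
  stopifnot(inherits(x, "spike_dataset") || inherits(x, "ground_truth_system"))
  x$meta <- artifact_meta(x$seed)
  saveRDS(x, path)
  invisible(path)
}

#' Load a spike dataset or ground-truth system
#'
#' @param path file written by [save_dataset()].
#' @return The stored object.
#' @export
load_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "spike_dataset") && !inherits(x, "ground_truth_system")) {
    stop("not an odinflow dataset archive: ", path)
  }
  x
}

#' Save a trained model checkpoint
#'
#' Stores the parameter arrays, configuration and training log in one RDS
#' archive tagged with the config hash and seed.
#'
#' @param model an `odin_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "odin_model"))
  model$meta <- artifact_meta(model$config$seed, model$config)
  saveRDS(model, path)
  invisible(path)
}

#' Load a trained model checkpoint
#'
#' @param path file written by [save_model()].
#' @return The stored `odin_model`.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "odin_model")) stop("not an odinflow checkpoint: ", path)
  x
}
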