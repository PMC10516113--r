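# Experiment driver: trains one model per (readout, D_hat, seed) cell on a
# shared synthetic benchmark, evaluates the full metric suite, and writes a
# tidy long-format results table (model_id, readout, D_hat, seed, metric,
# value).  Cells are resumable: a completed cell's RDS result is reused on
# rerun.

#' Evaluate a trained model against its ground truth
#'
#' Computes the full metric suite on the validation split: spike NLL,
#' Rate R2, State R2 (with alignment map), mean activation-recovery R2,
#' and, for linear readouts, the effective rank of the readout weights.
#'
#' @param model a trained `odin_model`.
#' @param gts the [generate_benchmark()] object it was trained on.
#' @param split dataset split to evaluate (default `"valid"`).
#' @return A list with `metrics` (named numeric vector), `state_fit`,
#'   `inference`.
#' @export
evaluate_model <- function(model, gts, split = "valid") {
  ds <- gts$dataset
  inf <- infer(model, ds, split)
  idx <- inf$trial_idx
  sr <- state_r2(gts$Z[idx, , , drop = FALSE], inf$Z_hat)
  metrics <- c(
    spike_nll = spike_nll(ds$X[idx, , , drop = FALSE], inf$rates),
    rate_r2 = rate_r2(gts$Y[idx, , , drop = FALSE], inf$rates),
    state_r2 = sr$r2,
    activation_r2 = mean(activation_recovery(gts, inf$Z_hat, inf$rates,
                                             sr$map, trial_idx = idx)))
  if (model$config$readout == "linear") {
    metrics["effective_rank"] <- effective_rank(model$params$readout$W[[1]])
  }
  list(metrics = metrics, state_fit = sr, inference = inf)
}

#' Run a model sweep over readouts, dimensionalities and seeds
#'
#' @param cells data frame with columns `readout`, `D_hat`, `seed`, one row
#'   per model to train.
#' @param gts a [generate_benchmark()] object shared by all cells.
#' @param out_dir directory for per-cell checkpoints and the combined
#'   results CSV; created if missing.
#' @param base_config a [model_config()] whose non-cell fields (epochs,
#'   sizes, learning rate) apply to every cell.
#' @param verbose print progress.
#' @return A tidy data frame (`model_id`, `readout`, `D_hat`, `seed`,
#'   `metric`, `value`), also written to `out_dir/results.csv`.
#' @export
run_sweep <- function(cells, gts, out_dir, base_config = model_config(),
                      verbose = TRUE) {
  stopifnot(all(c("readout", "D_hat", "seed") %in% names(cells)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    model_id <- sprintf("%s_d%d_s%d", cell$readout, cell$D_hat, cell$seed)
    cell_file <- file.path(out_dir, paste0(model_id, ".rds"))
    if (file.exists(cell_file)) {
      res <- readRDS(cell_file)
      if (verbose) message("reusing completed cell ", model_id)
    } else {
      cfg <- base_config
      cfg$readout <- as.character(cell$readout)
      cfg$D_hat <- as.integer(cell$D_hat)
      cfg$seed <- as.integer(cell$seed)
      res <- tryCatch({
        model <- train_model(gts$dataset, cfg)
        ev <- evaluate_model(model, gts)
        out <- list(model_id = model_id, metrics = ev$metrics,
                    config_hash = config_hash(cfg), seed = cfg$seed,
                    error = NA_character_)
        saveRDS(out, cell_file)
        save_model(model, file.path(out_dir, paste0(model_id, "_model.rds")))
        out
      }, error = function(e) {
        warning("cell ", model_id, " failed: ", conditionMessage(e))
        list(model_id = model_id, metrics = c(failed = 1),
             config_hash = config_hash(cfg), seed = cfg$seed,
             error = conditionMessage(e))
      })
      if (verbose && is.na(res$error)) message("trained cell ", model_id)
    }
    rows[[i]] <- data.frame(model_id = res$model_id,
                            readout = as.character(cell$readout),
                            D_hat = cell$D_hat, seed = res$seed,
                            metric = names(res$metrics),
                            value = unname(res$metrics),
                            config_hash = res$config_hash,
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE)
  out
}
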