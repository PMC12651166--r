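#' Fit the drug-target interaction model
#'
#' The main entry point: takes labeled (SMILES, sequence, label) records,
#' splits them into stratified train/validation/test partitions, trains the
#' full architecture (or an ablation variant) end to end with Adam and early
#' stopping on validation AUROC, and returns a fitted model object.
#'
#' @param data Data.frame with columns `smiles`, `sequence`, `label`
#'   (see [read_pairs()]), or a path to a pair file.
#' @param config A [dti_config()]; `config$ablation` selects the variant and
#'   `config$seed` controls initialization, splitting, batching and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"dti_model"` with components `theta` (all
#'   parameters), `config`, `history` (per-epoch data.frame), `metrics`
#'   (validation and test [compute_metrics()] reports), `best_epoch`, and
#'   the split row indices.
#' @seealso [predict.dti_model()], [run_ablation()], [save_checkpoint()]
#' @export
#' @examples
#' \donttest{
#' pairs <- synth_pairs(120, seed = 7)
#' cfg <- dti_config(profile = "desk", epochs = 2)
#' fit <- dti_fit(pairs, cfg)
#' print(fit)
#' }
dti_fit <- function(data, config = dti_config(), verbose = FALSE) {
  if (is.character(data) && length(data) == 1) data <- read_pairs(data)
  stopifnot(all(c("smiles", "sequence", "label") %in% names(data)))
  config <- validate_config(config)
  splits <- split_dataset(data, config$split, config$seed)
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  preps <- list(
    train = prepare_records(splits$train, config, cache),
    valid = prepare_records(splits$valid, config, cache),
    test = prepare_records(splits$test, config, cache)
  )
  theta <- init_params(config)
  fitted <- train_loop(theta, preps$train, preps$valid, config, verbose = verbose)
  p_test <- predict_prepared(fitted$theta, preps$test, config)
  m_test <- compute_metrics(vapply(preps$test, `[[`, 0, "label"), p_test,
                            config$threshold)
  structure(list(
    theta = fitted$theta,
    config = config,
    history = fitted$history,
    best_epoch = fitted$epoch,
    metrics = list(valid = fitted$val_metrics, test = m_test),
    split_rows = lapply(splits, attr, "rows"),
    n_obs = nrow(data),
    checkpoint_version = 1L
  ), class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat("Drug-target interaction model (", x$config$ablation, " variant, ",
      x$config$profile, " profile)\n", sep = "")
  cat(sprintf("  %d parameters in %d tensors; trained %d epoch(s), best epoch %d\n",
              n_parameters(x), length(x$theta),
              if (is.null(x$history)) 0L else max(x$history$epoch), x$best_epoch))
  if (!is.null(x$metrics$test)) {
    cat("  test: ")
    print(x$metrics$test)
  }
  invisible(x)
}

#' @export
summary.dti_model <- function(object, ...) {
  structure(list(
    config = object$config,
    n_parameters = n_parameters(object),
    best_epoch = object$best_epoch,
    history = object$history,
    metrics = object$metrics
  ), class = "summary.dti_model")
}

#' @export
print.summary.dti_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("parameters: %d | best epoch: %d\n", x$n_parameters, x$best_epoch))
  cat("validation: ")
  print(x$metrics$valid)
  cat("test      : ")
  print(x$metrics$test)
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `dti_model`.
#' @return Integer count of scalar parameters across all tensors.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$theta, length, 1L))
}

#' @export
coef.dti_model <- function(object, ...) {
  unlist(object$theta)
}

#' Predict interaction probabilities
#'
#' @param object A fitted `dti_model`.
#' @param newdata Data.frame with `smiles` and `sequence` columns (a `label`
#'   column, if present, is ignored for prediction).
#' @param smiles,sequence Alternative scalar interface for a single pair.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.dti_model <- function(object, newdata = NULL, smiles = NULL,
                              sequence = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(smiles) || is.null(sequence)) {
      stop("supply `newdata` or both `smiles` and `sequence`")
    }
    newdata <- data.frame(smiles = smiles, sequence = sequence,
                          stringsAsFactors = FALSE)
  }
  if (is.null(newdata$label)) newdata$label <- 0L
  preps <- prepare_records(newdata, object$config)
  predict_prepared(object$theta, preps, object$config)
}

#' @export
residuals.dti_model <- function(object, data, ...) {
  stopifnot(!missing(data))
  data$label - predict(object, data)
}

#' Plot training history
#'
#' Training loss and validation AUROC per epoch.
#'
#' @param x A `dti_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dti_model <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 20,
                 xlab = "epoch", ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_auroc, type = "b", pch = 20, ylim = c(0, 1),
                 xlab = "epoch", ylab = "validation AUROC", main = "AUROC", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Train and evaluate an ablation variant
#'
#' Trains the requested architecture variant on the same data, split and
#' seed, so reports are directly comparable to the full model's.
#'
#' @param mode One of `"full"`, `"Noco"`, `"single"`, `"NoCross"`.
#' @param data Interaction records.
#' @param config Base configuration; its `ablation` field is replaced by
#'   `mode`.
#' @param verbose Print progress.
#' @return The fitted `dti_model` for the variant.
#' @export
run_ablation <- function(mode, data, config = dti_config(), verbose = FALSE) {
  if (!mode %in% c("full", "Noco", "single", "NoCross")) {
    stop("unknown ablation mode: ", mode)
  }
  config$ablation <- mode
  dti_fit(data, config, verbose = verbose)
}
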