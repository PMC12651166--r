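# Seeded end-to-end training: per-sample forward/backward on the autodiff
# tape, Adam updates, early stopping on validation AUROC, and checkpoint
# save/load.

adam_state <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

# Accumulated gradients (sum) for one batch of prepared samples; returns
# list(loss = mean loss, grads = named list).
batch_gradients <- function(theta, preps, cfg, training = TRUE) {
  # parameter leaves live on their own tape and are shared by every sample
  # in the batch, so per-sample backward sweeps accumulate the batch
  # gradient directly into the leaves
  ptape <- ad_tape(64L)
  nodes <- lapply(theta, function(v) ad_leaf(ptape, v, param = TRUE))
  total <- 0
  for (prep in preps) {
    tp <- ad_tape(384L)
    out <- forward_sample(tp, nodes, prep, cfg, training = training)
    loss <- ad_bce_logits(tp, out$logit, prep$label)
    total <- total + ad_value(loss)
    ad_backward(tp, loss)
  }
  k <- length(preps)
  list(loss = total / k,
       grads = lapply(nodes, function(nd) if (is.null(nd$grad)) NULL else nd$grad / k))
}

# Core training loop over prepared samples. Returns the best-validation
# parameters, the per-epoch history and the epoch retained.
train_loop <- function(theta, preps_train, preps_valid, cfg, verbose = FALSE) {
  state <- adam_state(theta)
  labels_valid <- vapply(preps_valid, `[[`, 0, "label")
  best <- list(auroc = -Inf, theta = theta, epoch = 0L)
  history <- vector("list", cfg$epochs)
  wait <- 0L
  n <- length(preps_train)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      bg <- batch_gradients(theta, preps_train[b], cfg)
      if (!is.finite(bg$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; diverged (check learning rate / inputs)")
      }
      ep_loss <- ep_loss + bg$loss * length(b)
      upd <- adam_step(theta, bg$grads, state, cfg$lr)
      theta <- upd$theta
      state <- upd$state
    }
    pv <- predict_prepared(theta, preps_valid, cfg)
    mv <- compute_metrics(labels_valid, pv, cfg$threshold)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   val_auroc = mv$auroc, val_auprc = mv$auprc,
                                   val_accuracy = mv$accuracy, val_f1 = mv$f1,
                                   val_mcc = mv$mcc)
    if (verbose) {
      message(sprintf("epoch %3d | loss %.4f | val AUROC %.4f", epoch,
                      ep_loss / n, mv$auroc))
    }
    if (!is.na(mv$auroc) && mv$auroc > best$auroc + 1e-12) {
      best <- list(auroc = mv$auroc, theta = theta, epoch = epoch,
                   val_metrics = mv)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  list(theta = best$theta, epoch = best$epoch,
       val_metrics = best$val_metrics,
       history = do.call(rbind, history[!vapply(history, is.null, TRUE)]))
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds all parameters, the full configuration, the training
#' history and the stored validation metrics, plus a format version.
#'
#' @param model A fitted `dti_model`.
#' @param path Destination file.
#' @return `path` (save) or the restored `dti_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dti_model"))
  saveRDS(unclass(model), path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$checkpoint_version) || is.null(obj$theta)) {
    stop("not a model checkpoint: ", path)
  }
  obj$config <- validate_config(structure(obj$config, class = "dti_config"))
  structure(obj, class = "dti_model")
}
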