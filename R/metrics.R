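#' Binary classification metrics
#'
#' Computes the five evaluation metrics from one prediction vector: AUROC
#' (via the rank statistic, equivalent to the probability that a random
#' positive outranks a random negative, ties counted half), AUPRC (average
#' precision, i.e. step-wise integration of the precision-recall curve),
#' and thresholded accuracy, F1 and Matthews correlation coefficient from
#' the full confusion matrix.
#'
#' @param labels 0/1 vector of true classes.
#' @param probabilities Predicted probabilities, same length.
#' @param threshold Cutoff for the thresholded metrics.
#' @return A list of class `"metric_report"`: `auroc`, `auprc`, `accuracy`,
#'   `f1`, `mcc`, `threshold`, `n`. With single-class labels, `auroc` and
#'   `auprc` are `NA` (undefined), never 0.
#' @export
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))$auroc  # 0.75
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(labels) != length(probabilities)) stop("length mismatch")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np > 0 && nn > 0) {
    r <- rank(probabilities)
    auroc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
    ord <- order(probabilities, decreasing = TRUE)
    y <- labels[ord]
    tp <- cumsum(y)
    prec <- tp / seq_along(y)
    rec <- tp / np
    drec <- diff(c(0, rec))
    auprc <- sum(prec * drec)
  } else {
    auroc <- NA_real_
    auprc <- NA_real_
  }
  pred <- as.numeric(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  accuracy <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  structure(list(auroc = auroc, auprc = auprc, accuracy = accuracy, f1 = f1,
                 mcc = mcc, threshold = threshold, n = length(labels)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "n = %d (threshold %.2f): AUROC %.4f | AUPRC %.4f | Acc %.4f | F1 %.4f | MCC %.4f\n",
    x$n, x$threshold, x$auroc, x$auprc, x$accuracy, x$f1, x$mcc))
  invisible(x)
}

#' Compare two configurations across repeated seeded runs
#'
#' Trains both configurations on the same data under `n_runs` seeds and
#' applies a paired t-test to the chosen test metric, mirroring the
#' significance protocol commonly reported for DTI benchmarks.
#'
#' @param data Interaction records (see [read_pairs()]).
#' @param cfg_a,cfg_b Two `dti_config` objects (e.g. full model vs. an
#'   ablation mode).
#' @param n_runs Number of independent runs (seeds `seed + 0:(n_runs-1)`).
#' @param metric Which metric to compare.
#' @param verbose Print progress.
#' @return List with per-run metric vectors `a`, `b` and the `htest` from
#'   [stats::t.test()] (paired).
#' @export
paired_comparison <- function(data, cfg_a, cfg_b, n_runs = 5L,
                              metric = "auroc", verbose = FALSE) {
  a <- numeric(n_runs)
  b <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    sa <- cfg_a; sa$seed <- cfg_a$seed + i - 1L
    sb <- cfg_b; sb$seed <- sa$seed
    ma <- dti_fit(data, sa, verbose = verbose)
    mb <- dti_fit(data, sb, verbose = verbose)
    a[i] <- ma$metrics$test[[metric]]
    b[i] <- mb$metrics$test[[metric]]
  }
  list(a = a, b = b, test = stats::t.test(a, b, paired = TRUE))
}
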