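#' Confusion counts and threshold metrics
#'
#' The positive class is AD (label 1); a sample is predicted positive
#' when its score is greater than or equal to `threshold` (ties on the
#' threshold count as positive so confusion counts are reproducible to
#' the bit).  Accuracy, sensitivity and specificity follow the standard
#' definitions ACC = (TP+TN)/n, SE = TP/(TP+FN), SP = TN/(TN+FP);
#' precision TP/(TP+FP) is reported as an extra column.  With one-sided
#' labels the undefined rate is `NA`, never 0.
#'
#' @param scores Numeric vector of P(AD) scores.
#' @param labels Binary vector (0 = NC, 1 = AD).
#' @param threshold Decision threshold, default 0.5.
#' @return An object of class `eval_report`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = (tp + tn) / n,
                 se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 auc = NA_real_, n = n, threshold = threshold),
            class = "eval_report")
}

#' Area under the ROC curve via the rank statistic
#'
#' AUC computed as the normalized Mann-Whitney U: with midranks, ties
#' between a positive and a negative score count one half.  Equal to the
#' probability that a random AD sample outscores a random NC sample.
#'
#' @param scores Numeric scores (higher = more AD-like).
#' @param labels Binary vector with both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Full evaluation report (confusion metrics plus AUC)
#'
#' @inheritParams confusion
#' @return An `eval_report` with `auc` filled in (NA if only one class
#'   is present).
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  rep <- confusion(scores, labels, threshold)
  if (rep$tp + rep$fn > 0 && rep$tn + rep$fp > 0)
    rep$auc <- roc_auc(scores, labels)
  rep
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d  (TP %d, TN %d, FP %d, FN %d; threshold %.2f)\n",
              x$n, x$tp, x$tn, x$fp, x$fn, x$threshold))
  cat(sprintf("  ACC %.*f  SE %.*f  SP %.*f  AUC %.*f\n",
              digits, x$acc, digits, x$se, digits, x$sp, digits, x$auc))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn, acc = x$acc,
             se = x$se, sp = x$sp, precision = x$precision, auc = x$auc,
             n = x$n, threshold = x$threshold)
}

#' Pooled latent values for distribution inspection
#'
#' Runs the encoder in inference mode over a set of samples and returns
#' the latent means per sample and dimension, together with a
#' per-dimension summary.  Under a strong KL constraint the pooled
#' spread of the latent means shrinks toward zero (the distributions
#' collapse onto N(0,1)); under alpha = 0 they stay scattered.
#'
#' @param model A fitted [recnn()] object with `latent_dim > 0`.
#' @param samples List of [sample_record()]s.
#' @return List with `values` (n x J matrix of latent means), `sigma`
#'   (n x J matrix of latent SDs) and `summary` (data frame with
#'   per-dimension mean and SD of the latent means).
#' @export
latent_histogram <- function(model, samples) {
  stopifnot(inherits(model, "recnn"))
  if (model$latent_dim == 0L) stop("model has no latent bottleneck (J = 0)")
  fw <- .model_forward(model, samples, training = FALSE)
  mu <- fw$latent$mu
  sigma <- exp(fw$latent$log_var / 2)
  summary <- data.frame(dim = seq_len(ncol(mu)),
                        mean = colMeans(mu),
                        sd = apply(mu, 2, stats::sd))
  list(values = mu, sigma = sigma, summary = summary)
}
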