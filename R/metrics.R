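#' Confusion matrix of predicted vs observed classes
#'
#' Builds the K x K count matrix with rows = predicted class and columns =
#' observed class. Classes absent from the data still get zero rows and
#' columns, so matrices over the same label set are always comparable.
#'
#' @param observed,predicted Vectors (or factors) of equal length whose
#'   values all belong to `labels`.
#' @param labels Character vector of class labels (default the four
#'   substrate classes).
#' @return Integer matrix of class `confusion_matrix` with dimnames
#'   `predicted` x `observed`.
#' @export
confusion <- function(observed, predicted, labels = substrate_classes()) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  obs <- factor(as.character(observed), levels = labels)
  prd <- factor(as.character(predicted), levels = labels)
  if (anyNA(obs) || anyNA(prd))
    stop("values outside the label set (or NA) encountered")
  m <- table(predicted = prd, observed = obs)
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(predicted = labels, observed = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix has negative counts")
  if (sum(cm) <= 0) stop("empty confusion matrix")
  invisible(cm)
}

#' Aggregate accuracy and error metrics of a confusion matrix
#'
#' With cell proportions \eqn{p_{ij}} (rows = predicted), prediction margins
#' \eqn{f_i} and observation margins \eqn{o_j}:
#' \itemize{
#'   \item overall accuracy \eqn{OA = \sum_i p_{ii}};
#'   \item multi-category true skill statistic (Peirce / Hanssen-Kuipers)
#'     \eqn{TSS = (\sum_i p_{ii} - \sum_i f_i o_i) / (1 - \sum_j o_j^2)},
#'     which is 0 whenever predictions are independent of observations and
#'     reduces to sensitivity + specificity - 1 for two classes;
#'   \item quantity error \eqn{\frac12 \sum_j |f_j - o_j|} (margin
#'     mismatch);
#'   \item exchange error \eqn{\sum_{i<j} 2\,\min(p_{ij}, p_{ji})} (pairwise
#'     swaps);
#'   \item shift error, the remaining disagreement
#'     \eqn{(1 - OA) - Quantity - Exchange};
#'   \item macro-averaged one-vs-rest true negative rate.
#' }
#' Quantity + Exchange + Shift always equals the total disagreement 1 - OA.
#' With a single observed class the TSS denominator vanishes; TSS is then
#' `NA` and the result is flagged.
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @return List with elements `n, oa, tss, tnr, quantity, exchange, shift`
#'   and logical `tss_undefined`.
#' @export
aggregate_metrics <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  p <- cm / n
  f <- rowSums(p)  # predicted margins
  o <- colSums(p)  # observed margins
  oa <- sum(diag(p))
  denom <- 1 - sum(o^2)
  tss_undef <- denom <= .Machine$double.eps
  tss <- if (tss_undef) NA_real_ else (oa - sum(f * o)) / denom
  quantity <- sum(abs(f - o)) / 2
  pt <- t(p)
  exch <- sum(2 * pmin(p, pt)[upper.tri(p)])
  shift <- (1 - oa) - quantity - exch
  k <- nrow(cm)
  tnr_c <- vapply(seq_len(k), function(i) {
    neg <- n - sum(cm[, i])
    if (neg == 0) return(NA_real_)
    (n - sum(cm[i, ]) - sum(cm[, i]) + cm[i, i]) / neg
  }, numeric(1))
  list(n = n, oa = oa, tss = tss, tnr = mean(tnr_c, na.rm = TRUE),
       quantity = quantity, exchange = exch, shift = shift,
       tss_undefined = tss_undef)
}

#' Per-class user accuracy, producer accuracy and true negative rate
#'
#' User accuracy conditions on the prediction (row-wise), producer accuracy
#' on the observation (column-wise); the TNR is the one-vs-rest proportion
#' of non-class cases correctly not assigned to the class. A class never
#' predicted (or never observed) has an undefined ratio, reported as 0 with
#' a flag rather than dropped.
#'
#' @param cm A `confusion_matrix`.
#' @return Data frame with one row per class: `class, user, producer, tnr,
#'   user_undefined, producer_undefined`.
#' @export
class_metrics <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  k <- nrow(cm)
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  rows <- rowSums(cm)
  cols <- colSums(cm)
  user <- ifelse(rows > 0, diag(cm) / rows, 0)
  producer <- ifelse(cols > 0, diag(cm) / cols, 0)
  tnr <- vapply(seq_len(k), function(i) {
    neg <- n - cols[i]
    if (neg == 0) return(NA_real_)
    (n - rows[i] - cols[i] + cm[i, i]) / neg
  }, numeric(1))
  data.frame(class = labels, user = unname(user),
             producer = unname(producer), tnr = unname(tnr),
             user_undefined = unname(rows == 0),
             producer_undefined = unname(cols == 0),
             stringsAsFactors = FALSE)
}

#' Class imbalance of a prevalence vector
#'
#' Normalised total-variation distance of the class prevalences from the
#' uniform distribution:
#' \deqn{Imbalance = \frac{\frac12 \sum_j |p_j - 1/K|}{1 - 1/K} \in [0,1],}
#' 0 for perfectly balanced classes and 1 when one class holds everything.
#'
#' @param prevalences Non-negative proportions summing to 1.
#' @return A single number in [0, 1].
#' @export
imbalance <- function(prevalences) {
  if (any(prevalences < 0)) stop("negative proportion")
  if (abs(sum(prevalences) - 1) > 1e-6)
    stop("proportions must sum to 1")
  k <- length(prevalences)
  if (k < 2) stop("need at least 2 classes")
  (sum(abs(prevalences - 1 / k)) / 2) / (1 - 1 / k)
}

#' No-information baselines for a K-class problem
#'
#' Expected scores of a predictor that guesses uniformly at random:
#' TSS 0 (it integrates across classes), per-class true positive rate
#' \eqn{1/K}, per-class true negative rate \eqn{1 - 1/K}. Accuracy shown as
#' a difference from these baselines expresses skill relative to chance.
#'
#' @param K Number of classes (>= 2).
#' @return List with elements `tss0`, `tpr0`, `tnr0`.
#' @export
baselines <- function(K) {
  if (K < 2) stop("K must be >= 2")
  list(tss0 = 0, tpr0 = 1 / K, tnr0 = 1 - 1 / K)
}

#' Full metric set for one evaluation cell
#'
#' Convenience wrapper assembling the aggregate metrics, the imbalance of
#' the observed prevalence, the L1 distance between predicted and observed
#' prevalence, and the no-information baselines into one row.
#'
#' @param observed,predicted Class vectors of equal length.
#' @param labels Class labels.
#' @return One-row data frame.
#' @export
metric_set <- function(observed, predicted, labels = substrate_classes()) {
  cm <- confusion(observed, predicted, labels)
  agg <- aggregate_metrics(cm)
  o_prev <- colSums(cm) / sum(cm)
  p_prev <- rowSums(cm) / sum(cm)
  b <- baselines(nrow(cm))
  data.frame(n = agg$n, imbalance = imbalance(o_prev), oa = agg$oa,
             tss = agg$tss, tnr = agg$tnr, quantity = agg$quantity,
             exchange = agg$exchange, shift = agg$shift,
             prev_l1 = sum(abs(p_prev - o_prev)),
             oa_adj = agg$oa - b$tpr0, tnr_adj = agg$tnr - b$tnr0,
             stringsAsFactors = FALSE)
}
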