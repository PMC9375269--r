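# Efficacy prediction by mini-group averaging over the concatenated pair
# features of the final iteration state, plus the evaluation metrics:
# confusion counts, sensitivity/specificity, and the Pearson correlation
# between predicted and observed efficacy.

#' Predict test-siRNA efficacy by mini-group averaging
#'
#' After the removal iteration, the concatenated 8-component pair features
#' at cut-off \code{alpha} (default 65\%, the largest removal cut-off) are
#' computed from the updated training data. Two separate Euclidean
#' mini-group partitions are then built: one over the P-cluster together
#' with the potent training records, one over the I-cluster together with
#' the ineffective training records. Each test record's prediction is the
#' mean experimental efficacy of the same-class training records in its
#' mini-group; a record whose group contains no training donor falls back
#' to the class-wide training mean and is flagged.
#'
#' @param state An \code{\link{run_iteration}} result.
#' @param alpha Cut-off (percent) at which the pair features are computed.
#'   Default 65.
#' @return Data frame with one row per original test record: \code{id},
#'   \code{sequence}, \code{observed}, \code{predicted}, \code{cluster}
#'   ("P" or "I"), \code{group}, \code{n_donors}, \code{fallback}.
#' @export
predict_efficacy <- function(state, alpha = 65) {
  stopifnot(inherits(state, "i_iteration"))
  ds <- state$dataset
  thr <- state$config$potency_threshold
  eff <- ds$inhibition
  C <- .final_c_alpha(state, alpha)
  test_idx <- which(!state$is_train0)
  in_P <- !state$removed[test_idx]

  potent_donors <- which(state$is_train0 & eff >= thr)
  ineff_donors <- which(state$is_train0 & eff < thr)
  if (!length(potent_donors) || !length(ineff_donors))
    stop("both donor classes (potent and ineffective training) must be non-empty")

  predicted <- rep(NA_real_, length(test_idx))
  group <- rep(NA_integer_, length(test_idx))
  n_donors <- rep(0L, length(test_idx))
  fallback <- rep(FALSE, length(test_idx))

  side <- function(rows_local, donors) {
    # rows_local indexes test_idx; donors are dataset row indices
    pred_rows <- test_idx[rows_local]
    idx <- c(pred_rows, donors)
    class_mean <- mean(eff[donors])
    if (!length(pred_rows)) return(invisible())
    if (length(idx) < 2L) {
      predicted[rows_local] <<- class_mean
      fallback[rows_local] <<- TRUE
      return(invisible())
    }
    labels <- .mg_labels(feature_dist(C[idx, , drop = FALSE], "euclidean"))
    donor_labels <- labels[(length(pred_rows) + 1L):length(idx)]
    donor_eff <- eff[donors]
    for (j in seq_along(pred_rows)) {
      g <- labels[j]
      mine <- donor_eff[donor_labels == g]
      group[rows_local[j]] <<- g
      n_donors[rows_local[j]] <<- length(mine)
      if (length(mine)) {
        predicted[rows_local[j]] <<- mean(mine)
      } else {
        predicted[rows_local[j]] <<- class_mean
        fallback[rows_local[j]] <<- TRUE
      }
    }
  }
  side(which(in_P), potent_donors)
  side(which(!in_P), ineff_donors)

  data.frame(id = ds$id[test_idx],
             sequence = ds$sequence[test_idx],
             observed = eff[test_idx],
             predicted = predicted,
             cluster = ifelse(in_P, "P", "I"),
             group = group,
             n_donors = n_donors,
             fallback = fallback,
             stringsAsFactors = FALSE)
}

#' Confusion counts of the cluster assignment
#'
#' Treats membership of the P-cluster as a potent call and membership of
#' the I-cluster as an ineffective call, scored against the true potency
#' labels (observed inhibition vs. the potency threshold): TP = potent in
#' P, FP = ineffective in P, TN = ineffective in I, FN = potent in I.
#'
#' @param state An \code{\link{run_iteration}} result.
#' @return Named list with integer \code{TP}, \code{TN}, \code{FP},
#'   \code{FN}; the four counts sum to the original test-set size.
#' @export
confusion_counts <- function(state) {
  stopifnot(inherits(state, "i_iteration"))
  ds <- state$dataset
  thr <- state$config$potency_threshold
  test_idx <- which(!state$is_train0)
  potent <- ds$inhibition[test_idx] >= thr
  in_P <- !state$removed[test_idx]
  list(TP = sum(potent & in_P), TN = sum(!potent & !in_P),
       FP = sum(!potent & in_P), FN = sum(potent & !in_P))
}

#' Sensitivity and specificity from confusion counts
#'
#' Se = TP / (TP + FN) and Sp = TN / (TN + FP), reported in percent. A
#' zero denominator makes the corresponding metric undefined (NA), never 0.
#'
#' @param TP,TN,FP,FN Confusion counts.
#' @return Named list with \code{Se} and \code{Sp} in percent (exact
#'   values; round for display).
#' @examples
#' se_sp(TP = 98, TN = 228, FP = 5, FN = 14)  # Se 87.5, Sp ~97.9
#' @export
se_sp <- function(TP, TN, FP, FN) {
  se <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  list(Se = se, Sp = sp)
}

#' Pearson correlation between predicted and observed efficacy
#'
#' The (b - 1)-normalized product-moment form: the mean (over b - 1) of the
#' products of the standardized predicted and observed values, using sample
#' standard deviations.
#'
#' @param predicted,observed Numeric vectors of equal length b >= 2, each
#'   with non-zero standard deviation.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pcc <- function(predicted, observed) {
  b <- length(predicted)
  if (length(observed) != b) stop("vectors must have equal length")
  if (b < 2L) stop("need at least 2 observations")
  sp <- stats::sd(predicted)
  so <- stats::sd(observed)
  if (sp == 0 || so == 0)
    stop("correlation undefined: zero variance")
  sum((predicted - mean(predicted)) / sp *
      (observed - mean(observed)) / so) / (b - 1)
}

#' Evaluate a prediction table
#'
#' Combines the confusion counts, sensitivity/specificity and the Pearson
#' correlation between predicted and observed efficacy into one report.
#'
#' @param pred Prediction data frame from \code{\link{predict_efficacy}}.
#' @param potency_threshold Percent threshold defining true potency labels.
#'   Default 70.
#' @return Named list: \code{TP}, \code{TN}, \code{FP}, \code{FN},
#'   \code{Se}, \code{Sp} (percent), \code{PCC}, \code{n_test}.
#' @export
evaluate_predictions <- function(pred, potency_threshold = 70) {
  potent <- pred$observed >= potency_threshold
  in_P <- pred$cluster == "P"
  cc <- list(TP = sum(potent & in_P), TN = sum(!potent & !in_P),
             FP = sum(!potent & in_P), FN = sum(potent & !in_P))
  ss <- se_sp(cc$TP, cc$TN, cc$FP, cc$FN)
  r <- tryCatch(pcc(pred$predicted, pred$observed),
                error = function(e) NA_real_)
  c(cc, ss, list(PCC = r, n_test = nrow(pred)))
}
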