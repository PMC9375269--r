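# The removal iteration: beta thresholds from the potent training records,
# the per-record removal conditions, and the staged procedure that moves
# recognisably ineffective test siRNAs into the training pool (as E3) until
# no further removal occurs. Surviving test records form the P-cluster,
# removed ones the I-cluster.

#' Beta removal thresholds at one stage
#'
#' Computed from the aggregated pair features of the potent training
#' records. For the mini-group types (t = 1, 2), beta1 is the minimum first
#' component; for the mini-cluster types (t = 3, 4), beta1 is the maximum
#' second component among potent records whose first component is zero
#' (+Inf when no such record exists). beta2 is always the maximum second
#' component over the potent training records.
#'
#' @param agg n x 2 aggregated pair matrix for one method type (all
#'   records).
#' @param potent_idx Row indices of the potent training records (at least
#'   one required).
#' @param t Method type, 1 (MG1), 2 (MG2), 3 (Icc1) or 4 (Icc2).
#' @return List with elements \code{beta1} and \code{beta2}.
#' @export
compute_beta <- function(agg, potent_idx, t) {
  if (!length(potent_idx))
    stop("no potent training records; the method is inapplicable")
  if (!t %in% 1:4) stop("t must be 1, 2, 3 or 4")
  c1 <- agg[potent_idx, 1L]
  c2 <- agg[potent_idx, 2L]
  beta1 <- if (t <= 2L) {
    min(c1)
  } else {
    z <- c2[c1 == 0L]
    if (length(z)) max(z) else Inf
  }
  list(beta1 = beta1, beta2 = max(c2))
}

# Condition labels, in evaluation order.
.COND_NAMES <- c("a:t1", "a:t2", "b:t1", "b:t2", "b:t3", "b:t4",
                 "c:t3", "c:t4")

# Vectorized removal conditions for the rows `active` of the four
# aggregated pair matrices. Returns a logical vector plus, per record, the
# first triggering condition label (NA when kept).
.removal_flags <- function(aggs, betas, s, active) {
  m <- matrix(FALSE, length(active), 8L,
              dimnames = list(NULL, .COND_NAMES))
  for (t in 1:2)
    m[, t] <- aggs[[t]][active, 1L] <= betas[[t]]$beta1
  for (t in 1:4)
    m[, 2L + t] <- aggs[[t]][active, 2L] >= max(betas[[t]]$beta2, 1)
  for (t in 3:4)
    m[, 4L + t] <- aggs[[t]][active, 1L] == 0L &
      aggs[[t]][active, 2L] >= min(betas[[t]]$beta1, 16 + s)
  remove <- rowSums(m) > 0L
  condition <- rep(NA_character_, length(active))
  if (any(remove)) {
    first <- apply(m[remove, , drop = FALSE], 1L, which.max)
    condition[remove] <- .COND_NAMES[first]
  }
  list(remove = remove, condition = condition)
}

#' Removal predicate for a single test record
#'
#' A test record is removed when ANY of the following holds: (a) for t = 1
#' or t = 2, its first aggregated component is at most beta1; (b) for any
#' t, its second aggregated component is at least \code{max(beta2, 1)}; (c)
#' for t = 3 or t = 4, its first component is zero and its second component
#' is at least \code{min(beta1, 16 + s)}.
#'
#' Condition (b) carries a positive-evidence guard: a removed record must
#' itself exhibit some ineffective-purity signal (second component > 0).
#' Without it, a stage at which every potent training record has a zero
#' second component (beta2 = 0, which happens for the mini-cluster types
#' when the cluster count approaches the sample count and most clusters
#' are singletons) would fire the condition vacuously and remove every
#' remaining test record; a record with no ineffective-similarity signal
#' cannot meaningfully exceed all potent training records.
#'
#' @param pairs List of four integer pairs (c1, c2), in order MG1, MG2,
#'   Icc1, Icc2.
#' @param betas List of four beta threshold lists (see
#'   \code{\link{compute_beta}}).
#' @param s Stage index of the current cut-off (see
#'   \code{\link{alpha_stage}}).
#' @return List with \code{remove} (logical) and \code{condition} (label of
#'   the first triggering condition, or NA).
#' @export
removal_predicate <- function(pairs, betas, s) {
  aggs <- lapply(pairs, function(p) matrix(as.numeric(p), nrow = 1L))
  fl <- .removal_flags(aggs, betas, s, 1L)
  list(remove = fl$remove, condition = fl$condition)
}

#' Run the removal iteration
#'
#' Drives the staged removal procedure over the ladder of efficacy cut-offs
#' from \code{alpha_start} to \code{alpha_max}. At each stage the training
#' records are split into E-groups at the current cut-off, aggregated pair
#' features and beta thresholds are computed, and every current test record
#' satisfying a removal condition is removed (all at once); removed records
#' join the training pool as E3 (their efficacy is treated as unknown from
#' then on) and the pass repeats until nothing is removed. Mini-group
#' partitions depend only on the sequences and are computed once;
#' mini-cluster partitions are refreshed at each stage start because the
#' cluster count follows the growing training-set size.
#'
#' @param ds A \code{sirna_dataset} with roles assigned.
#' @param alpha_start First cut-off in percent. Default 20.
#' @param alpha_max Largest removal cut-off in percent. Default 65: the
#'   potency threshold itself (70\%) is excluded because records with
#'   efficacy just either side of the threshold are not separable and
#'   potent test records would be falsely removed.
#' @param recompute_icc Refresh the mini-cluster partitions at every stage
#'   start (default TRUE); when FALSE they are computed once from the
#'   initial training-set size.
#' @param keep_history Store the per-pass aggregated feature matrices in
#'   the returned state (useful for audits; default FALSE).
#' @param verbose Print one line per pass.
#' @return An object of class \code{"i_iteration"}: a list with the final
#'   \code{P_cluster} and \code{I_cluster} id sets, the \code{removal_log}
#'   (id, stage, alpha, pass, condition), the per-pass \code{trace} (stage,
#'   alpha, pass, active and removed counts, beta values), the maximum
#'   aggregated component observed (\code{max_aggregate}), and the cached
#'   distance structures needed for prediction.
#' @seealso \code{\link{predict_efficacy}}, \code{\link{confusion_counts}}
#' @export
run_iteration <- function(ds, alpha_start = 20, alpha_max = 65,
                          recompute_icc = TRUE, keep_history = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(ds, "sirna_dataset"))
  if (anyNA(ds$role))
    stop("all records need a role; use split_every_fifth() or split_modulus()")
  thr <- attr(ds, "potency_threshold")
  if (is.null(thr)) thr <- 70
  n <- nrow(ds)
  eff <- ds$inhibition
  is_train0 <- ds$role == "train"
  potent_train <- which(is_train0 & eff >= thr)
  if (!length(potent_train))
    stop("no potent training records; the method is inapplicable")

  feats <- .all_ck_matrices(ds$sequence)
  Deuc <- lapply(feats, feature_dist, metric = "euclidean")
  Dpcc <- lapply(feats, feature_dist, metric = "pcc")
  mg1 <- lapply(Deuc, .mg_labels)
  mg2 <- lapply(Dpcc, .mg_labels)

  removed <- rep(FALSE, n)
  alphas <- alpha_ladder(alpha_start, alpha_max)
  icc1 <- icc2 <- NULL
  max_aggregate <- 0
  log_rows <- list()
  trace_rows <- list()
  history <- if (keep_history) list() else NULL

  for (alpha in alphas) {
    s <- alpha_stage(alpha)
    n_train <- sum(is_train0 | removed)
    if (is.null(icc1) || recompute_icc) {
      icc1 <- lapply(Deuc, function(D) .icc_labels(D, n_train)$labels)
      icc2 <- lapply(Dpcc, function(D) .icc_labels(D, n_train)$labels)
    }
    pass <- 0L
    repeat {
      pass <- pass + 1L
      e <- .e_groups(eff, is_train0, removed, alpha, thr)
      aggs <- list(.agg_pairs(mg1, e), .agg_pairs(mg2, e),
                   .agg_pairs(icc1, e), .agg_pairs(icc2, e))
      max_aggregate <- max(max_aggregate, vapply(aggs, max, numeric(1)))
      if (keep_history)
        history[[length(history) + 1L]] <-
          list(alpha = alpha, pass = pass, c_alpha = .c_alpha_matrix(aggs))
      betas <- lapply(1:4, function(t) compute_beta(aggs[[t]], potent_train, t))
      active <- which(!is_train0 & !removed)
      fl <- if (length(active)) .removal_flags(aggs, betas, s, active)
            else list(remove = logical(0), condition = character(0))
      n_removed <- sum(fl$remove)
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        stage = s, alpha = alpha, pass = pass,
        n_active = length(active), n_removed = n_removed,
        beta1_t1 = betas[[1]]$beta1, beta1_t2 = betas[[2]]$beta1,
        beta1_t3 = betas[[3]]$beta1, beta1_t4 = betas[[4]]$beta1,
        beta2_t1 = betas[[1]]$beta2, beta2_t2 = betas[[2]]$beta2,
        beta2_t3 = betas[[3]]$beta2, beta2_t4 = betas[[4]]$beta2)
      if (verbose)
        message(sprintf("alpha=%g pass=%d active=%d removed=%d",
                        alpha, pass, length(active), n_removed))
      if (!n_removed) break
      rem_idx <- active[fl$remove]
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        id = ds$id[rem_idx], stage = s, alpha = alpha, pass = pass,
        condition = fl$condition[fl$remove], stringsAsFactors = FALSE)
      removed[rem_idx] <- TRUE
    }
  }

  removal_log <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(id = character(0), stage = numeric(0),
                    alpha = numeric(0), pass = integer(0),
                    condition = character(0), stringsAsFactors = FALSE)
  structure(list(
    dataset = ds,
    P_cluster = ds$id[!is_train0 & !removed],
    I_cluster = ds$id[!is_train0 & removed],
    removed = removed,
    is_train0 = is_train0,
    potent_train = potent_train,
    removal_log = removal_log,
    trace = do.call(rbind, trace_rows),
    history = history,
    max_aggregate = max_aggregate,
    partitions_static = list(mg1 = mg1, mg2 = mg2),
    dist = list(euclidean = Deuc, pcc = Dpcc),
    config = list(alpha_start = alpha_start, alpha_max = alpha_max,
                  recompute_icc = recompute_icc,
                  potency_threshold = thr)),
    class = "i_iteration")
}

#' @export
print.i_iteration <- function(x, ...) {
  cat(sprintf(paste0("removal iteration: %d test records -> %d kept",
                     " (P-cluster), %d removed (I-cluster)\n"),
              length(x$P_cluster) + length(x$I_cluster),
              length(x$P_cluster), length(x$I_cluster)))
  cat(sprintf("  cut-offs %g%%..%g%%, %d passes, %d removals logged\n",
              x$config$alpha_start, x$config$alpha_max,
              nrow(x$trace), nrow(x$removal_log)))
  invisible(x)
}

# Aggregated pair matrices of the final state at a given cut-off, using the
# final training membership (removed records labelled E3) and mini-cluster
# partitions refreshed at the final training-set size.
.final_c_alpha <- function(state, alpha) {
  n_train <- sum(state$is_train0 | state$removed)
  e <- .e_groups(state$dataset$inhibition, state$is_train0, state$removed,
                 alpha, state$config$potency_threshold)
  icc1 <- lapply(state$dist$euclidean,
                 function(D) .icc_labels(D, n_train)$labels)
  icc2 <- lapply(state$dist$pcc,
                 function(D) .icc_labels(D, n_train)$labels)
  aggs <- list(.agg_pairs(state$partitions_static$mg1, e),
               .agg_pairs(state$partitions_static$mg2, e),
               .agg_pairs(icc1, e), .agg_pairs(icc2, e))
  .c_alpha_matrix(aggs)
}
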