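# The alpha-ladder feature cascade: E-group assignment of training siRNAs,
# group-purity fractions (D), their binarization, and aggregation over the
# 31 composite encodings into the per-record pair features used by the
# removal iteration.

#' The ladder of artificial efficacy cut-offs
#'
#' alpha_s = (20 + 5(s - 1))\% for s = 1..11: 20\%, 25\%, ..., 70\%. The
#' ladder can be extended downward (e.g. to 10\%) for sensitivity analyses.
#'
#' @param alpha_start First cut-off in percent. Default 20.
#' @param alpha_end Last cut-off in percent. Default 70.
#' @param by Step in percent. Default 5.
#' @return Numeric vector of cut-offs.
#' @export
alpha_ladder <- function(alpha_start = 20, alpha_end = 70, by = 5) {
  if (alpha_end < alpha_start) stop("alpha_end must be >= alpha_start")
  seq(alpha_start, alpha_end, by = by)
}

#' Stage index of an efficacy cut-off
#'
#' Inverts alpha_s = 20 + 5(s - 1): the canonical ladder maps 20\% to
#' stage 1 and 70\% to stage 11. Cut-offs below 20\% give stage indices
#' below 1 (used only by the downward-extended ladder).
#'
#' @param alpha Cut-off in percent.
#' @return Stage index s (numeric).
#' @export
alpha_stage <- function(alpha) {
  (alpha - 20) / 5 + 1
}

# E-group labels over all records: 1 = potent training, 2 = ineffective
# training with alpha <= efficacy < threshold, 3 = training efficacy below
# alpha OR any removed (recycled) test record, NA = active test record.
.e_groups <- function(eff, is_train0, removed, alpha, threshold = 70) {
  e <- rep(NA_integer_, length(eff))
  e[is_train0] <- ifelse(eff[is_train0] >= threshold, 1L,
                         ifelse(eff[is_train0] >= alpha, 2L, 3L))
  e[removed] <- 3L
  e
}

#' E-group assignment of training siRNAs
#'
#' Splits the training records at an artificial efficacy cut-off
#' \code{alpha}: potent records (efficacy at or above the potency threshold)
#' form E1; ineffective records with efficacy in \[alpha, threshold) form
#' E2; records below alpha form E3. Test records are unlabelled (NA).
#'
#' @param ds A \code{sirna_dataset} with roles assigned.
#' @param alpha Cut-off in percent (canonically 20..70 in steps of 5).
#' @return Integer vector over the records: 1, 2, 3 or NA.
#' @export
assign_e_groups <- function(ds, alpha) {
  thr <- attr(ds, "potency_threshold")
  if (is.null(thr)) thr <- 70
  .e_groups(ds$inhibition, !is.na(ds$role) & ds$role == "train",
            rep(FALSE, nrow(ds)), alpha, thr)
}

# Group-level E counts for one partition: G x 3 integer matrix.
.group_e_counts <- function(labels, e) {
  G <- max(labels)
  cbind(tabulate(labels[which(e == 1L)], G),
        tabulate(labels[which(e == 2L)], G),
        tabulate(labels[which(e == 3L)], G))
}

#' Group-purity fractions (D features)
#'
#' For each record, the fractions of E1, E2 and E3 members among the
#' E-labelled members of its group. The three fractions sum to 1 whenever
#' the group has at least one labelled member; a group with no labelled
#' member yields the neutral triple (0, 0, 0).
#'
#' @param partition A \code{sirna_partition} (or integer label vector) over
#'   all records.
#' @param e E-group labels as returned by \code{\link{assign_e_groups}}.
#' @return n x 3 numeric matrix of per-record triples (d1, d2, d3).
#' @export
d_features <- function(partition, e) {
  labels <- if (inherits(partition, "sirna_partition")) partition$labels
            else as.integer(partition)
  cnt <- .group_e_counts(labels, e)
  den <- rowSums(cnt)
  frac <- cnt / ifelse(den > 0, den, 1)
  frac[den == 0, ] <- 0
  out <- frac[labels, , drop = FALSE]
  colnames(out) <- c("d1", "d2", "d3")
  out
}

#' Binarize purity triples
#'
#' The pair (c1, c2) with c1 = 1 iff d1 > d3 and c2 = 1 iff d1 < d3; a tie
#' (including the neutral all-zero triple) gives (0, 0). The pair (1, 1) is
#' impossible.
#'
#' @param d A numeric triple, or an n x 3 matrix of triples.
#' @return Integer pair, or n x 2 integer matrix.
#' @export
binarize_d <- function(d) {
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  out <- cbind(c1 = as.integer(d[, 1L] > d[, 3L]),
               c2 = as.integer(d[, 1L] < d[, 3L]))
  if (nrow(out) == 1L) drop(out) else out
}

# Per-record binarized pair for one partition, computed group-wise. With a
# common denominator, d1 > d3 iff the E1 count exceeds the E3 count.
.group_binaries <- function(labels, e) {
  cnt <- .group_e_counts(labels, e)
  lab <- cnt[, 1L] + cnt[, 2L] + cnt[, 3L] > 0L
  g1 <- as.integer(lab & cnt[, 1L] > cnt[, 3L])
  g2 <- as.integer(lab & cnt[, 1L] < cnt[, 3L])
  cbind(g1[labels], g2[labels])
}

#' Aggregate binarized pairs over the 31 composite encodings
#'
#' Element-wise sum of the 31 per-encoding pairs of one record (or of all
#' records at once when given matrices): each aggregated entry counts the
#' encodings whose binarized purity bit is set, so it lies in 0..31.
#'
#' @param binaries A list of exactly 31 pairs (or n x 2 matrices).
#' @return Integer pair (or n x 2 integer matrix) with entries in 0..31.
#' @export
aggregate_c <- function(binaries) {
  if (length(binaries) != 31L)
    stop("expected exactly 31 binarized pairs, got ", length(binaries))
  Reduce(`+`, lapply(binaries, function(b) {
    if (is.null(dim(b))) matrix(as.integer(b), nrow = 1L) else b
  }))
}

# Aggregated n x 2 pair matrix for one method type: sum the group binaries
# over the 31 partitions of that type.
.agg_pairs <- function(label_list, e) {
  Reduce(`+`, lapply(label_list, .group_binaries, e = e))
}

# The concatenated 8-column feature (t = 1..4, each contributing its pair).
.c_alpha_matrix <- function(aggs) {
  out <- do.call(cbind, aggs)
  colnames(out) <- paste0(rep(paste0("t", 1:4), each = 2L), "_c", 1:2)
  out
}

#' Build the per-encoding partitions used by the cascade
#'
#' For each of the 31 composite encodings, partitions all records (training
#' and test together) with the four neighbour structures: MG1 and MG2
#' (feature-only, independent of roles) and Icc1 and Icc2 with the number of
#' clusters set to the current training-set size.
#'
#' @param ds A \code{sirna_dataset} with roles assigned, or a character
#'   vector of sequences (then \code{n_train} is required).
#' @param n_train Number of clusters for the Icc structures; defaults to the
#'   dataset's training-set size.
#' @return A list with elements \code{mg1}, \code{mg2}, \code{icc1},
#'   \code{icc2}, each a list of 31 integer label vectors.
#' @export
build_partitions <- function(ds, n_train = NULL) {
  seqs <- if (is.character(ds)) ds else ds$sequence
  if (is.null(n_train)) {
    if (is.character(ds)) stop("n_train is required when passing sequences")
    n_train <- sum(!is.na(ds$role) & ds$role == "train")
  }
  feats <- .all_ck_matrices(seqs)
  Deuc <- lapply(feats, feature_dist, metric = "euclidean")
  Dpcc <- lapply(feats, feature_dist, metric = "pcc")
  list(mg1 = lapply(Deuc, .mg_labels),
       mg2 = lapply(Dpcc, .mg_labels),
       icc1 = lapply(Deuc, function(D) .icc_labels(D, n_train)$labels),
       icc2 = lapply(Dpcc, function(D) .icc_labels(D, n_train)$labels))
}

#' Aggregated pair features of every record at one cut-off
#'
#' Convenience wrapper computing, for each method type t = 1..4, the n x 2
#' aggregated pair matrix at cut-off \code{alpha}, and their 8-column
#' concatenation.
#'
#' @param ds A \code{sirna_dataset} with roles assigned.
#' @param alpha Efficacy cut-off in percent.
#' @param partitions Optional result of \code{\link{build_partitions}}
#'   (recomputed when omitted).
#' @return A list with \code{pairs} (list of four n x 2 matrices, in order
#'   MG1, MG2, Icc1, Icc2) and \code{c_alpha} (n x 8 matrix).
#' @export
c_alpha_features <- function(ds, alpha, partitions = NULL) {
  if (is.null(partitions)) partitions <- build_partitions(ds)
  e <- assign_e_groups(ds, alpha)
  aggs <- lapply(partitions, .agg_pairs, e = e)
  names(aggs) <- c("MG1", "MG2", "Icc1", "Icc2")
  list(pairs = aggs, c_alpha = .c_alpha_matrix(aggs))
}
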