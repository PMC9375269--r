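# End-to-end orchestration: read or simulate a dataset, split, run the
# removal iteration, predict, evaluate, and write all outputs together
# with a manifest sufficient to reproduce them bit-exactly.

#' Run the full potency-boundary pipeline
#'
#' Reads (or accepts) a dataset, optionally assigns train/test roles,
#' runs the removal iteration, predicts test efficacies by mini-group
#' averaging and writes: \code{clusters.tsv} (P/I assignment),
#' \code{removal_log.tsv}, \code{trace.tsv} (per-pass beta values and
#' removal counts), \code{predictions.tsv}, \code{metrics.json} and
#' \code{manifest.json} (configuration, input checksum and versions). The
#' pipeline itself is deterministic: rerunning with an identical manifest
#' reproduces the outputs byte-identically.
#'
#' @param input A \code{sirna_dataset} or a path readable by
#'   \code{\link{read_sirna}}.
#' @param out_dir Output directory (created if missing).
#' @param split Role assignment: \code{"every_fifth"}, \code{"modulus"}
#'   or \code{"none"} (roles already present). Default \code{"every_fifth"}
#'   unless roles are already assigned.
#' @param modulus,offset Parameters for \code{split = "modulus"}.
#' @param alpha_start,alpha_max,recompute_icc Passed to
#'   \code{\link{run_iteration}}. \code{alpha_start} must be positive and at
#'   most \code{alpha_max}.
#' @param potency_threshold Percent threshold. Default 70.
#' @param write_features Also export the concatenated pair features at
#'   \code{alpha_max} as \code{c_alpha.tsv}. Default FALSE.
#' @return Invisibly, a list with the iteration \code{state}, the
#'   \code{predictions} data frame and the \code{metrics} list.
#' @export
run_pipeline <- function(input, out_dir,
                         split = c("auto", "every_fifth", "modulus", "none"),
                         modulus = 5, offset = 0,
                         alpha_start = 20, alpha_max = 65,
                         recompute_icc = TRUE, potency_threshold = 70,
                         write_features = FALSE) {
  split <- match.arg(split)
  if (alpha_start < 0 || alpha_start > alpha_max)
    stop("alpha_start must lie in [0, alpha_max]")
  input_path <- NULL
  if (is.character(input)) {
    input_path <- input
    ds <- read_sirna(input, potency_threshold = potency_threshold)
  } else {
    ds <- input
  }
  if (split == "auto")
    split <- if (any(!is.na(ds$role))) "none" else "every_fifth"
  ds <- switch(split,
               every_fifth = split_every_fifth(ds),
               modulus = split_modulus(ds, modulus, offset),
               none = ds)
  if (anyNA(ds$role))
    stop("records without roles; choose a split rule")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- run_iteration(ds, alpha_start = alpha_start,
                         alpha_max = alpha_max,
                         recompute_icc = recompute_icc)
  pred <- predict_efficacy(state, alpha = alpha_max)
  metrics <- evaluate_predictions(pred, potency_threshold)

  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  clusters <- data.frame(
    id = c(state$P_cluster, state$I_cluster),
    cluster = rep(c("P", "I"),
                  c(length(state$P_cluster), length(state$I_cluster))),
    stringsAsFactors = FALSE)
  tsv(clusters, "clusters.tsv")
  tsv(state$removal_log, "removal_log.tsv")
  tsv(state$trace, "trace.tsv")
  tsv(pred[, c("id", "sequence", "observed", "predicted", "cluster")],
      "predictions.tsv")
  if (write_features) {
    C <- .final_c_alpha(state, alpha_max)
    tsv(cbind(data.frame(id = ds$id, stringsAsFactors = FALSE),
              as.data.frame(C)), "c_alpha.tsv")
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "sirnaboundary",
    version = as.character(utils::packageVersion("sirnaboundary")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input = if (is.null(input_path)) "in-memory dataset" else input_path,
    input_md5 = if (is.null(input_path)) NA
                else unname(tools::md5sum(input_path)),
    n_records = nrow(ds),
    config = list(split = split, modulus = modulus, offset = offset,
                  alpha_start = alpha_start, alpha_max = alpha_max,
                  recompute_icc = recompute_icc,
                  potency_threshold = potency_threshold))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(list(state = state, predictions = pred, metrics = metrics))
}
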