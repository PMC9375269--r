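# Seeded synthetic siRNA datasets with the statistical structure the
# boundary method exploits: ineffective siRNAs carrying planted local
# sequence similarity (motif families), potent siRNAs as motif-free random
# sequences, and efficacies split cleanly by the 70% potency threshold.

# Evaluate code under a temporary RNG state; the caller's global RNG state
# is untouched.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_seqs <- function(n) {
  vapply(seq_len(n),
         function(i) paste(sample(.NT, 19L, replace = TRUE), collapse = ""),
         character(1))
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(19L) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(.NT, b), 1L), character(1))
  paste(ch, collapse = "")
}

#' Generate a seeded synthetic siRNA dataset
#'
#' Emulates the structure the boundary method relies on. Each motif family
#' owns a random 19-nt template; its member ineffective siRNAs are copies
#' of the template with independent per-base mutations at
#' \code{mutation_rate}, so members differ only at mutated positions and
#' exhibit strong local similarity (akin to siRNAs tiling the same target
#' region). A designated motif window of each template (length
#' \code{motif_length}) is recorded in the truth sidecar for audits.
#' Potent siRNAs are motif-free random sequences. Potent efficacies are
#' uniform on \[70, 100\]; ineffective efficacies are an equal mixture of
#' uniform \[0, 20) and uniform \[20, 70), so every E2/E3 boundary of the
#' cut-off ladder is populated. Roles are assigned with
#' \code{\link{split_every_fifth}}.
#'
#' All draws are governed by the single integer \code{seed}; the global RNG
#' state is left untouched and the same seed always yields the same
#' dataset.
#'
#' @param n_potent Number of potent siRNAs. Default 50.
#' @param n_ineffective Number of ineffective siRNAs. Default 150.
#' @param n_motif_families Number of motif families among the ineffective
#'   siRNAs (assigned round-robin). Default 5.
#' @param motif_length Length of the recorded motif window, 1..19. Default
#'   7.
#' @param mutation_rate Per-base mutation probability in \[0, 1). Default
#'   0.05.
#' @param seed Integer seed. Default 0.
#' @param potency_threshold Percent threshold stored on the dataset.
#'   Default 70.
#' @param split Assign roles via \code{\link{split_every_fifth}} (default
#'   TRUE).
#' @return A \code{sirna_dataset} with a \code{truth} attribute: a data
#'   frame with \code{id}, \code{class}, \code{family}, \code{motif},
#'   \code{motif_start} aligned to the dataset rows.
#' @export
generate_fixture <- function(n_potent = 50, n_ineffective = 150,
                             n_motif_families = 5, motif_length = 7,
                             mutation_rate = 0.05, seed = 0,
                             potency_threshold = 70, split = TRUE) {
  if (n_potent < 1 || n_ineffective < 1 || n_motif_families < 1)
    stop("counts must be at least 1")
  if (motif_length < 1 || motif_length > 19)
    stop("motif_length must lie in 1..19")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must lie in [0, 1)")
  res <- .with_seed(seed, {
    pot_seq <- .random_seqs(n_potent)
    templates <- .random_seqs(n_motif_families)
    motif_start <- sample(seq_len(19L - motif_length + 1L),
                          n_motif_families, replace = TRUE)
    family <- rep_len(seq_len(n_motif_families), n_ineffective)
    ine_seq <- vapply(family,
                      function(f) .mutate_seq(templates[f], mutation_rate),
                      character(1))
    pot_eff <- stats::runif(n_potent, 70, 100)
    low <- stats::runif(n_ineffective) < 0.5
    ine_eff <- ifelse(low, stats::runif(n_ineffective, 0, 20),
                      stats::runif(n_ineffective, 20, 70))
    # guard the clean threshold split against the open upper bound
    ine_eff <- pmin(ine_eff, 70 - 1e-9)
    list(
      id = c(sprintf("pot%03d", seq_len(n_potent)),
             sprintf("ine%03d", seq_len(n_ineffective))),
      sequence = c(pot_seq, ine_seq),
      inhibition = c(pot_eff, ine_eff),
      truth = data.frame(
        id = c(sprintf("pot%03d", seq_len(n_potent)),
               sprintf("ine%03d", seq_len(n_ineffective))),
        class = rep(c("potent", "ineffective"),
                    c(n_potent, n_ineffective)),
        family = c(rep(NA_integer_, n_potent), family),
        motif = c(rep(NA_character_, n_potent),
                  substr(templates[family], motif_start[family],
                         motif_start[family] + motif_length - 1L)),
        motif_start = c(rep(NA_integer_, n_potent), motif_start[family]),
        stringsAsFactors = FALSE))
  })
  ds <- sirna_dataset(res$id, res$sequence, res$inhibition,
                      potency_threshold = potency_threshold)
  if (split) ds <- split_every_fifth(ds)
  truth <- res$truth[match(ds$id, res$truth$id), , drop = FALSE]
  rownames(truth) <- NULL
  attr(ds, "truth") <- truth
  ds
}

#' Count pure-ineffective mini-groups
#'
#' Builds the Euclidean mini-group partition on the full composite feature
#' (all five blocks, k = 31) and counts the groups whose members are all
#' ineffective. The boundary method requires such groups to exist; this
#' audit verifies a fixture provides them.
#'
#' @param ds A \code{sirna_dataset}.
#' @param k Composite feature index used for the partition. Default 31.
#' @param metric Distance metric. Default Euclidean.
#' @return Integer count of all-ineffective mini-groups.
#' @export
count_pure_ineffective_groups <- function(ds, k = 31,
                                          metric = c("euclidean", "pcc")) {
  metric <- match.arg(metric)
  part <- mg_partition(ck_matrix(ds$sequence, k), metric)
  ineff <- !is_potent(ds)
  sum(vapply(seq_len(part$n_groups),
             function(g) all(ineff[part$labels == g]), logical(1)))
}
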