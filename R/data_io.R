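# Dataset construction, validation, file I/O and train/test splitting.

.NT <- c("A", "C", "G", "T")

#' Canonicalize an siRNA sequence
#'
#' Upper-cases the sequence and converts RNA uracil (U) to thymine (T) so
#' that the internal alphabet is always \{A, C, G, T\}.
#'
#' @param x Character vector of sequences.
#' @return Character vector of canonical sequences.
#' @export
canonicalize_sequence <- function(x) {
  gsub("U", "T", toupper(as.character(x)), fixed = TRUE)
}

#' Construct a validated siRNA dataset
#'
#' An siRNA dataset is a data frame with one row per siRNA holding its
#' identifier, canonical 19-nt sequence, observed inhibition (percent
#' knockdown on the 0--100 scale) and an optional role (\code{"train"} or
#' \code{"test"}). A record is called \emph{potent} when its observed
#' inhibition is at least \code{potency_threshold} (default 70\%), and
#' \emph{ineffective} otherwise.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of 19-nt sequences over A/C/G/T (U and
#'   lower case accepted on input and canonicalized).
#' @param inhibition Numeric vector of observed inhibition percentages in
#'   \[0, 100\].
#' @param role Optional character vector, each entry \code{"train"},
#'   \code{"test"} or \code{NA} (unassigned).
#' @param potency_threshold Percent knockdown separating potent from
#'   ineffective siRNAs. Default 70.
#' @return A data frame of class \code{"sirna_dataset"} with columns
#'   \code{id}, \code{sequence}, \code{inhibition}, \code{role} and a
#'   \code{potency_threshold} attribute.
#' @examples
#' ds <- sirna_dataset("s1", "ACGUACGUACGUACGUACG", 85)
#' ds$sequence  # "ACGTACGTACGTACGTACG"
#' is_potent(ds)
#' @export
sirna_dataset <- function(id, sequence, inhibition, role = NA_character_,
                          potency_threshold = 70) {
  id <- as.character(id)
  sequence <- canonicalize_sequence(sequence)
  inhibition <- as.numeric(inhibition)
  role <- rep_len(as.character(role), length(id))
  if (length(sequence) != length(id) || length(inhibition) != length(id))
    stop("id, sequence and inhibition must have equal length")
  ds <- data.frame(id = id, sequence = sequence, inhibition = inhibition,
                   role = role, stringsAsFactors = FALSE)
  attr(ds, "potency_threshold") <- potency_threshold
  class(ds) <- c("sirna_dataset", "data.frame")
  validate_sirna_dataset(ds)
  ds
}

#' Validate an siRNA dataset
#'
#' Checks identifier uniqueness, sequence length and alphabet, inhibition
#' range and role values. Called by all constructors; exported so that
#' externally assembled data frames can be checked too.
#'
#' @param ds A \code{sirna_dataset}.
#' @return \code{ds}, invisibly, if valid; otherwise an error naming the
#'   offending record.
#' @export
validate_sirna_dataset <- function(ds) {
  if (anyDuplicated(ds$id))
    stop("duplicate siRNA ids: ",
         paste(unique(ds$id[duplicated(ds$id)]), collapse = ", "))
  bad_len <- nchar(ds$sequence) != 19L
  if (any(bad_len))
    stop("sequences must be exactly 19 nt; offending id(s): ",
         paste(ds$id[bad_len], collapse = ", "))
  bad_chr <- grepl("[^ACGT]", ds$sequence)
  if (any(bad_chr))
    stop("sequences must contain only A/C/G/T(U); offending id(s): ",
         paste(ds$id[bad_chr], collapse = ", "))
  bad_inh <- !is.finite(ds$inhibition) | ds$inhibition < 0 | ds$inhibition > 100
  if (any(bad_inh))
    stop("observed inhibition must lie in [0, 100]; offending id(s): ",
         paste(ds$id[bad_inh], collapse = ", "))
  bad_role <- !(is.na(ds$role) | ds$role %in% c("train", "test"))
  if (any(bad_role))
    stop("role must be 'train', 'test' or NA; offending id(s): ",
         paste(ds$id[bad_role], collapse = ", "))
  invisible(ds)
}

#' Potency labels of a dataset
#'
#' @param ds A \code{sirna_dataset}.
#' @return Logical vector, \code{TRUE} where observed inhibition is at least
#'   the dataset's potency threshold.
#' @export
is_potent <- function(ds) {
  thr <- attr(ds, "potency_threshold")
  if (is.null(thr)) thr <- 70
  ds$inhibition >= thr
}

#' Read an siRNA dataset from TSV, CSV or FASTA
#'
#' Tabular input requires a header with columns \code{id}, \code{sequence}
#' and \code{inhibition} (an optional \code{role} column is honoured). FASTA
#' input encodes the observed inhibition in the description line as
#' \code{inhibition=<float>}; the identifier is the first whitespace-separated
#' token of the header.
#'
#' @param path Input file path.
#' @param format One of \code{"auto"} (by extension), \code{"tsv"},
#'   \code{"csv"}, \code{"fasta"}.
#' @param potency_threshold Percent threshold stored on the dataset.
#' @return A validated \code{sirna_dataset}.
#' @export
read_sirna <- function(path, format = c("auto", "tsv", "csv", "fasta"),
                       potency_threshold = 70) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     tsv = , txt = "tsv",
                     csv = "csv",
                     fa = , fasta = , fna = "fasta",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (format %in% c("tsv", "csv")) {
    df <- if (format == "tsv") {
      utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    }
    need <- c("id", "sequence", "inhibition")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    inh <- suppressWarnings(as.numeric(df$inhibition))
    if (anyNA(inh)) {
      bad <- which(is.na(inh))[1L]
      stop("malformed inhibition value at data line ", bad,
           " (file line ", bad + 1L, ")")
    }
    role <- if ("role" %in% names(df)) as.character(df$role) else NA_character_
    sirna_dataset(df$id, df$sequence, inh, role = role,
                  potency_threshold = potency_threshold)
  } else {
    xs <- Biostrings::readBStringSet(path)
    headers <- names(xs)
    ids <- sub("\\s.*$", "", headers)
    m <- regmatches(headers,
                    regexpr("inhibition=([0-9.eE+-]+)", headers))
    if (length(m) != length(headers) || any(!nzchar(m))) {
      missing_ids <- ids[!grepl("inhibition=", headers)]
      stop("FASTA header(s) missing 'inhibition=<float>': ",
           paste(missing_ids, collapse = ", "))
    }
    inh <- as.numeric(sub("inhibition=", "", m, fixed = TRUE))
    sirna_dataset(ids, as.character(xs), inh,
                  potency_threshold = potency_threshold)
  }
}

#' Write an siRNA dataset
#'
#' Writes canonical TSV (columns \code{id}, \code{sequence},
#' \code{inhibition}, plus \code{role} when any role is assigned) or FASTA
#' with \code{inhibition=} in the description. TSV written by this function
#' round-trips byte-identically through \code{\link{read_sirna}}.
#'
#' @param ds A \code{sirna_dataset}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @return \code{path}, invisibly.
#' @export
write_sirna <- function(ds, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- c("id", "sequence", "inhibition")
    if (any(!is.na(ds$role))) cols <- c(cols, "role")
    utils::write.table(as.data.frame(ds)[, cols], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    lines <- paste0(">", ds$id, " inhibition=", ds$inhibition, "\n",
                    ds$sequence)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.sirna_dataset <- function(x, ...) {
  thr <- attr(x, "potency_threshold")
  cat(sprintf("siRNA dataset: %d records (%d potent / %d ineffective at %g%%)\n",
              nrow(x), sum(is_potent(x)), sum(!is_potent(x)), thr))
  if (any(!is.na(x$role)))
    cat(sprintf("  roles: %d train, %d test\n",
                sum(x$role == "train", na.rm = TRUE),
                sum(x$role == "test", na.rm = TRUE)))
  NextMethod()
}

#' Serial-number train/test split
#'
#' Records are reordered by observed inhibition (descending by default, ties
#' broken by id), given serial numbers 1..n, and those whose serial number is
#' congruent to \code{offset} modulo \code{modulus} become the test set; all
#' others are training. \code{offset = 0} selects the multiples of
#' \code{modulus}. The split depends only on inhibition values and ids, never
#' on input row order.
#'
#' @param ds A \code{sirna_dataset}.
#' @param modulus Positive integer; every \code{modulus}-th record becomes
#'   test.
#' @param offset Integer in \[0, modulus). Default 0 (multiples of
#'   \code{modulus}).
#' @param decreasing Sort direction for the reordering. Default
#'   \code{TRUE} (highest inhibition first).
#' @return The dataset reordered by serial number with roles assigned.
#' @seealso \code{\link{split_every_fifth}}
#' @export
split_modulus <- function(ds, modulus, offset = 0, decreasing = TRUE) {
  modulus <- as.integer(modulus)
  offset <- as.integer(offset)
  if (is.na(modulus) || modulus < 1L)
    stop("modulus must be a positive integer")
  if (is.na(offset) || offset < 0L || offset >= modulus)
    stop("offset must lie in [0, modulus)")
  ord <- order(ds$inhibition, ds$id, decreasing = c(decreasing, FALSE),
               method = "radix")
  out <- ds[ord, , drop = FALSE]
  rownames(out) <- NULL
  serial <- seq_len(nrow(out))
  test <- (serial %% modulus) == offset
  if (!any(test))
    stop("split produces no test records (n = ", nrow(out),
         ", modulus = ", modulus, ")")
  if (!any(!test))
    warning("split produces an empty training set (modulus = ", modulus, ")")
  out$role <- ifelse(test, "test", "train")
  attr(out, "potency_threshold") <- attr(ds, "potency_threshold")
  class(out) <- class(ds)
  out
}

#' Every-fifth train/test split
#'
#' Reorders records by observed inhibition and assigns every record whose
#' serial number is a multiple of 5 (20\% of the data) to the test set.
#' Equivalent to \code{split_modulus(ds, 5, 0)}.
#'
#' @inheritParams split_modulus
#' @return The dataset reordered by serial number with roles assigned;
#'   exactly \code{floor(n/5)} test records.
#' @export
split_every_fifth <- function(ds, decreasing = TRUE) {
  if (nrow(ds) < 5L)
    stop("need at least 5 records to produce a test record")
  split_modulus(ds, 5L, 0L, decreasing = decreasing)
}
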