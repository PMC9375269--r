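# Raw sequence encodings: m-mer frequency blocks F1..F4 (computed on the
# circularly extended sequence so every block sums to 19), the 76-entry
# positional one-hot block B, and the catalogue of 31 composite features.

.BLOCKS <- c("F1", "F2", "F3", "F4", "B")
.BLOCK_DIM <- c(F1 = 4L, F2 = 16L, F3 = 64L, F4 = 256L, B = 76L)

.check_seq <- function(seq) {
  seq <- canonicalize_sequence(seq)
  if (any(nchar(seq) != 19L))
    stop("sequence must be exactly 19 nt")
  if (any(grepl("[^ACGT]", seq)))
    stop("sequence must contain only A/C/G/T(U)")
  seq
}

# All m-mers in lexicographic A<C<G<T order, e.g. AA, AC, AG, AT, CA, ...
.kmer_names <- function(m) {
  Biostrings::mkAllStrings(.NT, m)
}

# n x 4^m matrix of m-mer counts over the 19 windows of the circular
# extension seq + first (m-1) nucleotides. Columns in lexicographic order.
.freq_matrix <- function(seqs, m) {
  ext <- paste0(seqs, substr(seqs, 1L, m - 1L))
  mat <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(ext),
                                              width = m)
  storage.mode(mat) <- "integer"
  colnames(mat) <- paste0("F", m, "_", colnames(mat))
  mat
}

# n x 76 one-hot matrix: position p occupies columns 4(p-1)+1 .. 4(p-1)+4,
# one-hot over A, C, G, T.
.binary_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  idx <- matrix(match(chars, .NT), nrow = n)
  out <- matrix(0L, n, 76L)
  cols <- sweep(idx, 2L, 4L * (seq_len(19L) - 1L), "+")
  out[cbind(rep(seq_len(n), 19L), as.vector(cols))] <- 1L
  colnames(out) <- paste0("B_p", rep(1:19, each = 4L), "_", .NT)
  out
}

# The five raw blocks for a vector of sequences, as a named list of matrices.
.block_matrices <- function(seqs) {
  seqs <- .check_seq(seqs)
  out <- c(lapply(1:4, function(m) .freq_matrix(seqs, m)),
           list(.binary_matrix(seqs)))
  names(out) <- .BLOCKS
  out
}

#' m-mer frequency encoding of a 19-nt siRNA
#'
#' Counts all 19 length-\code{m} windows of the circularly extended sequence
#' (the sequence followed by its first \code{m - 1} nucleotides), indexed by
#' the \code{4^m} m-mers in lexicographic A<C<G<T order. Because of the
#' circular extension the entries always sum to 19, for every \code{m}.
#'
#' @param seq A 19-nt sequence (U and lower case accepted).
#' @param m Word length, 1 to 4.
#' @return Named integer vector of length \code{4^m} summing to 19.
#' @examples
#' f1 <- encode_frequency("ACGTACGTACGTACGTACG", 1)
#' sum(f1)  # 19
#' @export
encode_frequency <- function(seq, m) {
  if (length(m) != 1L || !m %in% 1:4) stop("m must be one of 1, 2, 3, 4")
  if (length(seq) != 1L) stop("encode_frequency expects a single sequence")
  drop(.freq_matrix(.check_seq(seq), as.integer(m)))
}

#' Positional one-hot encoding of a 19-nt siRNA
#'
#' Encodes each of the 19 positions as a one-hot quadruple over A, C, G, T,
#' giving a 76-entry 0/1 vector with exactly 19 ones (one per consecutive
#' block of four entries).
#'
#' @param seq A 19-nt sequence.
#' @return Named integer vector of length 76.
#' @export
encode_binary <- function(seq) {
  if (length(seq) != 1L) stop("encode_binary expects a single sequence")
  drop(.binary_matrix(.check_seq(seq)))
}

#' Catalogue of the 31 composite features
#'
#' Every non-empty subset of the five raw blocks \{F1, F2, F3, F4, B\}
#' defines one composite feature; there are exactly 31. The index k encodes
#' the subset in binary: bit 1 = F1, bit 2 = F2, bit 4 = F3, bit 8 = F4,
#' bit 16 = B. Hence k = 15 is the combination of the four frequency blocks
#' and k = 31 is the full combination of all five blocks.
#'
#' @return Named list of 31 character vectors, element k giving the member
#'   blocks of composite k in concatenation order F1, F2, F3, F4, B.
#' @examples
#' ck_catalogue()[[15]]  # F1 F2 F3 F4
#' length(ck_catalogue())  # 31
#' @export
ck_catalogue <- function() {
  out <- lapply(1:31, function(k) .BLOCKS[bitwAnd(k, c(1L, 2L, 4L, 8L, 16L)) > 0L])
  names(out) <- paste0("C", 1:31)
  out
}

#' Dimension of a composite feature
#'
#' @param k Composite index, 1 to 31.
#' @return Integer: the summed dimensions of the member blocks
#'   (4, 16, 64, 256, 76 for F1..F4, B).
#' @export
ck_dim <- function(k) {
  sum(.BLOCK_DIM[.ck_members(k)])
}

.ck_members <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1L || k > 31L)
    stop("k must be an integer in 1..31")
  .BLOCKS[bitwAnd(as.integer(k), c(1L, 2L, 4L, 8L, 16L)) > 0L]
}

#' Composite feature vector of one siRNA
#'
#' Concatenates the member blocks of composite \code{k} in the fixed order
#' F1, F2, F3, F4, B. A pure function: identical input gives identical
#' output.
#'
#' @param seq A 19-nt sequence.
#' @param k Composite index, 1 to 31.
#' @return Named numeric vector of length \code{ck_dim(k)}.
#' @export
encode_ck <- function(seq, k) {
  drop(ck_matrix(seq, k))
}

#' Composite feature matrix of many siRNAs
#'
#' @param seqs Character vector of 19-nt sequences.
#' @param k Composite index, 1 to 31.
#' @return Numeric matrix, one row per sequence, \code{ck_dim(k)} columns.
#' @export
ck_matrix <- function(seqs, k) {
  members <- .ck_members(k)
  seqs <- .check_seq(seqs)
  blocks <- lapply(members, function(b) {
    if (b == "B") .binary_matrix(seqs)
    else .freq_matrix(seqs, as.integer(substr(b, 2L, 2L)))
  })
  do.call(cbind, blocks)
}

# All 31 composite matrices at once, sharing the five block computations.
.all_ck_matrices <- function(seqs) {
  blocks <- .block_matrices(seqs)
  lapply(ck_catalogue(), function(members) {
    do.call(cbind, blocks[members])
  })
}
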