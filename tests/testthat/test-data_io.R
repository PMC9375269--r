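test_that("reading canonicalizes U/case and derives potency", {
  path <- random_tsv()
  ds <- read_sirna(path)
  expect_s3_class(ds, "sirna_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$sequence[ds$id == "s1"], "ACGTACGTACGTACGTACG")
  expect_equal(ds$sequence[ds$id == "s3"], "ACGTACGTACGTACGTACG")
  expect_equal(ds$inhibition[ds$id == "s1"], 85.0)
  expect_equal(is_potent(ds), c(TRUE, FALSE, FALSE))
})

test_that("validation rejects bad length, alphabet, range and duplicates", {
  expect_error(sirna_dataset("x", "ACGTACGTACGTACGTACGT", 50), "19 nt.*x")
  expect_error(sirna_dataset("x", "ACGTACGTACGTACGTACN", 50), "A/C/G/T")
  expect_error(sirna_dataset("x", "ACGTACGTACGTACGTACG", 101), "\\[0, 100\\]")
  expect_error(sirna_dataset(c("a", "a"),
                             rep("ACGTACGTACGTACGTACG", 2), c(10, 20)),
               "duplicate")
})

test_that("malformed tabular rows are reported with their line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tinhibition",
               "s1\tACGTACGTACGTACGTACG\t85.0",
               "s2\tACGTACGTACGTACGTACG\tnot-a-number"), path)
  expect_error(read_sirna(path), "line 2")
})

test_that("FASTA headers carry the observed inhibition", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 inhibition=42.0", "ACGUACGUACGUACGUACG",
               ">s2 inhibition=90", "AAAAAAAAAAAAAAAAAAA"), path)
  ds <- read_sirna(path)
  expect_equal(ds$inhibition, c(42, 90))
  expect_equal(ds$sequence[1], "ACGTACGTACGTACGTACG")
  expect_equal(is_potent(ds), c(FALSE, TRUE))

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 eff=42", "ACGTACGTACGTACGTACG"), bad)
  expect_error(read_sirna(bad), "inhibition")
})

test_that("canonical TSV round-trips byte-identically", {
  ds <- generate_fixture(n_potent = 5, n_ineffective = 15, seed = 3,
                         split = FALSE)
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_sirna(ds, p1)
  write_sirna(read_sirna(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("every-fifth split selects floor(n/5) test records by serial", {
  ds10 <- generate_fixture(n_potent = 4, n_ineffective = 6, seed = 1,
                           split = FALSE)
  sp <- split_every_fifth(ds10)
  expect_equal(sum(sp$role == "test"), 2L)
  expect_equal(which(sp$role == "test"), c(5L, 10L))

  ds100 <- generate_fixture(n_potent = 30, n_ineffective = 70, seed = 2,
                            split = FALSE)
  expect_equal(sum(split_every_fifth(ds100)$role == "test"), 20L)
  expect_error(split_every_fifth(ds100[1:4, ]), "at least 5")
})

test_that("splits are order-invariant and partition the ids", {
  ds <- generate_fixture(n_potent = 10, n_ineffective = 20, seed = 7,
                         split = FALSE)
  shuffled <- ds[rev(seq_len(nrow(ds))), ]
  class(shuffled) <- class(ds)
  attr(shuffled, "potency_threshold") <- 70
  a <- split_every_fifth(ds)
  b <- split_every_fifth(shuffled)
  expect_identical(a$id, b$id)
  expect_identical(a$role, b$role)
  expect_equal(sum(a$role == "test") + sum(a$role == "train"), nrow(ds))
  expect_length(intersect(a$id[a$role == "test"], a$id[a$role == "train"]), 0)
})

test_that("modulus splitter generalizes the serial rule", {
  ds <- generate_fixture(n_potent = 3, n_ineffective = 7, seed = 5,
                         split = FALSE)
  expect_equal(sum(split_modulus(ds, 2, 0)$role == "test"), 5L)
  expect_identical(split_modulus(ds, 5, 0)$role, split_every_fifth(ds)$role)

  ds9 <- ds[1:9, ]; class(ds9) <- class(ds)
  attr(ds9, "potency_threshold") <- 70
  sp <- split_modulus(ds9, 3, 1)
  expect_equal(which(sp$role == "test"), c(1L, 4L, 7L))
  expect_error(split_modulus(ds, 0, 0), "modulus")
  expect_error(split_modulus(ds, 3, 3), "offset")
  expect_warning(split_modulus(ds, 1, 0), "empty training")
})
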