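test_that("the cut-off ladder runs 20..70 in steps of 5", {
  a <- alpha_ladder()
  expect_length(a, 11L)
  expect_equal(a[1], 20)
  expect_equal(a[11], 70)
  expect_true(all(diff(a) == 5))
  expect_equal(alpha_stage(20), 1)
  expect_equal(alpha_stage(65), 10)
  expect_equal(alpha_stage(10), -1)
})

test_that("E-groups split training records at the cut-off", {
  ds <- sirna_dataset(c("x1", "y1", "y2", "z1"),
                      rep("ACGTACGTACGTACGTACG", 4) |>
                        (\(s) c(s[1], "AAAAAAAAAAAAAAAAAAA",
                                "CCCCCCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGGGGGG"))(),
                      c(85, 10, 50, 60),
                      role = c("train", "train", "train", "test"))
  expect_equal(assign_e_groups(ds, 20), c(1L, 3L, 2L, NA))
  expect_equal(assign_e_groups(ds, 40), c(1L, 3L, 2L, NA))
  expect_equal(assign_e_groups(ds, 55), c(1L, 3L, 3L, NA))
  # boundary handling: efficacy exactly at alpha joins E2, at 70 joins E1
  ds2 <- sirna_dataset(c("a", "b"),
                       c("AAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCC"),
                       c(40, 70), role = "train")
  expect_equal(assign_e_groups(ds2, 40), c(2L, 1L))
})

test_that("purity fractions are labelled-member shares summing to one", {
  labels <- c(1L, 1L, 1L, 1L, 2L, 2L)
  e <- c(1L, 1L, 2L, 3L, 3L, 3L)
  d <- d_features(labels, e)
  expect_equal(d[1, ], c(d1 = 0.5, d2 = 0.25, d3 = 0.25))
  expect_equal(d[5, ], c(d1 = 0, d2 = 0, d3 = 1))
  expect_equal(unname(rowSums(d)), rep(1, 6))

  # unlabelled members are excluded from the denominator
  e2 <- c(1L, 1L, NA, 3L, NA, NA)
  d2 <- d_features(labels, e2)
  expect_equal(unname(d2[1, ]), c(2 / 3, 0, 1 / 3))
  expect_equal(unname(d2[5, ]), c(0, 0, 0))  # no labelled member: neutral
})

test_that("binarization keeps at most one bit and ties are neutral", {
  expect_equal(unname(binarize_d(c(0.6, 0.2, 0.2))), c(1L, 0L))
  expect_equal(unname(binarize_d(c(0.2, 0.2, 0.6))), c(0L, 1L))
  expect_equal(unname(binarize_d(c(0.4, 0.2, 0.4))), c(0L, 0L))
  set.seed(7)
  for (i in 1:50) {
    d <- stats::runif(3)
    expect_false(all(binarize_d(d / sum(d)) == c(1L, 1L)))
  }
})

test_that("aggregation sums the 31 pairs and stays within 0..31", {
  all_ones <- replicate(31, c(1L, 0L), simplify = FALSE)
  expect_equal(unname(drop(aggregate_c(all_ones))), c(31L, 0L))
  mixed <- c(replicate(10, c(1L, 0L), simplify = FALSE),
             replicate(5, c(0L, 1L), simplify = FALSE),
             replicate(16, c(0L, 0L), simplify = FALSE))
  expect_equal(unname(drop(aggregate_c(mixed))), c(10L, 5L))
  expect_error(aggregate_c(mixed[1:30]), "31")
})

test_that("per-record cascade over a labelled dataset matches a direct trace", {
  ds <- tiny_dataset()
  parts <- build_partitions(ds)
  expect_length(parts$mg1, 31L)
  expect_length(parts$icc2, 31L)
  n_train <- sum(ds$role == "train")
  for (k in c(1, 15, 31))
    expect_length(unique(parts$icc1[[k]]), n_train)

  feats <- c_alpha_features(ds, 30, parts)
  expect_equal(dim(feats$c_alpha), c(nrow(ds), 8L))
  expect_true(all(feats$c_alpha >= 0 & feats$c_alpha <= 31))

  # direct recomputation for one record and one encoding
  e <- assign_e_groups(ds, 30)
  k <- 15L
  lab <- parts$mg1[[k]]
  d <- d_features(lab, e)
  cb <- binarize_d(d)
  manual <- Reduce(`+`, lapply(parts$mg1, function(l)
    binarize_d(d_features(l, e))))
  expect_equal(unname(manual), unname(feats$pairs$MG1))
})

test_that("relabelling a training record from E2 to E3 shifts purity toward d3", {
  labels <- c(1L, 1L, 1L, 2L, 2L)
  e_before <- c(1L, 2L, 2L, 2L, 3L)
  e_after <- c(1L, 2L, 3L, 2L, 3L)  # one group-1 member E2 -> E3
  d_b <- d_features(labels, e_before)
  d_a <- d_features(labels, e_after)
  expect_true(all(d_a[1:3, "d2"] <= d_b[1:3, "d2"]))
  expect_true(all(d_a[1:3, "d3"] >= d_b[1:3, "d3"]))
  expect_equal(d_a[4:5, ], d_b[4:5, ])
})

test_that("a record whose groups are purely E3 aggregates to (0, 31)", {
  # two well-separated blocks: ineffective near-duplicates + potent cloud
  ds <- generate_fixture(n_potent = 6, n_ineffective = 6,
                         n_motif_families = 1, mutation_rate = 0,
                         seed = 21, split = FALSE)
  ds$role <- rep(c("train", "test"), c(10, 2))
  # make the two test records the last potent and last ineffective ones
  ds$role[c(6, 12)] <- "test"
  ds$role[c(11, 10)] <- "train"
  feats <- c_alpha_features(ds, 65)
  ineff_test <- which(ds$role == "test" & ds$inhibition < 70)
  for (t in c("MG1", "MG2")) {
    pair <- feats$pairs[[t]][ineff_test, ]
    expect_equal(unname(pair), c(0L, 31L))
  }
})
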