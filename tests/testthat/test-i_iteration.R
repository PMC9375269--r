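test_that("beta thresholds follow the potent training aggregates", {
  agg <- rbind(c(0, 7), c(2, 4), c(3, 11), c(9, 1))
  expect_equal(compute_beta(agg, 1:3, t = 1),
               list(beta1 = 0, beta2 = 11))
  # conditional max over potent records with first component zero
  agg3 <- rbind(c(0, 4), c(0, 11), c(2, 30))
  expect_equal(compute_beta(agg3, 1:3, t = 3),
               list(beta1 = 11, beta2 = 30))
  # no potent record with zero first component: +Inf sentinel
  agg4 <- rbind(c(1, 4), c(2, 11))
  expect_equal(compute_beta(agg4, 1:2, t = 4)$beta1, Inf)
  expect_error(compute_beta(agg, integer(0), 1), "no potent")
})

test_that("the removal predicate fires on any single condition", {
  betas0 <- lapply(1:4, function(t) list(beta1 = if (t <= 2) 0 else Inf,
                                         beta2 = 25))
  keep <- list(c(3, 5), c(2, 4), c(1, 6), c(2, 3))

  # (a): first component at or below beta1 for a mini-group type
  p <- keep; p[[1]] <- c(0, 5)
  r <- removal_predicate(p, betas0, s = 1)
  expect_true(r$remove)
  expect_equal(r$condition, "a:t1")

  # (c): zero first component and second >= min(Inf, 16+s) = 17
  p <- keep; p[[3]] <- c(0, 18)
  r <- removal_predicate(p, betas0, s = 1)
  expect_true(r$remove)
  expect_equal(r$condition, "c:t3")
  p[[3]] <- c(0, 16)
  expect_false(removal_predicate(p, betas0, s = 1)$remove)

  # (b): second component reaching the potent maximum
  p <- keep; p[[2]] <- c(2, 25)
  expect_equal(removal_predicate(p, betas0, s = 1)$condition, "b:t2")

  # none: all components strictly inside the thresholds
  expect_false(removal_predicate(keep, betas0, s = 1)$remove)
})

test_that("records with no ineffective-purity signal are never removed by the potent-maximum condition", {
  # beta2 = 0 (every potent training record has zero second component):
  # the condition must not fire vacuously on a record that also shows none
  betas <- lapply(1:4, function(t) list(beta1 = if (t <= 2) 0 else Inf,
                                        beta2 = 0))
  quiet <- list(c(3, 0), c(2, 0), c(1, 0), c(2, 0))
  expect_false(removal_predicate(quiet, betas, s = 5)$remove)
  loud <- list(c(3, 1), c(2, 0), c(1, 0), c(2, 0))
  expect_true(removal_predicate(loud, betas, s = 5)$remove)
})

test_that("aggregates that strictly dominate in the potent direction are never removed", {
  set.seed(31)
  for (rep in 1:50) {
    betas <- lapply(1:4, function(t) {
      list(beta1 = if (t <= 2) sample(0:5, 1) else sample(c(10:20, Inf), 1),
           beta2 = sample(5:31, 1))
    })
    pairs <- lapply(1:4, function(t) {
      c1 <- if (t <= 2) betas[[t]]$beta1 + sample(1:5, 1) else sample(1:31, 1)
      c2 <- sample(seq_len(min(betas[[t]]$beta2, 31)), 1) - 1L
      c(c1, c2)
    })
    expect_false(removal_predicate(pairs, betas, s = sample(1:10, 1))$remove)
  }
})

test_that("a single pass matches a naive trace of the cascade", {
  ds <- tiny_dataset(n = 12, seed = 42)
  st <- run_iteration(ds, alpha_start = 20, alpha_max = 20,
                      recompute_icc = FALSE)
  parts <- build_partitions(ds)
  e <- assign_e_groups(ds, 20)
  removed_oracle <- oracle_pass_removals(
    parts, e, ds$inhibition, ds$role == "train", 70, s = 1)
  first_pass <- st$removal_log[st$removal_log$pass == 1 &
                                 st$removal_log$stage == 1, "id"]
  expect_setequal(first_pass, ds$id[removed_oracle])
})

test_that("the staged iteration conserves and never resurrects test records", {
  st <- default_state()
  ds <- default_fixture()
  n_test <- sum(ds$role == "test")
  expect_equal(length(st$P_cluster) + length(st$I_cluster), n_test)
  expect_length(intersect(st$P_cluster, st$I_cluster), 0)
  expect_setequal(c(st$P_cluster, st$I_cluster), ds$id[ds$role == "test"])
  # removal log ids are unique: once removed, never removed again
  expect_false(anyDuplicated(st$removal_log$id) > 0)
  # cumulative removals are non-decreasing in stage
  removed_by_stage <- tapply(st$trace$n_removed, st$trace$stage, sum)
  expect_true(all(cumsum(removed_by_stage) >= 0))
  expect_true(all(diff(cumsum(removed_by_stage)) >= 0))
  # each non-final pass of a stage removes at least one record
  per_stage_last <- tapply(seq_len(nrow(st$trace)), st$trace$stage, max)
  nonfinal <- setdiff(seq_len(nrow(st$trace)), per_stage_last)
  expect_true(all(st$trace$n_removed[nonfinal] >= 1))
})

test_that("iteration is deterministic", {
  ds <- tiny_dataset(n = 15, seed = 8)
  a <- run_iteration(ds)
  b <- run_iteration(ds)
  expect_identical(a$removal_log, b$removal_log)
  expect_identical(a$P_cluster, b$P_cluster)
  expect_identical(a$trace, b$trace)
})

test_that("an empty or unremovable test set terminates cleanly", {
  ds <- tiny_dataset(n = 12, seed = 5)
  # all-train dataset: no test record to remove
  ds_all <- ds
  ds_all$role <- "train"
  class(ds_all) <- class(ds)
  attr(ds_all, "potency_threshold") <- 70
  st <- run_iteration(ds_all)
  expect_length(st$P_cluster, 0)
  expect_length(st$I_cluster, 0)
  expect_true(all(st$trace$n_removed == 0))
  expect_error(run_iteration(unclass(ds)), "sirna_dataset")
})

test_that("iteration requires potent training records", {
  ds <- generate_fixture(n_potent = 2, n_ineffective = 18, seed = 9,
                         split = FALSE)
  ds$role <- rep(c("train", "test"), length.out = nrow(ds))
  ds$role[ds$inhibition >= 70] <- "test"  # strip potent from training
  class(ds) <- c("sirna_dataset", "data.frame")
  attr(ds, "potency_threshold") <- 70
  expect_error(run_iteration(ds), "no potent training")
})
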