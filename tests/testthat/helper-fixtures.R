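# Shared fixtures, memoised so expensive end-to-end runs happen once per
# test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_fixture <- function() {
  cached("ds0", generate_fixture(seed = 0))
}

default_state <- function() {
  cached("state0", run_iteration(default_fixture()))
}

default_state_alpha10 <- function() {
  cached("state0_a10", run_iteration(default_fixture(), alpha_start = 10))
}

default_predictions <- function() {
  cached("pred0", predict_efficacy(default_state()))
}

# Small labelled dataset built by hand: sequences drawn deterministically.
tiny_dataset <- function(n = 12, seed = 42) {
  ds <- generate_fixture(n_potent = ceiling(n / 3),
                         n_ineffective = n - ceiling(n / 3),
                         n_motif_families = 2, mutation_rate = 0.1,
                         seed = seed)
  ds
}

random_tsv <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tinhibition",
               "s1\tACGUACGUACGUACGUACG\t85.0",
               "s2\tAAAAAAAAAAAAAAAAAAA\t42.0",
               "s3\tacgtacgtacgtacgtacg\t12.5"),
             path)
  path
}
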