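test_that("default skeleton matches the emulated summary structure exactly", {
  net <- generate_skeleton(seed = 1)
  expect_equal(n_trials(net), 117L)
  expect_equal(n_arms(net), 236L)
  expect_equal(length(treatments(net)), 12L)
  expect_equal(n_participants(net), 25928L)
  expect_true(is_skeleton(net))
  arms_per_trial <- table(table(net$study))
  expect_equal(unname(arms_per_trial[["2"]]), 115L)
  expect_equal(unname(arms_per_trial[["3"]]), 2L)
})

test_that("degenerate configuration is forced by its constraints", {
  net <- generate_skeleton(n_treatments = 2, n_trials = 1, n_arms = 2,
                           n_participants = 200, dispersion = 0, seed = 5)
  expect_equal(n_trials(net), 1L)
  expect_equal(net$sampleSize, c(100L, 100L))
})

test_that("generation is deterministic in the seed", {
  a <- generate_skeleton(seed = 42)
  b <- generate_skeleton(seed = 42)
  c_ <- generate_skeleton(seed = 43)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$treatment, c_$treatment))
})

test_that("conservation and connectivity hold across many seeds", {
  for (seed in 1:100) {
    net <- generate_skeleton(n_treatments = 6, n_trials = 12, n_arms = 26,
                             n_participants = 1500, seed = seed)
    expect_equal(n_trials(net), 12L)
    expect_equal(n_arms(net), 26L)
    expect_equal(n_participants(net), 1500L)
    # trial_network() would have errored on a disconnected graph; assert
    # explicitly anyway
    expect_equal(nrow(validate_network(net)), 0L)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generate_skeleton(n_treatments = 4, n_trials = 10, n_arms = 19),
               "at least 2")
  expect_error(generate_skeleton(n_arms = 236, n_participants = 100),
               "participant")
  expect_error(generate_skeleton(n_treatments = 1), "at least 2 treatments")
})

test_that("even sample-size allocation splits 25,928 over 236 arms as 110s and 109s", {
  sizes <- allocate_sample_sizes(236, 25928, dispersion = 0)
  expect_equal(sum(sizes), 25928L)
  expect_setequal(unique(sizes), c(109L, 110L))
  expect_equal(sum(sizes == 110L), 204L)
  expect_equal(sum(sizes == 109L), 32L)
  expect_equal(allocate_sample_sizes(2, 200), c(100L, 100L))
})

test_that("dispersed allocation conserves the total and keeps every arm populated", {
  for (seed in 1:25) {
    sizes <- allocate_sample_sizes(40, 813, dispersion = 0.6, seed = seed)
    expect_equal(sum(sizes), 813L)
    expect_true(all(sizes >= 1L))
  }
  expect_error(allocate_sample_sizes(10, 5), "at least n_arms")
})

test_that("treatment labels are symmetric: relabeling gives an isomorphic graph", {
  net <- generate_skeleton(n_treatments = 6, n_trials = 15, n_arms = 31,
                           n_participants = 3000, seed = 9)
  g1 <- igraph::graph_from_edgelist(as.matrix(do.call(rbind, lapply(
    split(net$treatment, net$study), function(tr) t(utils::combn(tr, 2))))),
    directed = FALSE)
  relabeled <- net
  map <- setNames(rev(treatments(net)), treatments(net))
  relabeled$treatment <- unname(map[net$treatment])
  g2 <- igraph::graph_from_edgelist(as.matrix(do.call(rbind, lapply(
    split(relabeled$treatment, relabeled$study),
    function(tr) t(utils::combn(tr, 2))))), directed = FALSE)
  expect_true(igraph::isomorphic(g1, g2))
})

test_that("generator configs load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_treatments: 4", "n_trials: 8", "n_arms: 17",
               "n_participants: 900", "seed: 2"), fy)
  cfg <- read_generator_config(fy)
  net <- do.call(generate_skeleton, cfg)
  expect_equal(n_arms(net), 17L)

  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_trials": 5, "n_arms": 10, "n_participants": 400}', fj)
  cfg2 <- read_generator_config(fj)
  expect_equal(cfg2$n_trials, 5L)
  fj2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"bogus_key": 1}', fj2)
  expect_error(read_generator_config(fj2), "unknown generator config key")
})
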