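test_that("bootstrap plans have the documented size, stratification and determinism", {
  lab <- class_labels(stats::setNames(rep(c("a", "b"), each = 5),
                                      paste0("s", 1:10)))
  plan <- make_bootstrap_plan(lab, k = 3, fraction = 0.9, master_seed = 9)
  expect_length(plan$index_sets, 3L)
  for (ix in plan$index_sets) {
    expect_length(ix, 9L)  # ceiling(0.9 * 10)
    expect_gte(sum(lab$labels[ix] == 1L), 2L)
    expect_gte(sum(lab$labels[ix] == -1L), 2L)
  }
  plan2 <- make_bootstrap_plan(lab, k = 3, fraction = 0.9, master_seed = 9)
  expect_identical(plan$index_sets, plan2$index_sets)
  expect_identical(plan$seeds, 9L + 1:3)

  expect_error(make_bootstrap_plan(lab, fraction = 1.5), "fraction")
  bad <- class_labels(stats::setNames(c("a", rep("b", 5)), paste0("s", 1:6)))
  expect_error(make_bootstrap_plan(bad), ">= 2 samples")
})

test_that("distinct-sample count matches the closed-form stratified expectation", {
  lab <- class_labels(stats::setNames(rep(c("a", "b"), each = 10),
                                      paste0("s", 1:20)))
  plan <- make_bootstrap_plan(lab, k = 1000, fraction = 0.9, master_seed = 7)
  mean_distinct <- mean(vapply(plan$index_sets,
                               function(ix) length(unique(ix)), numeric(1)))
  # drawing with replacement 9 of each stratum of 10:
  # E[distinct] = sum_c n_c (1 - (1 - 1/n_c)^draws_c)
  expected <- 2 * 10 * (1 - (1 - 1 / 10)^9)
  expect_lt(abs(mean_distinct - expected) / expected, 0.02)
})

test_that("per-bootstrap ranking yields valid permutations and degenerates to a direct call", {
  ds <- tiny_dataset(seed = 61, d = 30, n_informative = 5)
  plan <- make_bootstrap_plan(ds$labels, k = 5, fraction = 0.9,
                              master_seed = 3)
  rls <- rank_all_bootstraps(ds$matrix, ds$labels, plan, elim_percent = 25)
  expect_length(rls, 5L)
  for (rl in rls) expect_identical(sort(rl$order), seq_len(30L))

  # k = 1 with the full sample set equals a direct elimination call
  plan1 <- make_bootstrap_plan(ds$labels, k = 1, fraction = 0.9,
                               master_seed = 3)
  plan1$index_sets[[1]] <- seq_len(ncol(ds$matrix))
  got <- rank_all_bootstraps(ds$matrix, ds$labels, plan1, elim_percent = 25)
  direct <- recursive_eliminate(ds$matrix, ds$labels, elim_percent = 25)
  expect_identical(got[[1]]$order, direct$order)
})

test_that("CLA aggregation sums ranks, conserves totals and breaks ties by index", {
  ds <- tiny_dataset(seed = 62, d = 6, n_informative = 2)
  rl <- recursive_eliminate(ds$matrix, ds$labels, elim_percent = 100)

  # identical lists -> consensus order equals the common order
  ens <- aggregate_cla(list(rl, rl, rl))
  expect_identical(ens$final_order, rl$order)
  # conservation: k * N(N+1)/2
  expect_equal(sum(ens$aggregated), 3 * 6 * 7 / 2)

  # two exact reverses: all sums N+1, order resolved by feature index
  rev_rl <- rl
  rev_rl$order <- rev(rl$order)
  rev_rl$feature_ids <- rev(rl$feature_ids)
  ens2 <- aggregate_cla(list(rl, rev_rl))
  expect_true(all(ens2$aggregated == 7))
  expect_identical(ens2$final_order, 1:6)

  # weighted conservation: (sum w) * N(N+1)/2
  ens3 <- aggregate_cla(list(rl, rev_rl), bootstrap_weights = c(2, 0.5))
  expect_equal(sum(ens3$aggregated), 2.5 * 21)

  # a feature ranked first everywhere is first in the consensus
  expect_identical(ens$final_order[1], rl$order[1])
})

test_that("aggregation rejects mismatched feature universes", {
  ds <- tiny_dataset(seed = 63, d = 8)
  rl <- recursive_eliminate(ds$matrix, ds$labels, elim_percent = 100)
  other <- recursive_eliminate(ds$matrix[1:7, ], ds$labels,
                               elim_percent = 100)
  expect_error(aggregate_cla(list(rl, other)), "feature")
  renamed <- rl
  renamed$feature_ids <- rev(rl$feature_ids)
  expect_error(aggregate_cla(list(rl, renamed)), "universe")
})

test_that("signature extraction resolves counts and percentages", {
  ds <- tiny_dataset(seed = 64, d = 200, n_informative = 5)
  rl <- recursive_eliminate(ds$matrix, ds$labels, elim_percent = 100)
  ens <- aggregate_cla(list(rl))
  expect_identical(extract_signature(ens, 1)$feature_ids,
                   ens$feature_ids[ens$final_order[1]])
  expect_identical(extract_signature(ens, "10%")$size, 20L)
  # consensus of identical lists equals the top-s of any single list
  ens3 <- aggregate_cla(list(rl, rl, rl))
  expect_identical(extract_signature(ens3, 10)$feature_ids,
                   extract_signature(rl, 10)$feature_ids)
  expect_error(extract_signature(ens, 0), "signature size")
  expect_error(extract_signature(ens, 200), "signature size")
})

test_that("ensemble selection is more stable than single-bootstrap selection", {
  # repeated subsampling experiments on planted-signal data: total
  # stability of small-ensemble CLA signatures across repetitions should
  # exceed that of single-bootstrap signatures
  ds <- tiny_dataset(seed = 65, d = 40, n_informative = 6, delta = 1.5,
                     n_plus = 15, n_minus = 15)
  ens_sigs <- list(); single_sigs <- list()
  for (rep in 1:10) {
    plan <- make_bootstrap_plan(ds$labels, k = 4, fraction = 0.9,
                                master_seed = 100 * rep)
    rls <- rank_all_bootstraps(ds$matrix, ds$labels, plan,
                               elim_percent = 25)
    ens_sigs[[rep]] <- extract_signature(aggregate_cla(rls), 8)
    single_sigs[[rep]] <- extract_signature(rls[[1]], 8)
  }
  s_ens <- total_stability(ens_sigs, N = 40)$s_tot
  s_single <- total_stability(single_sigs, N = 40)$s_tot
  expect_gte(s_ens, s_single)
})
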