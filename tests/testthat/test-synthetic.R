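test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 100, n_up_true = 10, n_down_true = 10, seed = 11)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$study$matrix, b$study$matrix)
  expect_identical(a$study$detection_call, b$study$detection_call)
  expect_identical(a$truth, b$truth)
})

test_that("planted effect sizes are recovered from the emitted matrix", {
  cfg <- sim_config(n_genes = 100, n_up_true = 10, n_down_true = 0,
                    effect_log2fc = 1, noise_sd_log2 = 0.25,
                    n_case = 5, n_control = 5, seed = 1)
  sim <- simulate_study(cfg)
  st <- sim$study
  up_probes <- st$symbols %in% sim$truth$true_up
  diffs <- rowMeans(st$matrix[up_probes, st$group == "case"]) -
    rowMeans(st$matrix[up_probes, st$group == "control"])
  se <- 0.25 * sqrt(1 / 5 + 1 / 5) / sqrt(sum(up_probes))
  expect_lt(abs(mean(diffs) - 1), 3 * se)
})

test_that("a null simulation plants no group difference but keeps truth sets", {
  cfg <- sim_config(n_genes = 80, n_up_true = 8, n_down_true = 8,
                    effect_log2fc = 0, noise_sd_log2 = 0.2, seed = 5)
  sim <- simulate_study(cfg)
  st <- sim$study
  diffs <- rowMeans(st$matrix[, st$group == "case"]) -
    rowMeans(st$matrix[, st$group == "control"])
  # group means differ only by noise: mean difference near 0 at 3 SE
  expect_lt(abs(mean(diffs)), 3 * 0.2 * sqrt(2 / 5) / sqrt(length(diffs)))
  expect_length(sim$truth$true_up, 8)
  expect_length(sim$truth$true_down, 8)
  expect_length(intersect(sim$truth$true_up, sim$truth$true_down), 0)
})

test_that("truth bookkeeping assigns each planted symbol one direction", {
  cfg <- sim_config(n_genes = 200, n_up_true = 30, n_down_true = 40, seed = 2)
  sim <- simulate_study(cfg)
  pm <- sim$truth$probe_map
  per_gene <- tapply(pm$direction, pm$symbol, function(d) length(unique(d)))
  expect_true(all(per_gene == 1))
  expect_setequal(unique(pm$symbol[pm$direction == "up"]), sim$truth$true_up)
  expect_setequal(unique(pm$symbol[pm$direction == "down"]),
                  sim$truth$true_down)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_case = 0), "n_case")
  expect_error(sim_config(n_genes = 50, n_up_true = 40, n_down_true = 40,
                          frac_unexpressed = 0),
               "exceeds")
  expect_error(sim_config(present_prob_expressed = 1.5), "probability")
})

test_that("multi-study overlap design is honoured at the extremes", {
  base <- sim_config(n_genes = 200, n_up_true = 20, n_down_true = 20,
                     seed = 1)
  full <- multi_study_config(list(base, base), shared_up_fraction = 1,
                             shared_down_fraction = 1, inverted_fraction = 0,
                             seed = 3)
  sim <- simulate_multi_study(full)
  expect_identical(sim$truth$per_study$study1$up, sim$truth$per_study$study2$up)
  expect_identical(sim$truth$per_study$study1$down,
                   sim$truth$per_study$study2$down)

  none <- multi_study_config(list(base, base), shared_up_fraction = 0,
                             shared_down_fraction = 0, inverted_fraction = 0,
                             seed = 3)
  sim0 <- simulate_multi_study(none)
  expect_length(intersect(sim0$truth$per_study$study1$up,
                          sim0$truth$per_study$study2$up), 0)
  expect_length(intersect(sim0$truth$per_study$study1$down,
                          sim0$truth$per_study$study2$down), 0)

  expect_error(multi_study_config(list(base, base), shared_up_fraction = 0.95,
                                  inverted_fraction = 0.1),
               "<= 1")
  expect_error(multi_study_config(list(base)), ">= 2")
})

test_that("realized pairwise overlap of truth sets matches the design", {
  base <- sim_config(n_genes = 400, n_up_true = 40, n_down_true = 40,
                     seed = 1)
  cfg <- multi_study_config(list(base, base, base),
                            shared_up_fraction = 0.5,
                            shared_down_fraction = 0.5,
                            inverted_fraction = 0, seed = 9)
  sim <- simulate_multi_study(cfg)
  # shared core in every pair: |A intersect B| = 20, Jaccard = 20/60 = 1/3
  ps <- sim$truth$per_study
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- ps[[pair[1]]]$up; b <- ps[[pair[2]]]$up
    jac <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(jac, 1 / 3, tolerance = 1e-9)
  }
})

test_that("inverted genes flip direction relative to the first study", {
  base <- sim_config(n_genes = 300, n_up_true = 30, n_down_true = 30,
                     seed = 1)
  cfg <- multi_study_config(list(base, base), shared_up_fraction = 0.2,
                            shared_down_fraction = 0.2,
                            inverted_fraction = 0.2, seed = 4)
  sim <- simulate_multi_study(cfg)
  tr <- sim$truth
  expect_true(all(tr$inverted_up %in% tr$per_study$study1$up))
  expect_true(all(tr$inverted_up %in% tr$per_study$study2$down))
  expect_true(all(tr$inverted_down %in% tr$per_study$study1$down))
  expect_true(all(tr$inverted_down %in% tr$per_study$study2$up))
})

test_that("qPCR plate simulation obeys the amplification model", {
  # planted FC = 4 with E = 2 and no noise: exactly 2 cycles earlier in cases
  pl <- simulate_qpcr_plate(c("T1", "ACTB"), c(T1 = 4, ACTB = 1),
                            c(T1 = 2, ACTB = 2), reference_genes = "ACTB",
                            ct_noise_sd = 0, seed = 2)
  w <- dplyr::filter(pl$wells, gene == "T1")
  dct <- mean(w$ct[w$group == "control"]) - mean(w$ct[w$group == "case"])
  expect_equal(dct, 2, tolerance = 1e-12)
  expect_equal(nrow(pl$wells), 2 * (6 + 5) * 3)  # 3 technical replicates

  # all fold changes 1, no noise: Pfaffl recovery is exactly 1
  pl1 <- simulate_qpcr_plate(c("T1", "ACTB"), c(T1 = 1, ACTB = 1),
                             c(T1 = 1.9, ACTB = 2), reference_genes = "ACTB",
                             ct_noise_sd = 0, seed = 3)
  expect_equal(pfaffl_fold_change(pl1, "T1")$fold_change, 1,
               tolerance = 1e-12)

  expect_error(
    simulate_qpcr_plate("T1", c(T1 = 2), c(T1 = 2),
                        reference_genes = "ACTB"),
    "reference")
  expect_error(
    simulate_qpcr_plate(c("T1", "ACTB"), c(T1 = 2, ACTB = 1),
                        c(T1 = 2.5, ACTB = 2), reference_genes = "ACTB"),
    "efficienc")
})
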