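sim_fixture <- function(seed = 14) {
  cfg <- sim_config(n_genes = 150, n_up_true = 15, n_down_true = 15,
                    present_prob_unexpressed = 0.05, seed = seed)
  sim <- simulate_study(cfg)
  res <- rp_analyze(sim$study, n_permutations = 100, seed = seed)
  list(sim = sim, res = res)
}

test_that("detection filtering matches a direct recount of present fractions", {
  fx <- sim_fixture()
  st <- fx$sim$study
  filtered <- detection_filter(fx$res, st, "fraction_present",
                               detection_threshold = 0.2)
  frac <- rowMeans(st$detection_call == "P")
  expect_equal(sort(filtered$table$probe_id),
               sort(st$probe_ids[frac > 0.2]))
  expect_equal(filtered$universe_size, nrow(filtered$table))

  # p-value dialect agrees with its own recount
  filt_p <- detection_filter(fx$res, st, "fraction_detected_p",
                             detection_threshold = 0.1, detection_p = 0.01)
  frac_p <- rowMeans(st$detection_p < 0.01)
  expect_equal(sort(filt_p$table$probe_id),
               sort(st$probe_ids[frac_p > 0.1]))

  # edge probes: present everywhere retained, present nowhere removed
  always <- st$probe_ids[rowMeans(st$detection_call == "P") == 1]
  never <- st$probe_ids[rowMeans(st$detection_call == "P") == 0]
  expect_true(all(always %in% filtered$table$probe_id))
  expect_false(any(never %in% filtered$table$probe_id))
})

test_that("detection filtering without detection data is an error", {
  fx <- sim_fixture()
  st <- fx$sim$study
  bare <- expression_study(st$matrix, st$group, st$probe_ids, st$symbols)
  expect_error(detection_filter(fx$res, bare, "fraction_present"),
               "detection calls")
})

test_that("cutoff filtering keeps exactly the probes satisfying the thresholds", {
  fx <- sim_fixture()
  up <- apply_cutoffs(fx$res, "up", p_max = 1e-4, pfp_max = 0.05)
  # per-entry recheck against the full table
  t <- fx$res$table
  expected <- t$probe_id[t$p_up <= 1e-4 & t$pfp_up <= 0.05]
  expect_setequal(up$probe_id, expected)
  expect_true(all(up$p <= 1e-4 & up$pfp <= 0.05))
  expect_equal(up$rank, sort(up$rank))  # ordered by RP rank

  # permissive thresholds return the full ranked list
  all_up <- apply_cutoffs(fx$res, "up", p_max = 1, pfp_max = Inf)
  expect_equal(nrow(all_up), nrow(t))
  expect_equal(all_up$rank, seq_len(nrow(t)))

  # fold-change gate respects direction
  fc_up <- apply_cutoffs(fx$res, "up", p_max = 1, pfp_max = Inf, fc_min = 2)
  expect_true(all(fc_up$fc >= 2))
  fc_down <- apply_cutoffs(fx$res, "down", p_max = 1, pfp_max = Inf,
                           fc_min = 2)
  expect_true(all(fc_down$fc <= 0.5))
})

test_that("filtering is monotone: tightening thresholds never adds entries", {
  fx <- sim_fixture()
  loose <- apply_cutoffs(fx$res, "up", p_max = 1e-2, pfp_max = 0.2)
  tight <- apply_cutoffs(fx$res, "up", p_max = 1e-4, pfp_max = 0.05)
  expect_true(all(tight$probe_id %in% loose$probe_id))
})

test_that("detection filter and cutoffs commute", {
  fx <- sim_fixture()
  st <- fx$sim$study
  a <- apply_cutoffs(detection_filter(fx$res, st, "fraction_present"), "up")
  b0 <- apply_cutoffs(fx$res, "up")
  frac <- rowMeans(st$detection_call == "P")
  b <- b0[b0$probe_id %in% st$probe_ids[frac > 0.2], ]
  expect_setequal(a$probe_id, b$probe_id)
})

test_that("length-targeted lists keep the best-ranked qualifying probes", {
  fx <- sim_fixture()
  t <- fx$res$table
  qualifying <- t[t$pfp_up < 0.05, ]
  n_q <- nrow(qualifying)

  small <- size_targeted_list(fx$res, "up", target_length = 5)
  expect_equal(nrow(small), 5)
  # order audit: every excluded qualifying probe ranks worse than included
  excluded <- setdiff(qualifying$probe_id, small$probe_id)
  expect_true(min(t$rank_up[t$probe_id %in% excluded]) >
                max(small$rank))

  # target at the full qualifying count reproduces the pfp-only cutoff list
  full <- size_targeted_list(fx$res, "up", target_length = n_q)
  expect_setequal(full$probe_id, qualifying$probe_id)

  # shortfall is flagged, not padded
  expect_warning(
    over <- size_targeted_list(fx$res, "up", target_length = n_q + 50),
    "only")
  expect_equal(nrow(over), n_q)
  expect_true(attr(over, "shortfall"))

  expect_error(size_targeted_list(fx$res, "up", target_length = 0),
               "target_length")
})

test_that("symbol collapsing keeps the best-ranked probe per symbol", {
  gl <- rpmeta:::new_gene_list(
    tibble::tibble(rank = c(3, 40, 7, 12),
                   probe_id = c("p1", "p2", "p3", "p4"),
                   symbol = c("DUP", "DUP", "SOLO", NA),
                   fc = c(2.5, 2.1, 3.0, 1.8),
                   p = c(1e-5, 2e-5, 1e-6, 1e-4),
                   pfp = c(0.01, 0.02, 0.001, 0.04)),
    study = "s", direction = "up", collapsed = FALSE, universe_size = 100)
  expect_message(out <- collapse_to_symbols(gl), "1 un-named")
  expect_equal(nrow(out), 2)
  expect_true(!anyDuplicated(out$symbol))
  # DUP carries the rank-3 probe's statistics verbatim
  dup <- out[out$symbol == "DUP", ]
  expect_equal(dup$probe_id, "p1")
  expect_equal(dup$fc, 2.5)
  expect_equal(dup$rank, 3)
  expect_true(rpmeta:::is_collapsed(out))
})

test_that("collapsing a synthetic list yields one entry per mapped symbol", {
  fx <- sim_fixture()
  full <- apply_cutoffs(fx$res, "up", p_max = 1, pfp_max = Inf)
  collapsed <- suppressMessages(collapse_to_symbols(full))
  expect_equal(nrow(collapsed),
               length(unique(full$symbol[!is.na(full$symbol)])))
  expect_true(all(collapsed$rank == sort(collapsed$rank)))
  expect_lte(nrow(collapsed), nrow(full))
  # every retained statistic equals some input entry verbatim
  expect_true(all(collapsed$probe_id %in% full$probe_id))
})

test_that("directional lists are made disjoint by better rank", {
  up <- rpmeta:::new_gene_list(
    tibble::tibble(rank = c(1, 5), probe_id = c("a", "b"),
                   symbol = c("X", "Y"), fc = c(3, 2),
                   p = c(1e-5, 1e-5), pfp = c(0, 0)),
    "s", "up", TRUE, 100)
  down <- rpmeta:::new_gene_list(
    tibble::tibble(rank = c(2, 3), probe_id = c("c", "d"),
                   symbol = c("X", "Z"), fc = c(0.4, 0.3),
                   p = c(1e-5, 1e-5), pfp = c(0, 0)),
    "s", "down", TRUE, 100)
  expect_message(dj <- disjoin_directions(up, down), "both directions")
  expect_true("X" %in% dj$up$symbol)     # rank 1 beats rank 2
  expect_false("X" %in% dj$down$symbol)
  expect_length(intersect(dj$up$symbol, dj$down$symbol), 0)
})
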