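three_list_fixture <- function() {
  core_up <- paste0("CU", 1:5)
  core_down <- paste0("CD", 1:3)
  study_list_set(
    s1 = list(up = make_list(c(core_up, paste0("A", 1:10)), "s1", "up"),
              down = make_list(c(core_down, paste0("AD", 1:6)), "s1", "down")),
    s2 = list(up = make_list(c(core_up, paste0("B", 1:7)), "s2", "up"),
              down = make_list(c(core_down, paste0("BD", 1:4)), "s2", "down")),
    s3 = list(up = make_list(c(core_up, paste0("C", 1:3)), "s3", "up"),
              down = make_list(c(core_down, paste0("CDX", 1:2)), "s3", "down"))
  )
}

test_that("directional overlap counts and percentages follow the column convention", {
  x <- make_list(c("A", "B", "C"), "x", "up")
  y <- make_list(c("B", "C", "D", "E"), "y", "up")
  ov <- directional_overlap(x, y)
  expect_equal(ov$count, 2)
  expect_equal(ov$pct, 100 * 2 / 4)
  # symmetric count, asymmetric percentage
  vo <- directional_overlap(y, x)
  expect_equal(vo$count, 2)
  expect_equal(ov$pct * nrow(y), vo$pct * nrow(x))

  # a list against itself: 100% shared, 0% inverted
  expect_equal(directional_overlap(x, x)$pct, 100)
  expect_equal(directional_overlap(x, x, opposite = TRUE)$pct, 0)

  # opposite-direction overlap only counts with the opposite flag
  xd <- make_list(c("B", "Q"), "x", "down")
  expect_equal(directional_overlap(xd, y, opposite = TRUE)$count, 1)
  expect_equal(directional_overlap(xd, y, opposite = FALSE)$count, 0)

  raw <- rpmeta:::new_gene_list(
    tibble::tibble(rank = 1, probe_id = "p", symbol = "A", fc = 2,
                   p = 1e-5, pfp = 0),
    "x", "up", collapsed = FALSE, universe_size = 10)
  expect_error(directional_overlap(raw, y), "collapsed")
})

test_that("comparison matrix equals brute-force set arithmetic on planted lists", {
  set <- three_list_fixture()
  cm <- comparison_matrix(set)
  for (d in c("up", "down")) {
    for (x in names(set)) for (y in setdiff(names(set), x)) {
      cell <- dplyr::filter(cm, direction == d, type == "shared",
                            row_study == x, col_study == y)
      expected <- length(intersect(set[[x]][[d]]$symbol,
                                   set[[y]][[d]]$symbol))
      expect_equal(cell$count, expected)
      expect_equal(cell$pct, 100 * expected / nrow(set[[y]][[d]]))
    }
  }
  # no inverted genes were planted
  expect_true(all(cm$count[cm$type == "inverted"] == 0))
  # ALL row: core genes are shared with at least one other study
  all_s1 <- dplyr::filter(cm, direction == "up", type == "shared",
                          row_study == "ALL", col_study == "s1")
  expect_equal(all_s1$count, 5)
})

test_that("two disjoint studies give an all-zero matrix", {
  set <- study_list_set(
    a = list(up = make_list(c("A1", "A2"), "a", "up"),
             down = make_list(c("A3"), "a", "down")),
    b = list(up = make_list(c("B1", "B2"), "b", "up"),
             down = make_list(c("B3"), "b", "down")))
  cm <- comparison_matrix(set)
  expect_true(all(cm$count == 0))
  expect_true(all(cm$pct_display == 0))
})

test_that("shared + inverted never exceeds 100% of the column list", {
  set <- three_list_fixture()
  cm <- comparison_matrix(set)
  tot <- cm |>
    dplyr::filter(row_study != "ALL") |>
    dplyr::group_by(direction, row_study, col_study) |>
    dplyr::summarise(total = sum(pct), .groups = "drop")
  expect_true(all(tot$total <= 100 + 1e-9))
})

test_that("intersection signature recovers the planted common core exactly", {
  set <- three_list_fixture()
  sig <- intersect_signature(set)
  expect_setequal(sig$up_symbols, paste0("CU", 1:5))
  expect_setequal(sig$down_symbols, paste0("CD", 1:3))
  # signature is contained in every selected list
  for (s in names(set)) {
    expect_true(all(sig$up_symbols %in% set[[s]]$up$symbol))
    expect_true(all(sig$down_symbols %in% set[[s]]$down$symbol))
  }
  # removing a list never shrinks the signature
  sig12 <- intersect_signature(set, c("s1", "s2"))
  expect_true(all(sig$up_symbols %in% sig12$up_symbols))

  # venn region counts cover all 2^3 - 1 regions and sum to the union size
  venn_up <- sig$venn_counts[sig$venn_counts$direction == "up", ]
  expect_equal(nrow(venn_up), 7)
  expect_equal(sum(venn_up$count),
               length(unique(unlist(lapply(set, function(s) s$up$symbol)))))
  expect_equal(venn_up$count[venn_up$region == "s1&s2&s3"], 5L)

  expect_error(intersect_signature(set, character()), "empty")
  expect_error(intersect_signature(set, "nope"), "unknown")
})

test_that("three identical lists give themselves back, centre region only", {
  l <- c("G1", "G2", "G3")
  set <- study_list_set(
    a = list(up = make_list(l, "a", "up"), down = make_list("D1", "a", "down")),
    b = list(up = make_list(l, "b", "up"), down = make_list("D1", "b", "down")),
    c = list(up = make_list(l, "c", "up"), down = make_list("D1", "c", "down")))
  sig <- intersect_signature(set)
  expect_setequal(sig$up_symbols, l)
  venn_up <- sig$venn_counts[sig$venn_counts$direction == "up", ]
  expect_equal(venn_up$count[venn_up$region == "a&b&c"], 3L)
  expect_true(all(venn_up$count[venn_up$region != "a&b&c"] == 0))
})

test_that("shared gene table lists per-study overlaps and the >=2-study union", {
  set <- three_list_fixture()
  tab <- shared_gene_table(set, "s1")
  s2_up <- tab$per_study[tab$per_study$study == "s2" &
                           tab$per_study$direction == "up", ]
  expect_setequal(s2_up$symbol, paste0("CU", 1:5))
  comb_up <- tab$combined[tab$combined$direction == "up", ]
  expect_setequal(comb_up$symbol, paste0("CU", 1:5))
  expect_true(all(comb_up$n_studies == 3))

  # all-disjoint lists: empty combined table
  dset <- study_list_set(
    a = list(up = make_list("A1", "a", "up"),
             down = make_list("A2", "a", "down")),
    b = list(up = make_list("B1", "b", "up"),
             down = make_list("B2", "b", "down")))
  expect_equal(nrow(shared_gene_table(dset, "a")$combined), 0)
})

test_that("the bundled six-study set reproduces the published denominator identity", {
  set <- reference_study_set()
  cm <- comparison_matrix(set)
  shared <- dplyr::filter(cm, type == "shared", row_study != "ALL")
  # shared_pct[X][Y] * N_Y = shared_pct[Y][X] * N_X (same intersection)
  for (i in seq_len(nrow(shared))) {
    r <- shared[i, ]
    mirror <- dplyr::filter(shared, direction == r$direction,
                            row_study == r$col_study,
                            col_study == r$row_study)
    expect_equal(r$pct * r$denominator, mirror$pct * mirror$denominator,
                 tolerance = 1e-9)
  }
})

test_that("study sets reject uncollapsed or direction-overlapping lists", {
  up <- make_list(c("X", "Y"), "s", "up")
  down_clash <- make_list(c("X"), "s", "down")
  expect_error(study_list_set(s = list(up = up, down = down_clash)),
               "both directions")
})
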