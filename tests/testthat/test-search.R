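test_that("subset enumeration matches the closed-form counts", {
  atlas <- fix_atlas()
  left_all <- enumerate_subsets(atlas, "left_all")
  expect_length(left_all, 511L)                 # 2^9 - 1
  expect_length(enumerate_subsets(atlas, "left_3"), choose(9, 3))
  expect_length(enumerate_subsets(atlas, "right_3"), 84L)
  expect_length(enumerate_subsets(atlas, "right_all"), 511L)
  expect_length(enumerate_subsets(atlas, "both_6"), choose(18, 6))
  # deterministic order: sizes ascending, lexicographic within size
  sizes <- vapply(left_all, function(s) length(s$roi_ids), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_identical(left_all[[1]]$roi_ids, "S1F_L")
  expect_identical(left_all[[511]]$roi_ids,
                   atlas$regions$id[atlas$regions$lobe == "L"])
  # lobes are respected
  expect_true(all(vapply(enumerate_subsets(atlas, "right_3"),
                         function(s) s$mode == "right", logical(1))))
  expect_error(enumerate_subsets(atlas, "sensor"), "unknown search mode")
})

test_that("evaluating the planted subset recovers the planted contrast", {
  roi <- fix_roi_mu()
  sub <- roi_subset(planted_roi_ids, fix_atlas())
  ev <- evaluate_subset(sub, 2, roi)
  expect_s3_class(ev, "eval_result")
  expect_gt(ev$accuracy, 90)
  expect_equal(ev$band, "mu")
  total <- with(ev$confusion, TP + FN + TN + FP)
  expect_equal(total, 100L)
  # determinism: identical result on re-evaluation
  ev2 <- evaluate_subset(sub, 2, roi)
  expect_equal(ev, ev2)
  # filter-pair capacity precondition
  expect_error(evaluate_subset(roi_subset("S1H_L", fix_atlas()), 1, roi),
               "floor")
  expect_error(evaluate_subset(sub, 3, roi), "floor")
})

test_that("the left-lobe searches find the planted regions and report dominant best", {
  roi <- fix_roi_mu()
  rep3 <- run_search(roi, "left_3", m_grid = 1)
  expect_equal(nrow(rep3$results), 84L)
  expect_true(all(rep3$results$m_pairs == 1))
  # best dominates every retained evaluation
  expect_equal(rep3$best$accuracy, max(rep3$results$accuracy))
  expect_true(all(rep3$best$accuracy >= rep3$results$accuracy))
  # the winner overlaps the planted set
  expect_gt(length(intersect(rep3$best$subset$roi_ids, planted_roi_ids)), 0)
  # monotone information: searching all subset sizes can only improve
  rep_all <- run_search(roi, "left_all", m_grid = 1)
  expect_gte(rep_all$best$accuracy, rep3$best$accuracy)
  # 9 singleton subsets cannot host a filter pair and are skipped
  expect_equal(nrow(rep_all$results), 502L)
  expect_equal(nrow(rep_all$skipped), 9L)
  # skipped configurations are recorded, not fatal
  rep_skip <- run_search(roi, "left_3", m_grid = c(1, 2))
  expect_equal(nrow(rep_skip$results), 84L)
  expect_equal(nrow(rep_skip$skipped), 84L)
  expect_match(rep_skip$skipped$reason[1], "floor")
})

test_that("occurrence tallies count best-subset memberships and conserve mass", {
  roi <- fix_roi_mu()
  rep3 <- run_search(roi, "left_3", m_grid = 1)
  tl <- tally_occurrences(list(rep3), weight = "winner")
  expect_equal(sum(tl$count), 3)
  expect_true(all(tl$count[match(rep3$best$subset$roi_ids, tl$roi_id)] == 1))
  # five reports sharing one region count it five times
  tl5 <- tally_occurrences(rep(list(rep3), 5), weight = "winner")
  expect_equal(tl5$count[match(rep3$best$subset$roi_ids[1], tl5$roi_id)], 5)
  expect_equal(sum(tl5$count), 15)
  # fractional weighting distributes one unit per report across ties
  tlf <- tally_occurrences(list(rep3), weight = "fractional")
  expect_equal(sum(tlf$count), 3 * 1) # size-3 subsets, one report
  # mixed modes are refused without explicit grouping
  repL <- run_search(roi, "left_3", m_grid = 1)
  rep_all <- run_search(roi, "left_all", m_grid = 1)
  expect_error(tally_occurrences(list(repL, rep_all)), "mix")
  expect_silent(tl_mixed <- tally_occurrences(list(repL, rep_all),
                                              allow_mixed = TRUE))
  # chart renders one line per region
  lines <- utils::capture.output(occurrence_chart(tl))
  expect_length(lines, nrow(tl))
})

test_that("null data yield chance-level accuracy through the full chain", {
  st <- fix_study()
  cfg0 <- generator_config(planted_effects = list(), n_train = 60,
                           n_test = 100, seed = 3)
  tt <- generate_trialset(cfg0, st$leadfield, st$sources)
  d0 <- prepare_roi_data(tt$train, tt$test, st$inverse_op, st$sources,
                         band_spec("mu"))
  ev <- evaluate_subset(roi_subset(planted_roi_ids, fix_atlas()), 1, d0)
  band <- null_band(100)
  expect_gt(ev$accuracy, band[1])
  expect_lt(ev$accuracy, band[2])
})
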