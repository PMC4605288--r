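test_that("the objective counts gold-contained top-N predictions", {
  fx <- recovery_fixture()
  w <- weight_set("binding")
  # empty gold -> 0
  empty_gold <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
  expect_equal(objective_top_n_overlap(fx$candidates, w, empty_gold, 10L), 0L)
  # saturation: top_n beyond the candidate count counts everything contained
  all_n <- objective_top_n_overlap(fx$candidates, w, fx$gold,
                                   top_n = 10000L)
  expect_equal(all_n, fx$n_gold)
  expect_error(objective_top_n_overlap(fx$candidates, w, fx$gold, 0L),
               "positive")
})

test_that("planted gold sites outscoring all decoys are all recovered", {
  fx <- recovery_fixture(n_gold = 20L)
  w <- weight_set("binding")  # (5, 70, 50): gold mask beats every decoy
  got <- objective_top_n_overlap(fx$candidates, w, fx$gold, top_n = 20L)
  # exhaustive check: gold mask scores strictly above all decoy masks here
  s_gold <- base_score(RECOVERY_GOLD_MASK, w)
  for (dm in RECOVERY_DECOY_MASKS) expect_lt(base_score(dm, w), s_gold)
  expect_equal(got, 20L)
})

test_that("a single-point grid returns that point", {
  fx <- recovery_fixture()
  # stop_drop = 0 freezes every boundary, so the grid is evaluated as-is
  res <- grid_search(fx$candidates, fx$gold,
                     grid_spec(5, 70, 50, stop_drop = 0, top_n = 8L))
  expect_equal(c(res$best$s1, res$best$s2, res$best$s3), c(5, 70, 50))
  expect_equal(nrow(res$table), 1L)
})

test_that("grid search recovers the planted weights and matches brute force", {
  fx <- recovery_fixture()
  res <- grid_search(fx$candidates, fx$gold, RECOVERY_GRID)
  expect_equal(c(res$best$s1, res$best$s2, res$best$s3), c(5, 70, 50))
  expect_false(res$all_zero)
  expect_equal(nrow(res$table), 125L)  # interior optimum: no expansion

  # brute-force oracle over the same grid via the standalone scoring path
  brute <- apply(res$table, 1L, function(row) {
    w <- weight_set("binding", s1 = row[["s1"]], s2 = row[["s2"]],
                    s3 = row[["s3"]])
    ranked <- finalize_scores(score_candidates(fx$candidates, w), NULL, w)
    top_n_overlap(ranked, fx$gold, 8L)
  })
  expect_equal(res$table$objective, as.numeric(brute))
  # the winner is the unique maximum of the exhaustive table
  best_rows <- res$table[res$table$objective == max(res$table$objective), ]
  expect_equal(nrow(best_rows), 1L)
  expect_equal(unlist(best_rows[, 1:3], use.names = FALSE), c(5, 70, 50))
  # optimum objective dominates every evaluated point
  expect_true(all(res$best_objective >= res$table$objective))
})

test_that("the objective is invariant under candidate order", {
  fx <- recovery_fixture()
  set.seed(33)
  perm <- sample(nrow(fx$candidates))
  res1 <- grid_search(fx$candidates, fx$gold, RECOVERY_GRID)
  res2 <- grid_search(fx$candidates[perm, ], fx$gold, RECOVERY_GRID)
  expect_equal(res1$table, res2$table)
  expect_equal(res1$best$s1, res2$best$s1)
})

test_that("boundary optima trigger uniform-spacing expansion and frontier stops", {
  fx <- recovery_fixture()
  # start the s3 axis far below the optimum: the search must walk the
  # boundary up to 50, then stop each axis once its frontier drops
  res <- grid_search(fx$candidates, fx$gold,
                     grid_spec(s1_values = 5, s2_values = 70,
                               s3_values = c(20, 30),
                               expansion_step = c(5, 5, 10),
                               stop_drop = 4, top_n = 8L))
  expect_equal(c(res$best$s1, res$best$s2, res$best$s3), c(5, 70, 50))
  expect_gt(res$rounds, 2L)
  expect_equal(res$best_objective, 8)
  expect_true(all(res$best_objective >= res$table$objective))
  # the frontier past the peak was evaluated and found worse
  expect_true(any(res$table$s3 > 50 & res$table$objective < 8))
})

test_that("an infinite stop_drop on a fixed interior grid is exhaustive", {
  fx <- recovery_fixture()
  grid <- grid_spec(s1_values = c(0, 5, 10), s2_values = c(60, 70, 80),
                    s3_values = c(40, 50, 60), stop_drop = Inf, top_n = 8L)
  res <- grid_search(fx$candidates, fx$gold, grid)
  expect_equal(nrow(res$table), 27L)
  expect_equal(res$best_objective, max(res$table$objective))
})

test_that("an all-zero objective warns and returns the tie-break minimum", {
  fx <- recovery_fixture()
  far_gold <- data.frame(chrom = "chrZ", start = 0L, end = 100L)
  expect_warning(
    res <- grid_search(fx$candidates, far_gold,
                       grid_spec(c(5, 10), c(60, 70), c(40, 50),
                                 top_n = 8L)),
    "zero everywhere")
  expect_true(res$all_zero)
  expect_equal(c(res$best$s1, res$best$s2, res$best$s3), c(5, 60, 40))
})

test_that("grid specs are validated", {
  expect_error(grid_spec(s1_values = numeric(0)), "non-empty")
  expect_error(grid_spec(s1_values = c(5, 5)), "strictly increasing")
  expect_error(grid_spec(s1_values = c(-1, 5)), "non-negative")
  expect_error(grid_spec(top_n = 0), "positive")
})

chromatin_training_fixture <- function() {
  # gold sites: single PAM-proximal mismatch (S = 800), highly accessible;
  # decoys: perfect matches (S = 875) in closed chromatin. Base score alone
  # ranks every decoy first; accessibility must separate them.
  mask_gold <- paste0(strrep("0", 19), "1")
  mk <- function(mask, start0, n) {
    data.frame(chrom = "chr1", start = start0 + (seq_len(n) - 1L) * 50L,
               end = start0 + (seq_len(n) - 1L) * 50L + 20L, strand = "+",
               site_seq = strrep("A", 20), pam = "AGG", pam_class = "NGG",
               mismatch_mask = mask, n_mismatches = sum(
                 strsplit(mask, "")[[1L]] == "1"),
               guide = "train", stringsAsFactors = FALSE)
  }
  gold_sites <- mk(mask_gold, 1000L, 6L)
  decoys <- mk(strrep("0", 20), 50000L, 6L)
  peaks <- rep(list(data.frame(chrom = "chr1", start = 900L, end = 1400L)),
               125L)
  list(candidates = rbind(gold_sites, decoys),
       gold = data.frame(chrom = "chr1", start = gold_sites$start - 5L,
                         end = gold_sites$end + 5L),
       track = build_bin_track(peaks, bin_width = 200L))
}

test_that("chromatin-weight training prefers d > 0 when accessibility separates", {
  fx <- chromatin_training_fixture()
  w <- weight_set("binding")
  res <- train_chromatin_weight(fx$candidates, fx$gold, fx$track,
                                d_values = c(0, 20, 40, 60, 80),
                                base_weights = w, top_n = 6L)
  # S_f(gold) = 800 + 0.0113*125*d exceeds 875 once d > 53
  expect_gt(res$best_d, 0)
  expect_equal(res$best_objective, 6)
  expect_true(all(diff(res$table$objective) >= 0))
})

test_that("chromatin-weight training degenerates gracefully", {
  fx <- chromatin_training_fixture()
  w <- weight_set("binding")
  single <- train_chromatin_weight(fx$candidates, fx$gold, fx$track,
                                   d_values = 7, base_weights = w)
  expect_equal(single$best_d, 7)
  # all-zero track: objective constant in d, smallest d returned
  far_track <- build_bin_track(
    list(data.frame(chrom = "chrZ", start = 0L, end = 100L)))
  res <- train_chromatin_weight(fx$candidates, fx$gold, far_track,
                                d_values = c(5, 10, 20), base_weights = w,
                                top_n = 6L)
  expect_equal(res$best_d, 5)
  expect_equal(length(unique(res$table$objective)), 1L)
  expect_error(train_chromatin_weight(fx$candidates, fx$gold, fx$track,
                                      numeric(0)), "non-empty")
})
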