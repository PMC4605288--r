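ranked_predictions <- function(df) {
  df$rank <- seq_len(nrow(df))
  df
}

test_that("top_n_overlap counts only fully contained predictions", {
  preds <- ranked_predictions(data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 480L),
    end = c(120L, 320L, 510L),
    stringsAsFactors = FALSE))
  # gold covers the first two entirely, the third only halfway
  gold <- data.frame(chrom = "chr1", start = c(90L, 290L, 495L),
                     end = c(130L, 330L, 600L))
  expect_equal(top_n_overlap(preds, gold, 3L), 2L)
  expect_equal(top_n_overlap(preds, gold, 1L), 1L)
  # saturation and edge cases
  expect_equal(top_n_overlap(preds, gold, 1000L), 2L)
  expect_equal(top_n_overlap(preds[0, ], gold, 5L), 0L)
  expect_error(top_n_overlap(preds, gold, 0L), "positive")
  # whole-genome gold saturates at n
  genome_gold <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  expect_equal(top_n_overlap(preds, genome_gold, 2L), 2L)
  # a prediction inside two overlapping gold intervals counts once
  double_gold <- data.frame(chrom = "chr1", start = c(90L, 95L),
                            end = c(130L, 125L))
  expect_equal(top_n_overlap(preds, double_gold, 3L), 1L)
})

test_that("predictions contained in their own intervals all count", {
  set.seed(23)
  genome <- random_genome(2000L)
  guide <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
  sites <- enumerate_candidates(genome, guide_query(guide, "binding"),
                                budget = 12L)
  ranked <- finalize_scores(score_candidates(sites, weight_set("binding")))
  self_gold <- ranked[, c("chrom", "start", "end")]
  for (n in c(1L, 5L, nrow(ranked), nrow(ranked) + 10L)) {
    expect_equal(top_n_overlap(ranked, self_gold, n),
                 min(n, nrow(ranked)))
  }
})

test_that("overlap curves are monotone and match per-n brute force", {
  set.seed(31)
  genome <- random_genome(2500L)
  guide <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
  sites <- enumerate_candidates(genome, guide_query(guide, "binding"),
                                budget = 11L)
  ranked <- finalize_scores(score_candidates(sites, weight_set("binding")))
  # gold: a random half of the predictions, padded
  pick <- sort(sample(nrow(ranked), nrow(ranked) %/% 2))
  gold <- data.frame(chrom = ranked$chrom[pick],
                     start = pmax(0L, ranked$start[pick] - 5L),
                     end = ranked$end[pick] + 5L)
  n_values <- c(0L, 1L, 2L, 5L, 10L, 20L, nrow(ranked))
  curve <- overlap_curve(ranked, gold, n_values)
  expect_equal(curve$n, n_values)
  expect_true(all(diff(curve$overlap) >= 0))
  expect_true(all(curve$overlap <= pmin(curve$n, nrow(ranked))))
  expect_equal(curve$overlap[1L], 0L)
  # brute force: walk the ranked list by hand for each n
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    if (n == 0) next
    top <- head(ranked, n)
    by_hand <- sum(vapply(seq_len(nrow(top)), function(j) {
      any(gold$chrom == top$chrom[j] & gold$start <= top$start[j] &
            gold$end >= top$end[j])
    }, logical(1)))
    expect_equal(curve$overlap[i], by_hand)
  }
  expect_error(overlap_curve(ranked, gold, c(-1L, 5L)), "non-negative")
})

enrichment_world <- function() {
  glen <- 20000L
  # accessible blocks with graded cell-type support
  peaks <- lapply(1:10, function(ct) {
    blocks <- data.frame(chrom = "chr1",
                         start = c(2000L, 6000L, 10000L),
                         end = c(2600L, 6600L, 10600L))
    # block support: 10, 6, 3 cell types
    keep <- c(TRUE, ct <= 6L, ct <= 3L)
    blocks[keep, , drop = FALSE]
  })
  list(track = build_bin_track(peaks, bin_width = 200L),
       sizes = c(chr1 = glen))
}

test_that("planted accessible sites are called enriched at the floor p-value", {
  world <- enrichment_world()
  # all sites inside the X = 10 block
  sites <- data.frame(chrom = "chr1",
                      start = seq(2050L, 2500L, by = 50L),
                      end = seq(2070L, 2520L, by = 50L))
  res <- random_region_enrichment(sites, world$track, world$sizes,
                                  n_simulations = 200L, seed = 99L)
  expect_equal(res$p_value, 1 / 201)
  expect_equal(res$observed_stat, 10)
  expect_equal(sum(res$per_class$observed_fraction), 1)
})

test_that("null sites are not systematically enriched", {
  world <- enrichment_world()
  set.seed(7)
  ps <- vapply(1:10, function(i) {
    sites <- place_random_regions(rep(20L, 40L), world$sizes)
    res <- random_region_enrichment(sites, world$track, world$sizes,
                                    n_simulations = 100L, seed = 1000L + i)
    c(res$p_value, abs(res$observed_stat - mean(res$sim_stats)) /
        max(sd(res$sim_stats), 1e-9))
  }, numeric(2))
  # most null repetitions are unremarkable
  expect_gte(mean(ps[1, ] > 0.05), 0.8)
  expect_gte(mean(ps[2, ] <= 3), 0.9)
})

test_that("the enrichment simulation is reproducible and validates input", {
  world <- enrichment_world()
  sites <- data.frame(chrom = "chr1", start = c(100L, 6100L),
                      end = c(120L, 6120L))
  r1 <- random_region_enrichment(sites, world$track, world$sizes,
                                 n_simulations = 50L, seed = 5L)
  r2 <- random_region_enrichment(sites, world$track, world$sizes,
                                 n_simulations = 50L, seed = 5L)
  expect_identical(r1$sim_stats, r2$sim_stats)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(random_region_enrichment(sites, world$track, world$sizes,
                                        n_simulations = 0L), "positive")
  expect_error(random_region_enrichment(sites[0, ], world$track,
                                        world$sizes, 10L), "empty")
  tiny <- c(chr1 = 10)
  expect_error(random_region_enrichment(sites, world$track, tiny, 10L),
               "too small")
})

test_that("the accessibility trend refit recovers a planted linear relation", {
  per_class <- data.frame(X = 0:10,
                          observed_fraction = 0.02 + 0.0113 * (0:10))
  fit <- fit_accessibility_trend(per_class)
  expect_equal(unname(fit["slope"]), 0.0113, tolerance = 1e-10)
  expect_equal(unname(fit["intercept"]), 0.02, tolerance = 1e-10)
})
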