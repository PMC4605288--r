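#' Top-N containment overlap with a gold-standard set
#'
#' Counts how many of the top `n` ranked predictions are 100% contained
#' within some gold interval (the containment fraction applies to the
#' prediction, as in `bedtools intersect -f 1`). A prediction inside two
#' overlapping gold intervals counts once; `n` beyond the number of
#' predictions saturates.
#'
#' @param predictions Ranked site table (rows in rank order, e.g. from
#'   [finalize_scores()]) or BED-like data.frame with `chrom`, `start`,
#'   `end`.
#' @param gold Gold intervals (data.frame or BED path).
#' @param n Number of top predictions to consider (positive).
#' @return Integer overlap count.
#' @export
top_n_overlap <- function(predictions, gold, n) {
  if (length(n) != 1L || is.na(n) || n <= 0)
    stop("`n` must be a positive integer")
  if ("rank" %in% names(predictions))
    predictions <- predictions[order(predictions$rank), , drop = FALSE]
  top <- head(predictions, n)
  sum(contained_in_gold(top, gold))
}

#' Overlap as a function of list length
#'
#' Applies [top_n_overlap()] for each requested `n`; the resulting curve
#' is non-decreasing in `n`. Larger prediction lists can only gain
#' validated sites, at the cost of more unvalidated ones.
#'
#' @inheritParams top_n_overlap
#' @param n_values Non-negative integers (`n = 0` contributes overlap 0).
#' @return Data.frame with columns `n` and `overlap`.
#' @export
overlap_curve <- function(predictions, gold, n_values) {
  if (any(n_values < 0)) stop("`n_values` must be non-negative")
  overlap <- vapply(n_values, function(n) {
    if (n == 0) 0L else as.integer(top_n_overlap(predictions, gold, n))
  }, integer(1))
  data.frame(n = n_values, overlap = overlap)
}

# Uniform placement of length-matched random regions: chromosome sampled
# proportional to length, start uniform among valid positions.
place_random_regions <- function(widths, genome_sizes) {
  chroms <- names(genome_sizes)
  out_chrom <- character(length(widths))
  out_start <- integer(length(widths))
  for (j in seq_along(widths)) {
    w <- widths[j]
    eligible <- genome_sizes >= w
    if (!any(eligible))
      stop("genome too small to place a region of width ", w)
    probs <- ifelse(eligible, genome_sizes, 0)
    ch <- sample(chroms, 1L, prob = probs)
    out_chrom[j] <- ch
    out_start[j] <- floor(runif(1L, 0, genome_sizes[[ch]] - w + 1))
  }
  data.frame(chrom = out_chrom, start = out_start,
             end = out_start + widths, stringsAsFactors = FALSE)
}

#' Enrichment of sites in frequently accessible chromatin
#'
#' Tests whether a set of genomic sites falls into commonly open chromatin
#' more often than expected by chance. Each site is assigned the
#' accessibility count `X` of the most accessible bin it overlaps; the
#' observed per-frequency-class fractions (proportion of sites at each
#' `X`) are compared with `n_simulations` sets of length-matched regions
#' placed uniformly at random (chromosome chosen proportional to length).
#' The summary statistic is the mean per-site `X`; the empirical one-sided
#' p-value is `(1 + #{simulated mean >= observed mean}) /
#' (n_simulations + 1)`.
#'
#' @param sites Data.frame with `chrom`, `start`, `end`.
#' @param track A [build_bin_track()] accessibility track.
#' @param genome_sizes Named vector of chromosome lengths (bp).
#' @param n_simulations Number of random placements (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `enrichment_result`: `per_class` (data.frame
#'   `X`, `observed_fraction`, `sim_mean`, `sim_sd` over all observed
#'   accessibility classes), `observed_stat`, `sim_stats`, `p_value`,
#'   `n_simulations`.
#' @export
random_region_enrichment <- function(sites, track, genome_sizes,
                                     n_simulations = 1000L, seed = NULL) {
  if (n_simulations <= 0L) stop("`n_simulations` must be positive")
  if (!nrow(sites)) stop("`sites` is empty")
  if (!is.null(seed)) set.seed(seed)
  widths <- sites$end - sites$start
  if (any(widths > max(genome_sizes)))
    stop("genome too small to place regions of the requested width")

  obs_x <- site_cell_type_count(sites, track)
  observed_stat <- mean(obs_x)

  classes <- sort(unique(c(0L, track$bins$X)))
  frac_of <- function(xv) {
    as.numeric(table(factor(xv, levels = classes))) / length(xv)
  }
  obs_frac <- frac_of(obs_x)

  sim_stats <- numeric(n_simulations)
  sim_frac <- matrix(0, nrow = n_simulations, ncol = length(classes))
  for (s in seq_len(n_simulations)) {
    rnd <- place_random_regions(widths, genome_sizes)
    x <- site_cell_type_count(rnd, track)
    sim_stats[s] <- mean(x)
    sim_frac[s, ] <- frac_of(x)
  }
  p_value <- (1 + sum(sim_stats >= observed_stat)) / (n_simulations + 1)

  per_class <- data.frame(
    X = classes,
    observed_fraction = obs_frac,
    sim_mean = colMeans(sim_frac),
    sim_sd = apply(sim_frac, 2L, sd)
  )
  structure(list(per_class = per_class, observed_stat = observed_stat,
                 sim_stats = sim_stats, p_value = p_value,
                 n_simulations = as.integer(n_simulations)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: observed mean X = %.3f, simulated %.3f +/- %.3f (n = %d), p = %.4g\n",
    x$observed_stat, mean(x$sim_stats), sd(x$sim_stats),
    x$n_simulations, x$p_value))
  invisible(x)
}

#' Least-squares slope of overlap fraction on accessibility class
#'
#' Optional utility refitting the linear trend of per-class overlap
#' fractions against the accessibility count, the kind of trend line from
#' which the default accessibility coefficient was calibrated.
#'
#' @param per_class Data.frame with `X` and `observed_fraction` (as
#'   returned in an `enrichment_result`).
#' @return Named numeric: `intercept` and `slope`.
#' @export
fit_accessibility_trend <- function(per_class) {
  fit <- stats::lm(observed_fraction ~ X, data = per_class)
  c(intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L]))
}
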