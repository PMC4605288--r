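#' Grid specification for weight training
#'
#' Value lists for the three segment scores. The historical default range
#' starts at 0 and ends at 20 with uniform spacing; ranges are extended on
#' the fly by [grid_search()] when the optimum sits on a boundary.
#'
#' @param s1_values,s2_values,s3_values Strictly increasing non-negative
#'   numeric vectors.
#' @param expansion_step Per-parameter spacing used when a range is
#'   extended; defaults to each parameter's initial grid spacing (or 5 for
#'   a single-point axis).
#' @param stop_drop Stop extending a parameter once the best objective on
#'   its outer boundary has dropped by at least this much below the best
#'   seen anywhere (default 10 correctly predicted sites).
#' @param top_n Number of top-ranked predictions scored against the gold
#'   set (default 1000).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(s1_values = seq(0, 20, by = 5),
                      s2_values = seq(0, 20, by = 5),
                      s3_values = seq(0, 20, by = 5),
                      expansion_step = NULL, stop_drop = 10,
                      top_n = 1000L) {
  vals <- list(s1 = s1_values, s2 = s2_values, s3 = s3_values)
  for (p in names(vals)) {
    v <- vals[[p]]
    if (!length(v) || any(v < 0) || is.unsorted(v, strictly = TRUE))
      stop("`", p, "_values` must be non-empty, non-negative, ",
           "strictly increasing")
  }
  default_step <- vapply(vals, function(v) {
    if (length(v) > 1L) v[2L] - v[1L] else 5
  }, numeric(1))
  step <- expansion_step %||% default_step
  if (length(step) == 1L) step <- rep(step, 3L)
  if (any(step <= 0)) stop("`expansion_step` must be positive")
  if (top_n <= 0L) stop("`top_n` must be positive")
  structure(list(values = vals, step = as.numeric(step),
                 stop_drop = stop_drop, top_n = as.integer(top_n)),
            class = "grid_spec")
}

# Interval table from a data.frame or BED path.
as_intervals <- function(x) {
  if (is.data.frame(x)) x else read_bed(x)
}

# TRUE for each site interval fully contained in >= 1 gold interval
# (bedtools intersect -f 1 semantics, fraction applied to the site).
contained_in_gold <- function(sites, gold) {
  gold <- as_intervals(gold)
  if (!nrow(sites)) return(logical(0))
  if (!nrow(gold)) return(rep(FALSE, nrow(sites)))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end))
  gold_gr <- GenomicRanges::GRanges(
    gold$chrom, IRanges::IRanges(gold$start + 1L, gold$end))
  suppressWarnings(IRanges::overlapsAny(site_gr, gold_gr, type = "within"))
}

# Precomputed machinery for rescoring a fixed candidate set under varying
# weights: coefficient matrix, accessibility counts, containment flags and
# tie-break keys. The candidate set itself is weight-independent.
objective_context <- function(candidates, gold, scheme = segment_scheme(),
                              track = NULL, top_n = 1000L,
                              aggregate = "max") {
  if (top_n <= 0L) stop("`top_n` must be positive")
  n <- nrow(candidates)
  list(
    n = n,
    A = if (n) candidate_coefficients(candidates, scheme) else
      matrix(0, 0, 3),
    X = site_cell_type_count(candidates, track, aggregate),
    contained = contained_in_gold(candidates, gold),
    tb_pam = PAM_PRIORITY[candidates$pam_class],
    tb_chrom = candidates$chrom,
    tb_start = candidates$start,
    tb_strand = match(candidates$strand, c("+", "-")),
    top_n = as.integer(top_n)
  )
}

objective_value <- function(ctx, s1, s2, s3, d = 0, coef = 0.0113) {
  if (!ctx$n) return(0L)
  sf <- as.numeric(ctx$A %*% c(s1, s2, s3)) + coef * ctx$X * d
  ord <- order(-sf, ctx$tb_pam, ctx$tb_chrom, ctx$tb_start, ctx$tb_strand)
  top <- ord[seq_len(min(ctx$top_n, ctx$n))]
  sum(ctx$contained[top])
}

#' Training objective: gold-set overlap of the top-N predictions
#'
#' Scores the (pre-enumerated, weight-independent) candidates under the
#' given weights, ranks them by final score, takes the top N, and counts
#' how many of those predicted sites are fully contained in some
#' gold-standard interval. The counting unit is the prediction: two
#' predictions inside one gold interval count twice.
#'
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param weights A [weight_set()].
#' @param gold Gold-standard intervals (data.frame or BED path).
#' @param top_n Number of top-ranked predictions to score (default 1000).
#' @param scheme A [segment_scheme()].
#' @param track Optional [build_bin_track()] accessibility track.
#' @return Integer count of gold-contained top-N predictions.
#' @export
objective_top_n_overlap <- function(candidates, weights, gold,
                                    top_n = 1000L,
                                    scheme = segment_scheme(),
                                    track = NULL) {
  stopifnot(inherits(weights, "weight_set"))
  ctx <- objective_context(candidates, gold, scheme, track, top_n)
  objective_value(ctx, weights$s1, weights$s2, weights$s3,
                  d = if (is.null(track)) 0 else weights$d,
                  coef = weights$dnase_coefficient)
}

#' Grid-search training of the segment weights
#'
#' Evaluates the top-N gold-overlap objective at every point of the
#' Cartesian product of the grid's `s1`/`s2`/`s3` values. Whenever the
#' best point sits on the current upper boundary of a parameter, that
#' parameter's range is extended by one step of uniform spacing and the
#' new points are evaluated, until the best objective on a parameter's
#' outer boundary has dropped by at least `stop_drop` below the best seen
#' (then that parameter stops extending). Ties are broken toward the
#' lexicographically smallest `(s1, s2, s3)`.
#'
#' @param candidates Candidate table (enumerated once; the search step is
#'   weight-independent).
#' @param gold Gold-standard intervals (data.frame or BED path).
#' @param grid A [grid_spec()].
#' @param base_weights [weight_set()] supplying mode, `d` and the
#'   accessibility coefficient (only used when `track` is given).
#' @param scheme A [segment_scheme()].
#' @param track Optional accessibility track included in the scoring.
#' @param max_rounds Safety cap on expansion rounds.
#' @return List of class `grid_search_result`: `best` (a [weight_set()]
#'   with the winning `s1`,`s2`,`s3`), `best_objective`, `table`
#'   (data.frame `s1`,`s2`,`s3`,`objective` over every point evaluated),
#'   `all_zero` (flag: every objective was zero, the returned optimum is
#'   just the tie-break minimum), `rounds`.
#' @export
grid_search <- function(candidates, gold, grid = grid_spec(),
                        base_weights = weight_set("binding"),
                        scheme = segment_scheme(), track = NULL,
                        max_rounds = 50L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(base_weights, "weight_set"))
  ctx <- objective_context(candidates, gold, scheme, track, grid$top_n)
  d <- if (is.null(track)) 0 else base_weights$d
  coef <- base_weights$dnase_coefficient

  values <- grid$values
  stopped <- c(s1 = FALSE, s2 = FALSE, s3 = FALSE)
  tab <- data.frame(s1 = numeric(0), s2 = numeric(0), s3 = numeric(0),
                    objective = numeric(0))
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    full <- expand.grid(s1 = values$s1, s2 = values$s2, s3 = values$s3,
                        KEEP.OUT.ATTRS = FALSE)
    new_pts <- full[!(paste(full$s1, full$s2, full$s3) %in%
                      paste(tab$s1, tab$s2, tab$s3)), , drop = FALSE]
    if (nrow(new_pts)) {
      new_pts$objective <- vapply(seq_len(nrow(new_pts)), function(j) {
        objective_value(ctx, new_pts$s1[j], new_pts$s2[j], new_pts$s3[j],
                        d = d, coef = coef)
      }, numeric(1))
      tab <- rbind(tab, new_pts)
    }
    best_obj <- max(tab$objective)
    cand <- tab[tab$objective == best_obj, , drop = FALSE]
    cand <- cand[order(cand$s1, cand$s2, cand$s3), , drop = FALSE]
    best_pt <- cand[1L, ]

    extended <- FALSE
    for (p in c("s1", "s2", "s3")) {
      if (stopped[[p]]) next
      frontier <- max(values[[p]])
      frontier_best <- max(tab$objective[tab[[p]] == frontier])
      if (best_obj - frontier_best >= grid$stop_drop) {
        stopped[[p]] <- TRUE
        next
      }
      # extend while a maximizer still sits on this parameter's boundary
      # (a zero objective carries no signal worth chasing)
      if (frontier_best == best_obj && best_obj > 0) {
        values[[p]] <- c(values[[p]],
                         frontier + grid$step[[match(p, c("s1", "s2", "s3"))]])
        extended <- TRUE
      }
    }
    if (!extended || rounds >= max_rounds) break
  }
  if (rounds >= max_rounds)
    warning("grid expansion stopped at max_rounds = ", max_rounds)

  all_zero <- best_obj == 0
  if (all_zero)
    warning("objective was zero everywhere; returning tie-break minimum")
  best <- weight_set(base_weights$mode_label,
                     s1 = best_pt$s1, s2 = best_pt$s2, s3 = best_pt$s3,
                     d = base_weights$d,
                     mismatch_limit = base_weights$mismatch_limit,
                     dnase_coefficient = coef)
  tab <- tab[order(tab$s1, tab$s2, tab$s3), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(best = best, best_objective = best_obj, table = tab,
                 all_zero = all_zero, rounds = rounds),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "grid_search_result: best (s1=%g, s2=%g, s3=%g), objective %g, %d points%s\n",
    x$best$s1, x$best$s2, x$best$s3, x$best_objective, nrow(x$table),
    if (x$all_zero) " [all-zero objective]" else ""))
  invisible(x)
}

#' Write a grid-search objective table as TSV
#'
#' @param result A [grid_search()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_objective_table <- function(result, path) {
  write.table(result$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' One-dimensional grid search over the chromatin weight
#'
#' With the segment weights held fixed, evaluates the same top-N
#' gold-overlap objective over candidate values of the chromatin weight
#' `d` and returns the best (smallest `d` on ties).
#'
#' @param candidates Candidate table.
#' @param gold Gold-standard intervals.
#' @param track Accessibility track (required; the objective is constant
#'   in `d` when the track is all-zero, in which case the smallest value
#'   is returned).
#' @param d_values Non-empty non-negative numeric vector of candidate
#'   weights.
#' @param base_weights [weight_set()] fixing `s1`,`s2`,`s3` and the
#'   coefficient.
#' @param scheme A [segment_scheme()].
#' @param top_n Top-N for the objective.
#' @return List with `best_d`, `best_objective` and `table`
#'   (data.frame `d`, `objective`).
#' @export
train_chromatin_weight <- function(candidates, gold, track, d_values,
                                   base_weights = weight_set("binding"),
                                   scheme = segment_scheme(),
                                   top_n = 1000L) {
  if (!length(d_values) || any(d_values < 0))
    stop("`d_values` must be non-empty and non-negative")
  d_values <- sort(unique(d_values))
  ctx <- objective_context(candidates, gold, scheme, track, top_n)
  obj <- vapply(d_values, function(d) {
    objective_value(ctx, base_weights$s1, base_weights$s2, base_weights$s3,
                    d = d, coef = base_weights$dnase_coefficient)
  }, numeric(1))
  best_idx <- which(obj == max(obj))[1L]  # values sorted: smallest d wins ties
  list(best_d = d_values[best_idx], best_objective = obj[best_idx],
       table = data.frame(d = d_values, objective = obj))
}
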