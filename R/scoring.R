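#' Segment weights and related scoring parameters
#'
#' A weight set holds the per-segment match score / mismatch penalty
#' magnitudes `s1`, `s2`, `s3`, the chromatin weight `d`, the mismatch
#' budget, and the coefficient of the accessibility score. Trained defaults
#' differ by mode: binding uses `s1 = 5, s2 = 70, s3 = 50, d = 20` with a
#' 9-mismatch budget; cleavage uses `s1 = 20, s2 = 60, s3 = 50, d = 10`
#' with a 6-mismatch budget.
#'
#' @param mode `"binding"` or `"cleavage"`; sets the defaults below.
#' @param s1,s2,s3 Non-negative segment scores (segment 1 PAM-distal under
#'   the default [segment_scheme()]).
#' @param d Non-negative chromatin weight.
#' @param mismatch_limit Mismatch budget for the search step.
#' @param dnase_coefficient Slope of the accessibility score in the
#'   cell-type count; 0.0113 per trend-line calibration on aggregate
#'   DNase I hypersensitivity data.
#' @return An object of class `weight_set`.
#' @examples
#' weight_set("binding")
#' weight_set("cleavage", s3 = 80)
#' @export
weight_set <- function(mode = c("binding", "cleavage"),
                       s1 = NULL, s2 = NULL, s3 = NULL, d = NULL,
                       mismatch_limit = NULL, dnase_coefficient = 0.0113) {
  mode <- match.arg(mode)
  def <- if (mode == "binding") {
    list(s1 = 5, s2 = 70, s3 = 50, d = 20, mismatch_limit = 9L)
  } else {
    list(s1 = 20, s2 = 60, s3 = 50, d = 10, mismatch_limit = 6L)
  }
  w <- list(
    s1 = s1 %||% def$s1, s2 = s2 %||% def$s2, s3 = s3 %||% def$s3,
    d = d %||% def$d,
    mismatch_limit = as.integer(mismatch_limit %||% def$mismatch_limit),
    dnase_coefficient = dnase_coefficient,
    mode_label = mode
  )
  if (any(unlist(w[c("s1", "s2", "s3", "d")]) < 0))
    stop("segment scores and chromatin weight must be non-negative")
  structure(w, class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf(
    "weight_set [%s]: s1=%g s2=%g s3=%g d=%g mm_limit=%d coef=%g\n",
    x$mode_label, x$s1, x$s2, x$s3, x$d, x$mismatch_limit,
    x$dnase_coefficient))
  invisible(x)
}

#' Segmentation of the 20-nt protospacer
#'
#' The protospacer is split into three segments scored with `s1`, `s2`,
#' `s3`. Default lengths are 5, 5, 10 with segment 1 at the PAM-distal end
#' (positions 1-5) and segment 3 PAM-proximal (positions 11-20). The
#' orientation switch reverses the assignment so that segment 1 becomes
#' PAM-proximal, for users who prefer the seed-first reading.
#'
#' @param lengths Three positive integers summing to 20.
#' @param orientation `"pam_distal_first"` (default) or
#'   `"pam_proximal_first"`.
#' @return An object of class `segment_scheme`.
#' @export
segment_scheme <- function(lengths = c(5L, 5L, 10L),
                           orientation = c("pam_distal_first",
                                           "pam_proximal_first")) {
  orientation <- match.arg(orientation)
  lengths <- as.integer(lengths)
  if (length(lengths) != 3L || any(lengths < 1L) || sum(lengths) != 20L)
    stop("segment lengths must be three positive integers summing to 20")
  structure(list(lengths = lengths, orientation = orientation),
            class = "segment_scheme")
}

# Segment index (1..3) of each protospacer position 1..20 (5'->3',
# position 20 adjacent to the PAM).
segment_of_position <- function(scheme) {
  idx <- rep.int(1:3, scheme$lengths)
  if (scheme$orientation == "pam_proximal_first") idx <- rev(idx)
  idx
}

as_mask <- function(mask) {
  if (is.character(mask) && length(mask) == 1L) {
    if (nchar(mask) != 20L) stop("mismatch mask must have length 20")
    mask <- strsplit(mask, "", fixed = TRUE)[[1L]] == "1"
  }
  mask <- as.logical(mask)
  if (length(mask) != 20L || anyNA(mask))
    stop("mismatch mask must be 20 logicals (or a 20-character 0/1 string)")
  mask
}

#' Classify mismatch positions as single or consecutive
#'
#' Partitions the 20 positions into matches, isolated (single) mismatches,
#' and members of maximal runs of two or more adjacent mismatches. Every
#' position inside such a run counts as a consecutive mismatch.
#'
#' @param mask 20 logicals (`TRUE` = mismatch) or a 20-character 0/1
#'   string, position 1 PAM-distal.
#' @return A list with `status` (per-position `"match"`,
#'   `"single_mismatch"` or `"consecutive_mismatch"`), `runs` (data.frame
#'   of maximal mismatch runs of length >= 2 with `start`, `end`,
#'   `length`), and the counts `n` (matches), `m` (consecutive mismatch
#'   positions), `k` (single mismatches); `n + m + k == 20`.
#' @examples
#' classify_mismatches("00110000000000000001")
#' @export
classify_mismatches <- function(mask) {
  mask <- as_mask(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  status <- character(20L)
  runs <- data.frame(start = integer(0), end = integer(0),
                     length = integer(0))
  for (j in seq_along(r$values)) {
    span <- starts[j]:ends[j]
    if (!r$values[j]) {
      status[span] <- "match"
    } else if (r$lengths[j] == 1L) {
      status[span] <- "single_mismatch"
    } else {
      status[span] <- "consecutive_mismatch"
      runs <- rbind(runs, data.frame(start = starts[j], end = ends[j],
                                     length = r$lengths[j]))
    }
  }
  list(status = status, runs = runs,
       n = sum(status == "match"),
       m = sum(status == "consecutive_mismatch"),
       k = sum(status == "single_mismatch"))
}

#' Per-segment linear coefficients of the base score
#'
#' The base score is linear in `(s1, s2, s3)`: each match at a position in
#' segment i contributes `+1` to coefficient i, each isolated mismatch
#' `-1/2`, and each position of a mismatch run of length >= 2 contributes
#' `-1/n_seg` to each of the `n_seg` distinct segments the run spans (the
#' run penalty is the mean of the spanned segments' scores). This
#' decomposition lets the optimizer rescore thousands of candidates per
#' grid point as a single matrix product.
#'
#' @param mask Mismatch mask as in [classify_mismatches()].
#' @param scheme A [segment_scheme()].
#' @return Numeric length-3 vector `a` with `S = sum(a * c(s1, s2, s3))`.
#' @export
score_coefficients <- function(mask, scheme = segment_scheme()) {
  mask <- as_mask(mask)
  seg <- segment_of_position(scheme)
  cls <- classify_mismatches(mask)
  a <- numeric(3L)
  for (i in 1:3) {
    a[i] <- a[i] + sum(cls$status == "match" & seg == i)
    a[i] <- a[i] - sum(cls$status == "single_mismatch" & seg == i) / 2
  }
  if (nrow(cls$runs)) {
    for (j in seq_len(nrow(cls$runs))) {
      spanned <- unique(seg[cls$runs$start[j]:cls$runs$end[j]])
      a[spanned] <- a[spanned] - cls$runs$length[j] / length(spanned)
    }
  }
  a
}

#' Three-segment base score of a mismatch mask
#'
#' Implements the segmented match/mismatch score: a match at a position in
#' segment i contributes `+s_i`; an isolated mismatch contributes
#' `-s_i / 2`; every position of a run of two or more adjacent mismatches
#' contributes `-s_i`, except that all positions of a run crossing a
#' segment boundary contribute the negative mean of the scores of the
#' segments the run spans. The all-match mask attains the maximum
#' `5*s1 + 5*s2 + 10*s3` (875 under binding defaults). Scores may go
#' negative; no floor is applied.
#'
#' @inheritParams score_coefficients
#' @param weights A [weight_set()].
#' @return The score S (numeric scalar).
#' @examples
#' base_score(rep(FALSE, 20), weight_set("binding"))  # 875
#' @export
base_score <- function(mask, weights = weight_set("binding"),
                       scheme = segment_scheme()) {
  stopifnot(inherits(weights, "weight_set"))
  a <- score_coefficients(mask, scheme)
  sum(a * c(weights$s1, weights$s2, weights$s3))
}

#' Score a set of candidate sites
#'
#' Order-preserving map of [base_score()] over the candidates' mismatch
#' masks. Chromatin columns are initialized neutral (`X = 0`, `S_d = 0`,
#' `S_f = S`); use [finalize_scores()] to add accessibility and rank.
#'
#' @param sites Candidate data.frame from [enumerate_candidates()].
#' @param weights A [weight_set()].
#' @param scheme A [segment_scheme()].
#' @return `sites` with columns `S`, `X`, `S_d`, `S_f` appended.
#' @export
score_candidates <- function(sites, weights = weight_set("binding"),
                             scheme = segment_scheme()) {
  stopifnot(is.data.frame(sites))
  if (!nrow(sites)) {
    out <- sites
    out$S <- numeric(0); out$X <- integer(0)
    out$S_d <- numeric(0); out$S_f <- numeric(0)
    return(out)
  }
  s_vec <- c(weights$s1, weights$s2, weights$s3)
  A <- candidate_coefficients(sites, scheme)
  sites$S <- as.numeric(A %*% s_vec)
  sites$X <- 0L
  sites$S_d <- 0
  sites$S_f <- sites$S
  sites
}

# n x 3 coefficient matrix for a candidate table; masks are deduplicated
# since at most 2^20 distinct masks exist and fixtures reuse few.
candidate_coefficients <- function(sites, scheme = segment_scheme()) {
  masks <- sites$mismatch_mask
  uniq <- unique(masks)
  Au <- t(vapply(uniq, score_coefficients, numeric(3L), scheme = scheme))
  Au[match(masks, uniq), , drop = FALSE]
}
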