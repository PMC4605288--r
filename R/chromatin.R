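#' Build a binned multi-cell-type accessibility track
#'
#' Tiles the genome into fixed-width bins and, for each bin, counts the
#' number of cell types (input peak files) with at least one open-chromatin
#' peak overlapping the bin by at least 1 bp. Each file contributes at most
#' once per bin, so `0 <= X <= n_cell_types` everywhere; bins with `X = 0`
#' are not stored.
#'
#' @param peak_files List of per-cell-type peak sets: BED file paths or
#'   data.frames with columns `chrom`, `start`, `end` (0-based half-open).
#' @param bin_width Bin width in bp (default 200, on the order of a DNase I
#'   hypersensitive site).
#' @return An object of class `dnase_bin_track`: list with `bin_width`,
#'   `n_cell_types` and `bins` (data.frame `chrom`, `bin`, `X`; bin `b`
#'   covers `[b*bin_width, (b+1)*bin_width)`).
#' @export
build_bin_track <- function(peak_files, bin_width = 200L) {
  if (length(peak_files) == 0L)
    stop("at least one peak file is required")
  bin_width <- as.integer(bin_width)
  if (bin_width < 1L) stop("`bin_width` must be positive")
  per_file <- lapply(seq_along(peak_files), function(fi) {
    pf <- peak_files[[fi]]
    peaks <- if (is.data.frame(pf)) pf else read_bed(pf)
    if (any(peaks$start >= peaks$end))
      stop("invalid interval (start >= end) in peak set ", fi)
    if (!nrow(peaks))
      return(data.frame(chrom = character(0), bin = integer(0)))
    covered <- lapply(seq_len(nrow(peaks)), function(j) {
      b0 <- peaks$start[j] %/% bin_width
      b1 <- (peaks$end[j] - 1L) %/% bin_width
      data.frame(chrom = peaks$chrom[j], bin = b0:b1)
    })
    unique(do.call(rbind, covered))  # one count per bin per cell type
  })
  all_bins <- do.call(rbind, per_file)
  if (is.null(all_bins) || !nrow(all_bins)) {
    bins <- data.frame(chrom = character(0), bin = integer(0), X = integer(0))
  } else {
    agg <- stats::aggregate(list(X = rep(1L, nrow(all_bins))),
                            by = all_bins[c("chrom", "bin")], FUN = sum)
    bins <- agg[order(agg$chrom, agg$bin), , drop = FALSE]
    rownames(bins) <- NULL
  }
  structure(list(bin_width = bin_width, n_cell_types = length(peak_files),
                 bins = bins),
            class = "dnase_bin_track")
}

#' @export
print.dnase_bin_track <- function(x, ...) {
  cat(sprintf(
    "dnase_bin_track: %d bp bins, %d cell types, %d non-zero bins\n",
    x$bin_width, x$n_cell_types, nrow(x$bins)))
  invisible(x)
}

#' Cell-type accessibility count at a site
#'
#' Looks up the accessibility count for each query interval: by default the
#' maximum `X` over all bins overlapping `[start, end)`; 0 when no stored
#' bin overlaps (including chromosomes absent from the track).
#'
#' @param sites Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param track A [build_bin_track()] result, or `NULL` for all zeros.
#' @param aggregate `"max"` (default) or `"mean"` over overlapped bins
#'   (mean counts non-stored overlapped bins as 0).
#' @return Integer (max) or numeric (mean) vector, one value per site.
#' @export
site_cell_type_count <- function(sites, track, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  n <- nrow(sites)
  if (is.null(track)) {
    return(if (aggregate == "max") integer(n) else numeric(n))
  }
  stopifnot(inherits(track, "dnase_bin_track"))
  bw <- track$bin_width
  key <- paste(track$bins$chrom, track$bins$bin)
  b0 <- sites$start %/% bw
  b1 <- (sites$end - 1L) %/% bw
  n_bins <- b1 - b0 + 1L
  # vectorized over sites, looping only over the (few) bins a site spans
  acc <- if (aggregate == "max") integer(n) else numeric(n)
  for (k in seq_len(max(n_bins)) - 1L) {
    live <- b0 + k <= b1
    x_k <- integer(n)
    hits <- match(paste(sites$chrom[live], b0[live] + k), key)
    x_k[live] <- ifelse(is.na(hits), 0L, track$bins$X[hits])
    acc <- if (aggregate == "max") pmax(acc, x_k) else acc + x_k
  }
  if (aggregate == "max") acc else acc / n_bins
}

#' Chromatin accessibility score
#'
#' `S_d = coefficient * X * d`, linear both in the number of cell types `X`
#' calling the site accessible and in the chromatin weight `d`.
#'
#' @param X Non-negative integer vector of cell-type counts.
#' @param weights A [weight_set()] supplying `d` and `dnase_coefficient`.
#' @return Numeric vector of chromatin scores.
#' @examples
#' dnase_score(125, weight_set("binding"))  # 0.0113 * 125 * 20 = 28.25
#' @export
dnase_score <- function(X, weights = weight_set("binding")) {
  stopifnot(inherits(weights, "weight_set"))
  if (any(X < 0)) stop("`X` must be non-negative")
  weights$dnase_coefficient * X * weights$d
}

#' Add chromatin scores and rank sites
#'
#' Computes `S_d` from the track (`S_d = 0` everywhere when `track` is
#' `NULL`, e.g. for non-human genomes without multi-cell-type DNase data),
#' sets the final score `S_f = S + S_d`, sorts descending by `S_f` with a
#' deterministic tie-break (PAM class priority GGG > NGG > NNG, then chrom,
#' start, strand) and assigns ranks 1..N.
#'
#' @param sites Scored sites from [score_candidates()] (column `S` filled).
#' @param track A [build_bin_track()] result or `NULL`.
#' @param weights A [weight_set()].
#' @param aggregate Bin aggregation rule, see [site_cell_type_count()].
#' @return The sites, ranked, with `X`, `S_d`, `S_f`, `rank` filled.
#' @export
finalize_scores <- function(sites, track = NULL,
                            weights = weight_set("binding"),
                            aggregate = "max") {
  stopifnot(is.data.frame(sites))
  if (!("S" %in% names(sites)))
    stop("`sites` must carry base scores; run score_candidates() first")
  sites$X <- site_cell_type_count(sites, track, aggregate)
  sites$S_d <- dnase_score(sites$X, weights)
  sites$S_f <- sites$S + sites$S_d
  ord <- order(-sites$S_f, PAM_PRIORITY[sites$pam_class],
               sites$chrom, sites$start, match(sites$strand, c("+", "-")))
  sites <- sites[ord, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites
}

#' Serialize a bin track to BedGraph
#'
#' One line per stored bin: chrom, bin start, bin end, X.
#'
#' @param track A [build_bin_track()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
track_to_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "dnase_bin_track"))
  b <- track$bins
  out <- data.frame(b$chrom, b$bin * track$bin_width,
                    (b$bin + 1L) * track$bin_width, b$X)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
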