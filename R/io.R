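#' Read a BED3+ file
#'
#' Reads the first three (plus optional name/score/strand) columns of a BED
#' file; extra columns are ignored. Coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return Data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(V1 = character(0), V2 = character(0),
                          V3 = character(0)))
      stop("failed to read BED file '", path, "': ", conditionMessage(e))
    })
  if (ncol(raw) < 3L)
    stop("BED file '", path, "' has fewer than 3 columns")
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed interval in '", path, "' at line ", bad[1L],
         ": non-numeric coordinates")
  out <- data.frame(chrom = raw[[1L]], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 4L) out$name <- raw[[4L]]
  if (ncol(raw) >= 5L) out$score <- suppressWarnings(as.numeric(raw[[5L]]))
  if (ncol(raw) >= 6L) out$strand <- raw[[6L]]
  out
}

#' Write intervals as BED
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 23-character display sequence: 20-nt site with mismatched positions in
# lower case, matches in upper case, followed by the 3-nt PAM.
display_seq <- function(site_seq, pam, mismatch_mask) {
  vapply(seq_along(site_seq), function(j) {
    chars <- strsplit(site_seq[j], "", fixed = TRUE)[[1L]]
    mm <- strsplit(mismatch_mask[j], "", fixed = TRUE)[[1L]] == "1"
    chars[mm] <- tolower(chars[mm])
    paste0(paste(chars, collapse = ""), pam[j])
  }, character(1))
}

PREDICTION_COLUMNS <- c("chrom", "start", "end", "strand", "sequence",
                        "pam", "n_mismatches", "S", "X", "S_d", "S_f",
                        "pam_class", "gene")

#' Write ranked predictions as a tab-delimited file
#'
#' One row per site, ranked order preserved. The `sequence` column shows
#' the 20-nt genomic protospacer with mismatched positions in lower case
#' followed by the PAM; scores are printed with 2 decimals. Output is
#' byte-identical for identical input. With `split_pam = TRUE`, one file
#' per PAM class is written next to `path` (suffixed `.GGG.tsv` etc.)
#' instead of a single merged file.
#'
#' @param records Ranked sites from [finalize_scores()], optionally passed
#'   through [annotate_genes()].
#' @param path Output path.
#' @param split_pam Write one file per PAM class?
#' @return The path(s) written, invisibly.
#' @export
write_predictions <- function(records, path, split_pam = FALSE) {
  needed <- c("chrom", "start", "end", "strand", "site_seq", "pam",
              "pam_class", "mismatch_mask", "n_mismatches",
              "S", "X", "S_d", "S_f")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  if (!("gene" %in% names(records)))
    records$gene <- rep("", nrow(records))
  out <- data.frame(
    chrom = records$chrom, start = records$start, end = records$end,
    strand = records$strand,
    sequence = if (nrow(records))
      display_seq(records$site_seq, records$pam, records$mismatch_mask)
      else character(0),
    pam = records$pam, n_mismatches = records$n_mismatches,
    S = sprintf("%.2f", records$S), X = records$X,
    S_d = sprintf("%.2f", records$S_d), S_f = sprintf("%.2f", records$S_f),
    pam_class = records$pam_class, gene = records$gene,
    stringsAsFactors = FALSE
  )
  if (split_pam) {
    base <- sub("\\.tsv$", "", path)
    paths <- character(0)
    for (cls in c("GGG", "NGG", "NNG")) {
      sub_out <- out[out$pam_class == cls, , drop = FALSE]
      if (!nrow(sub_out)) next
      p <- paste0(base, ".", cls, ".tsv")
      write.table(sub_out, p, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = TRUE)
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parse a prediction file back into a site table
#'
#' Inverse of [write_predictions()]: recovers the mismatch mask from the
#' lower-case positions of the display sequence and restores the
#' upper-case `site_seq`.
#'
#' @param path Prediction TSV path.
#' @return Data.frame in the layout produced by [finalize_scores()], with
#'   a `gene` column and rank restored from row order.
#' @export
read_predictions <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(S = "character", S_d = "character",
                                   S_f = "character", gene = "character"))
  proto <- substr(raw$sequence, 1L, 20L)
  mask <- vapply(proto, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(as.integer(chars %in% letters), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    chrom = as.character(raw$chrom), start = raw$start, end = raw$end,
    strand = raw$strand, site_seq = toupper(proto), pam = raw$pam,
    pam_class = raw$pam_class, mismatch_mask = mask,
    n_mismatches = raw$n_mismatches,
    S = as.numeric(raw$S), X = raw$X, S_d = as.numeric(raw$S_d),
    S_f = as.numeric(raw$S_f), gene = ifelse(is.na(raw$gene), "", raw$gene),
    rank = seq_len(nrow(raw)), stringsAsFactors = FALSE
  )
}

#' Annotate sites with overlapping gene names
#'
#' Fills the `gene` column with the name(s) of every gene interval
#' overlapping the site by at least 1 bp, comma-joined in coordinate
#' order; empty string when none (or when no annotation is supplied).
#'
#' @param records Site table with `chrom`, `start`, `end`.
#' @param genes Gene annotation: BED path or data.frame with `chrom`,
#'   `start`, `end`, `name`; `NULL` leaves all annotations empty.
#' @return `records` with a `gene` column.
#' @export
annotate_genes <- function(records, genes = NULL) {
  records$gene <- rep("", nrow(records))
  if (is.null(genes) || !nrow(records)) return(records)
  g <- if (is.data.frame(genes)) genes else read_bed(genes)
  if (!("name" %in% names(g)))
    stop("gene annotation needs a name column (BED column 4)")
  g <- g[order(g$chrom, g$start, g$end), , drop = FALSE]
  site_gr <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(records$start + 1L, records$end))
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, gene_gr))
  if (length(ov)) {
    hits <- split(g$name[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    idx <- as.integer(names(hits))
    records$gene[idx] <- vapply(hits, paste, character(1), collapse = ",")
  }
  records
}

#' Read scoring parameters from a key-value config file
#'
#' Plain-text `key = value` lines (one per line, `#` comments allowed).
#' Recognized keys: `mode`, `s1`, `s2`, `s3`, `d`, `mismatch_limit`,
#' `dnase_coefficient`, `bin_width`. Unspecified keys fall back to the
#' mode's trained defaults.
#'
#' @param path Config file path.
#' @return List with `weights` (a [weight_set()]) and `bin_width`.
#' @export
read_weight_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed config line: '", lines[bad[1L]], "'")
  vals <- setNames(vapply(kv, `[[`, character(1), 2L),
                   vapply(kv, `[[`, character(1), 1L))
  known <- c("mode", "s1", "s2", "s3", "d", "mismatch_limit",
             "dnase_coefficient", "bin_width")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  num <- function(key) if (key %in% names(vals)) as.numeric(vals[[key]]) else NULL
  mode <- if ("mode" %in% names(vals)) vals[["mode"]] else "binding"
  weights <- weight_set(mode, s1 = num("s1"), s2 = num("s2"),
                        s3 = num("s3"), d = num("d"),
                        mismatch_limit = num("mismatch_limit"),
                        dnase_coefficient = num("dnase_coefficient") %||% 0.0113)
  list(weights = weights, bin_width = as.integer(num("bin_width") %||% 200L))
}
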