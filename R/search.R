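#' Normalize a genome to a named character vector
#'
#' Accepts a path to a (multi-record, possibly line-wrapped) FASTA file, a
#' [Biostrings::DNAStringSet], or a named character vector. Sequences are
#' uppercased; record names are truncated at the first whitespace.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @return Named character vector of uppercase sequences.
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
             !grepl("^[ACGTNacgtn]+$", genome) && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    seqs <- as.character(ss)
  } else if (is.character(genome)) {
    seqs <- genome
    if (is.null(names(seqs)) && length(seqs))
      names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stop("unsupported genome input; use a FASTA path, DNAStringSet, ",
         "or named character vector")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}

empty_candidate_frame <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), site_seq = character(0), pam = character(0),
    pam_class = character(0), mismatch_mask = character(0),
    n_mismatches = integer(0), guide = character(0),
    stringsAsFactors = FALSE
  )
}

# Sliding Hamming-distance profile: mm[p] = mismatches of the 20-mer window
# starting at position p (1-based) against the 20 query codes. Non-ACGT
# genome bases (code 0) always mismatch.
window_mismatch_profile <- function(codes, qcodes) {
  n_win <- length(codes) - 20L + 1L
  if (n_win < 1L) return(integer(0))
  mm <- integer(n_win)
  for (i in seq_len(20L)) {
    mm <- mm + (codes[i:(i + n_win - 1L)] != qcodes[i])
  }
  mm
}

#' Enumerate candidate off-target sites
#'
#' Scans every 20-nt window on both strands of the genome and returns the
#' loci whose Hamming distance to the guide protospacer does not exceed the
#' mismatch budget and whose adjacent 3' trinucleotide classifies to an
#' admitted PAM class. Minus-strand windows are compared after
#' reverse-complementation, so `site_seq` always reads 5'->3' facing the
#' guide with position 20 adjacent to the PAM. Windows whose PAM would run
#' off the chromosome end are skipped; non-ACGT bases count as mismatches
#' and never satisfy a PAM G.
#'
#' @param genome Anything accepted by [as_genome()].
#' @param query A [guide_query()].
#' @param policy A [pam_policy()]; the default searches GGG/NGG only.
#' @param budget Mismatch budget; defaults to the mode's budget
#'   (9 binding, 6 cleavage).
#' @return A `data.frame` with one row per candidate, sorted by
#'   (chrom, start, strand): columns `chrom`, `start`, `end` (0-based
#'   half-open, covering the 20-nt protospacer only; the PAM lies at
#'   `[end, end+3)` on + and `[start-3, start)` on -), `strand`,
#'   `site_seq`, `pam`, `pam_class`, `mismatch_mask` (20-character string
#'   of 0/1, position 1 PAM-distal), `n_mismatches`, `guide`.
#' @examples
#' g <- c(chr1 = "ACGTACGTACGTACGTACGTAGGACGT")
#' q <- guide_query("ACGTACGTACGTACGTACGT", "cleavage")
#' enumerate_candidates(g, q)
#' @export
enumerate_candidates <- function(genome, query, policy = pam_policy(),
                                 budget = NULL) {
  stopifnot(inherits(query, "guide_query"), inherits(policy, "pam_policy"))
  genome <- as_genome(genome)
  budget <- as.integer(budget %||% mismatch_budget(query$mode))
  if (budget < 0L) stop("`budget` must be non-negative")
  admitted <- admitted_classes(policy)

  q <- encode_dna(query$protospacer)
  qr <- rev(comp_codes(q))  # revcomp of the guide, as codes

  per_chrom <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    if (L < 23L) return(empty_candidate_frame())
    codes <- encode_dna(seq)

    rows <- list()

    # plus strand: windows at p = 1..L-22 (PAM needs 3 nt after the window)
    mm_plus <- window_mismatch_profile(codes, q)
    p_plus <- which(mm_plus <= budget)
    p_plus <- p_plus[p_plus <= L - 22L]
    if (length(p_plus)) {
      pam <- substr(rep(seq, length(p_plus)), p_plus + 20L, p_plus + 22L)
      cls <- classify_pam(pam)
      keep <- !is.na(cls) & cls %in% admitted
      p_keep <- p_plus[keep]
      if (length(p_keep)) {
        mask <- vapply(p_keep, function(p) {
          paste(as.integer(codes[p:(p + 19L)] != q), collapse = "")
        }, character(1))
        rows$plus <- data.frame(
          chrom = chrom, start = p_keep - 1L, end = p_keep + 19L,
          strand = "+",
          site_seq = substr(rep(seq, length(p_keep)), p_keep, p_keep + 19L),
          pam = pam[keep], pam_class = cls[keep],
          mismatch_mask = mask, n_mismatches = mm_plus[p_keep],
          guide = query$label, stringsAsFactors = FALSE
        )
      }
    }

    # minus strand: window [p, p+19] read as revcomp; PAM at [p-3, p-1]
    mm_minus <- window_mismatch_profile(codes, qr)
    p_minus <- which(mm_minus <= budget)
    p_minus <- p_minus[p_minus >= 4L]
    if (length(p_minus)) {
      pam_fwd <- substr(rep(seq, length(p_minus)), p_minus - 3L, p_minus - 1L)
      pam <- vapply(pam_fwd, revcomp, character(1), USE.NAMES = FALSE)
      cls <- classify_pam(pam)
      keep <- !is.na(cls) & cls %in% admitted
      p_keep <- p_minus[keep]
      if (length(p_keep)) {
        # window mismatches vs revcomp(guide) map to guide positions reversed
        mask <- vapply(p_keep, function(p) {
          paste(rev(as.integer(codes[p:(p + 19L)] != qr)), collapse = "")
        }, character(1))
        site <- vapply(p_keep, function(p) {
          revcomp(substr(seq, p, p + 19L))
        }, character(1))
        rows$minus <- data.frame(
          chrom = chrom, start = p_keep - 1L, end = p_keep + 19L,
          strand = "-",
          site_seq = site, pam = pam[keep], pam_class = cls[keep],
          mismatch_mask = mask, n_mismatches = mm_minus[p_keep],
          guide = query$label, stringsAsFactors = FALSE
        )
      }
    }
    if (!length(rows)) return(empty_candidate_frame())
    do.call(rbind, unname(rows))
  })

  out <- do.call(rbind, per_chrom)
  if (is.null(out) || !nrow(out)) return(empty_candidate_frame())
  ord <- order(out$chrom, out$start, match(out$strand, c("+", "-")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert candidate (or scored) sites to a GRanges
#'
#' @param sites A candidate data.frame from [enumerate_candidates()].
#' @return A [GenomicRanges::GRanges] with the extra columns as metadata.
#' @export
sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand,
    sites[, setdiff(names(sites), c("chrom", "start", "end", "strand")),
          drop = FALSE]
  )
}

#' Write candidate sites as BED6
#'
#' Name column is the guide label, score column the mismatch count.
#'
#' @param sites Candidate data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$start, sites$end,
                    sites$guide, sites$n_mismatches, sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
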