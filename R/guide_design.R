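#' Find candidate protospacers in a short region
#'
#' Scans a user-supplied region (23-250 nt) on both strands for every
#' 20-mer whose adjacent 3' trinucleotide classifies as GGG or NGG — i.e.
#' every position Cas9 could be targeted to within the region.
#'
#' @param region Sequence string (A/C/G/T/N) or path to a single-record
#'   FASTA file, at most 250 nt.
#' @return Data.frame sorted by (position, strand): `position` (0-based
#'   start of the protospacer in the region, + strand coordinates),
#'   `strand`, `protospacer` (20-mer, 5'->3' on its strand), `pam`.
#'   Regions shorter than 23 nt yield zero rows.
#' @examples
#' find_protospacers("GACGCATAAAGATGAGACGCTGG")
#' @export
find_protospacers <- function(region) {
  if (length(region) != 1L || !is.character(region))
    stop("`region` must be a single string or FASTA path")
  if (!grepl("^[ACGTNacgtn]+$", region) && file.exists(region)) {
    ss <- Biostrings::readDNAStringSet(region)
    if (length(ss) != 1L) stop("region FASTA must contain one record")
    region <- as.character(ss[[1L]])
  }
  region <- toupper(region)
  if (grepl("[^ACGTN]", region))
    stop("region must contain only A, C, G, T, N")
  L <- nchar(region)
  if (L > 250L) stop("region longer than 250 nt (got ", L, ")")
  empty <- data.frame(position = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      stringsAsFactors = FALSE)
  if (L < 23L) return(empty)

  rows <- list()
  # plus strand: protospacer [p, p+19], PAM [p+20, p+22] (1-based)
  for (p in 1:(L - 22L)) {
    pam <- substr(region, p + 20L, p + 22L)
    cls <- classify_pam(pam)
    if (!is.na(cls) && cls %in% c("GGG", "NGG")) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = p - 1L, strand = "+",
        protospacer = substr(region, p, p + 19L), pam = pam,
        stringsAsFactors = FALSE)
    }
  }
  # minus strand: protospacer = revcomp of [p, p+19], PAM = revcomp [p-3, p-1]
  for (p in 4:(L - 19L)) {
    pam <- revcomp(substr(region, p - 3L, p - 1L))
    cls <- classify_pam(pam)
    if (!is.na(cls) && cls %in% c("GGG", "NGG")) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = p - 1L, strand = "-",
        protospacer = revcomp(substr(region, p, p + 19L)), pam = pam,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$position, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate guides by predicted off-target burden
#'
#' For each guide, enumerates all candidate sites in the genome, scores
#' and ranks them, identifies the on-target locus as the best-scoring
#' perfect (0-mismatch) hit, and sums the final scores of everything else
#' as the guide's off-target burden. Guides are ranked ascending by
#' burden, so the top guide is the most specific choice. A guide with
#' multiple perfect hits is non-unique: the extra perfect hits count
#' toward its burden. A guide with no perfect hit is flagged and ranked by
#' the burden over all its hits.
#'
#' @param guides Character vector of 20-nt protospacers, or the output of
#'   [find_protospacers()].
#' @param genome Anything accepted by [as_genome()].
#' @param weights A [weight_set()]; the default uses the cleavage weights,
#'   the genome-editing use case for guide design.
#' @param scheme A [segment_scheme()].
#' @param track Optional accessibility track.
#' @param policy A [pam_policy()].
#' @param top_k Off-target sites to report per guide (default 5).
#' @return List of class `guide_report`: `guides` (data.frame with
#'   `guide`, `label`, `burden`, `n_offtargets`, `on_target_found`,
#'   `rank`) and `offtargets` (named list of per-guide top-`top_k`
#'   off-target site tables).
#' @export
rank_guides <- function(guides, genome, weights = weight_set("cleavage"),
                        scheme = segment_scheme(), track = NULL,
                        policy = pam_policy(), top_k = 5L) {
  if (is.data.frame(guides)) guides <- guides$protospacer
  if (!length(guides)) stop("no guides supplied")
  genome <- as_genome(genome)
  labels <- if (!is.null(names(guides))) names(guides) else
    paste0("guide", seq_along(guides))

  per_guide <- lapply(seq_along(guides), function(j) {
    q <- guide_query(guides[j], weights$mode_label, label = labels[j])
    cand <- enumerate_candidates(genome, q, policy,
                                 budget = weights$mismatch_limit)
    ranked <- finalize_scores(score_candidates(cand, weights, scheme),
                              track, weights)
    perfect <- which(ranked$n_mismatches == 0L)
    on_target_found <- length(perfect) > 0L
    # on-target = best-ranked perfect hit; all other hits are burden
    off <- if (on_target_found)
      ranked[-perfect[1L], , drop = FALSE] else ranked
    list(label = labels[j], guide = guides[j],
         burden = if (nrow(off)) sum(off$S_f) else 0,
         n_offtargets = nrow(off),
         on_target_found = on_target_found,
         offtargets = head(off, top_k))
  })

  tab <- data.frame(
    guide = vapply(per_guide, `[[`, character(1), "guide"),
    label = vapply(per_guide, `[[`, character(1), "label"),
    burden = vapply(per_guide, `[[`, numeric(1), "burden"),
    n_offtargets = vapply(per_guide, `[[`, integer(1), "n_offtargets"),
    on_target_found = vapply(per_guide, `[[`, logical(1), "on_target_found"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$burden, tab$guide)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  offtargets <- lapply(per_guide[ord], `[[`, "offtargets")
  names(offtargets) <- tab$label
  structure(list(guides = tab, offtargets = offtargets),
            class = "guide_report")
}

#' @export
print.guide_report <- function(x, ...) {
  cat("guide_report:", nrow(x$guides), "guides ranked by off-target burden\n")
  print(x$guides)
  invisible(x)
}

#' Write a guide design report as TSV
#'
#' @param report A [rank_guides()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_report <- function(report, path) {
  write.table(report$guides, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
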