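# Run code with a temporarily fixed RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Describe a planted off-target site
#'
#' One entry of a [synthetic_spec()]'s `planted` list: where mismatches go
#' (explicit positions control the run structure; left `NULL` they are
#' drawn at random), the PAM written next to the site, the strand, whether
#' the site joins the gold-standard set, and the fraction of simulated
#' cell types whose DNase peak set covers the site.
#'
#' @param n_mismatches Number of mismatched positions (0-20).
#' @param positions Optional integer vector of mismatch positions (1-20,
#'   position 1 PAM-distal); length must equal `n_mismatches`.
#' @param pam 3-nt PAM trinucleotide written 3' of the site.
#' @param strand `"+"` or `"-"`.
#' @param gold Include this site's (padded) interval in the gold set?
#' @param accessibility Fraction in `[0, 1]` of cell types given a peak
#'   over the site.
#' @return A list of class `planted_site`.
#' @export
planted_site <- function(n_mismatches = 0L, positions = NULL, pam = "AGG",
                         strand = "+", gold = TRUE, accessibility = 0) {
  n_mismatches <- as.integer(n_mismatches)
  stopifnot(n_mismatches >= 0L, n_mismatches <= 20L,
            nchar(pam) == 3L, strand %in% c("+", "-"),
            accessibility >= 0, accessibility <= 1)
  if (!is.null(positions)) {
    positions <- sort(as.integer(positions))
    if (length(positions) != n_mismatches ||
        any(positions < 1L | positions > 20L) || anyDuplicated(positions))
      stop("`positions` must be n_mismatches distinct values in 1..20")
  }
  structure(list(n_mismatches = n_mismatches, positions = positions,
                 pam = toupper(pam), strand = strand, gold = gold,
                 accessibility = accessibility),
            class = "planted_site")
}

#' Specification of a synthetic study fixture
#'
#' A pure, seeded description of a test world: a random background genome,
#' a guide, a set of planted off-target sites with known mismatch
#' structure, per-cell-type DNase peak tracks, and a gold-standard subset.
#' [generate_fixture()] realizes it deterministically: identical specs
#' give identical bytes.
#'
#' @param seed Integer seed; the fixture is a pure function of the spec.
#' @param guide 20-nt protospacer, or `NULL` to draw one at random.
#' @param genome_length Length of each chromosome (bp).
#' @param n_chrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param gc GC fraction of the background (default 0.41, human-like).
#' @param planted List of [planted_site()] entries, all placed on
#'   chromosome 1 in non-overlapping blocks.
#' @param budget Mismatch budget used for the manifest's expected
#'   candidate set.
#' @param admit_nng PAM policy for the expected candidate set.
#' @param gold_pad Padding (bp) added on each side of a planted gold
#'   site's interval in the gold BED, so that predictions are strictly
#'   contained.
#' @param n_cell_types Number of simulated DNase cell-type tracks.
#' @param peaks_per_type Background peaks per cell type.
#' @param peak_width Peak width (bp).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, guide = NULL, genome_length = 4000L,
                           n_chrom = 1L, gc = 0.41,
                           planted = list(planted_site(0L)),
                           budget = 9L, admit_nng = FALSE, gold_pad = 10L,
                           n_cell_types = 0L, peaks_per_type = 20L,
                           peak_width = 400L) {
  stopifnot(genome_length >= 200L, n_chrom >= 1L, gc > 0, gc < 1,
            budget >= 0L, gold_pad >= 0L, n_cell_types >= 0L)
  if (!is.null(guide)) {
    guide <- toupper(guide)
    stopifnot(nchar(guide) == 20L, !grepl("[^ACGT]", guide))
  }
  if (!all(vapply(planted, inherits, logical(1), "planted_site")))
    stop("`planted` must be a list of planted_site() entries")
  block <- genome_length %/% max(length(planted), 1L)
  if (length(planted) && block < 60L)
    stop("spec infeasible: too many planted sites for genome length")
  structure(list(seed = as.integer(seed), guide = guide,
                 genome_length = as.integer(genome_length),
                 n_chrom = as.integer(n_chrom), gc = gc, planted = planted,
                 budget = as.integer(budget), admit_nng = admit_nng,
                 gold_pad = as.integer(gold_pad),
                 n_cell_types = as.integer(n_cell_types),
                 peaks_per_type = as.integer(peaks_per_type),
                 peak_width = as.integer(peak_width)),
            class = "synthetic_spec")
}

# Mutate the guide at the given positions (each to a random different base).
mutate_guide <- function(guide, positions) {
  chars <- strsplit(guide, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Realize a synthetic fixture
#'
#' Draws the background genome, plants each specified site (guide mutated
#' at its mismatch positions, PAM written 3' of it, reverse-complemented
#' for minus-strand sites), builds the per-cell-type peak sets and the
#' gold BED, and assembles a ground-truth manifest. The realized genome is
#' verified by a full candidate scan: if the random background (or a
#' planted decoy) produces any hit not in the manifest — or perturbs a
#' planted one — the background is redrawn, so the manifest's expected
#' candidate set is exact. Generation is deterministic in the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory: when given, writes `genome.fa`,
#'   `guide.txt`, `gold.bed`, `manifest.tsv` and `dnase/cell_NN.bed`.
#' @param max_tries Background redraws allowed before giving up.
#' @return A list of class `synthetic_fixture`: `genome` (named character
#'   vector), `guide`, `planted` (ground-truth table with coordinates,
#'   mismatch masks, gold and accessibility flags), `expected_candidates`
#'   (the exact candidate table [enumerate_candidates()] must return at
#'   the spec's budget and policy), `gold` (padded intervals data.frame),
#'   `peaks` (list of per-cell-type peak data.frames), `genome_sizes`,
#'   `spec`, and the paths written (when `dir` is given).
#' @export
generate_fixture <- function(spec, dir = NULL, max_tries = 50L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    policy <- pam_policy(admit_nng = spec$admit_nng)
    n_pl <- length(spec$planted)

    # draw guide, layout and background together until the scan agrees
    # exactly with the manifest (a guide that nearly matches itself at a
    # shift can make every planted site spawn an offset hit, so the guide
    # must be redrawn along with the background)
    genome <- NULL
    for (try in seq_len(max_tries)) {
      guide <- spec$guide %||% random_dna(20L, 0.5)
      query <- guide_query(guide, "binding", label = "synthetic")

      planted_tab <- NULL
      if (n_pl) {
        block <- spec$genome_length %/% n_pl
        rows <- lapply(seq_len(n_pl), function(j) {
          ps <- spec$planted[[j]]
          pos <- ps$positions %||%
            sort(sample.int(20L, ps$n_mismatches))
          site_seq <- mutate_guide(guide, pos)
          mask <- paste(as.integer(seq_len(20L) %in% pos), collapse = "")
          lo <- (j - 1L) * block + 10L         # leave room for a - strand PAM
          hi <- j * block - 33L
          start <- lo + sample.int(hi - lo, 1L)  # 0-based protospacer start
          data.frame(chrom = "chr1", start = start, end = start + 20L,
                     strand = ps$strand, site_seq = site_seq, pam = ps$pam,
                     pam_class = classify_pam(ps$pam),
                     mismatch_mask = mask, n_mismatches = ps$n_mismatches,
                     gold = ps$gold, accessibility = ps$accessibility,
                     stringsAsFactors = FALSE)
        })
        planted_tab <- do.call(rbind, rows)
      }

      expected <- if (is.null(planted_tab)) empty_candidate_frame() else {
        keep <- planted_tab$n_mismatches <= spec$budget &
          planted_tab$pam_class %in% admitted_classes(policy) &
          !is.na(planted_tab$pam_class)
        exp_tab <- planted_tab[keep,
          c("chrom", "start", "end", "strand", "site_seq", "pam",
            "pam_class", "mismatch_mask", "n_mismatches"), drop = FALSE]
        exp_tab$guide <- rep("synthetic", nrow(exp_tab))
        exp_tab <- exp_tab[order(exp_tab$chrom, exp_tab$start,
                                 match(exp_tab$strand, c("+", "-"))), ,
                           drop = FALSE]
        rownames(exp_tab) <- NULL
        exp_tab
      }

      chroms <- vapply(seq_len(spec$n_chrom), function(i) {
        random_dna(spec$genome_length, spec$gc)
      }, character(1))
      names(chroms) <- paste0("chr", seq_len(spec$n_chrom))
      if (!is.null(planted_tab)) {
        for (j in seq_len(nrow(planted_tab))) {
          r <- planted_tab[j, ]
          cassette <- paste0(r$site_seq, r$pam)
          if (r$strand == "+") {
            substr(chroms[["chr1"]], r$start + 1L, r$start + 23L) <- cassette
          } else {
            substr(chroms[["chr1"]], r$start - 2L, r$start + 20L) <-
              revcomp(cassette)
          }
        }
      }
      got <- enumerate_candidates(chroms, query, policy,
                                  budget = spec$budget)
      if (identical(got[, names(expected)], expected)) {
        genome <- chroms
        break
      }
    }
    if (is.null(genome))
      stop("could not realize a collision-free background in ",
           max_tries, " tries")

    gold <- if (is.null(planted_tab)) {
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    } else {
      g <- planted_tab[planted_tab$gold, , drop = FALSE]
      data.frame(chrom = g$chrom,
                 start = pmax(0L, g$start - spec$gold_pad),
                 end = pmin(spec$genome_length, g$end + spec$gold_pad))
    }

    # per-cell-type peak tracks: background peaks plus planted coverage
    peaks <- NULL
    if (spec$n_cell_types > 0L) {
      sizes <- setNames(rep(spec$genome_length, spec$n_chrom),
                        names(genome))
      peaks <- lapply(seq_len(spec$n_cell_types), function(ct) {
        bg <- place_random_regions(
          rep(spec$peak_width, spec$peaks_per_type), sizes)
        if (!is.null(planted_tab)) {
          covered <- which(ceiling(planted_tab$accessibility *
                                     spec$n_cell_types) >= ct)
          if (length(covered)) {
            extra <- planted_tab[covered, , drop = FALSE]
            bg <- rbind(bg, data.frame(
              chrom = extra$chrom,
              start = pmax(0L, extra$start - 5L),
              end = extra$end + 5L))
          }
        }
        bg[order(bg$chrom, bg$start), , drop = FALSE]
      })
      names(peaks) <- sprintf("cell_%02d", seq_len(spec$n_cell_types))
    }

    fixture <- structure(list(
      genome = genome, guide = guide, planted = planted_tab,
      expected_candidates = expected, gold = gold, peaks = peaks,
      genome_sizes = setNames(rep(spec$genome_length, spec$n_chrom),
                              names(genome)),
      spec = spec, paths = NULL
    ), class = "synthetic_fixture")

    if (!is.null(dir)) fixture$paths <- write_fixture(fixture, dir)
    fixture
  })
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat(sprintf(
    "synthetic_fixture: %d chrom x %d bp, guide %s, %d planted sites, %d cell types\n",
    length(x$genome), x$spec$genome_length, x$guide,
    if (is.null(x$planted)) 0L else nrow(x$planted),
    x$spec$n_cell_types))
  invisible(x)
}

# Serialize a fixture to plain-text files; returns the paths written.
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$genome), paths$genome)
  paths$guide <- file.path(dir, "guide.txt")
  writeLines(fixture$guide, paths$guide)
  paths$gold <- file.path(dir, "gold.bed")
  write_bed(fixture$gold, paths$gold)
  paths$manifest <- file.path(dir, "manifest.tsv")
  manifest <- fixture$planted %||%
    data.frame(chrom = character(0), start = integer(0))
  write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  if (!is.null(fixture$peaks)) {
    pk_dir <- file.path(dir, "dnase")
    dir.create(pk_dir, showWarnings = FALSE)
    paths$peaks <- vapply(names(fixture$peaks), function(nm) {
      p <- file.path(pk_dir, paste0(nm, ".bed"))
      write_bed(fixture$peaks[[nm]], p)
      p
    }, character(1))
  }
  paths
}
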