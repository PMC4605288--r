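# Independent oracles, written deliberately apart from the package
# implementation: string-based naive sliding-window scan, per-position
# score evaluator with neighbor walking, and small fixture builders.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
        collapse = "")
}

oracle_pam_class <- function(tri) {
  b <- strsplit(tri, "")[[1L]]
  if (b[3L] != "G") return(NA_character_)
  if (b[2L] != "G") return("NNG")
  if (b[1L] != "G") return("NGG")
  "GGG"
}

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  sum(ca != cb | !(ca %in% c("A", "C", "G", "T")))
}

# Naive scan: slide a window over every position of both strands, count
# mismatches per window, check the PAM by hand.
oracle_scan <- function(genome, guide, budget, admit_nng = FALSE) {
  admitted <- if (admit_nng) c("GGG", "NGG", "NNG") else c("GGG", "NGG")
  rows <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    if (L < 23L) next
    for (p in 1:(L - 19L)) {
      win <- substr(seq, p, p + 19L)
      # plus strand
      if (p + 22L <= L) {
        mm <- oracle_hamming(win, guide)
        if (mm <= budget) {
          cls <- oracle_pam_class(substr(seq, p + 20L, p + 22L))
          if (!is.na(cls) && cls %in% admitted) {
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom, start = p - 1L, end = p + 19L, strand = "+",
              site_seq = win, n_mismatches = mm, pam_class = cls,
              stringsAsFactors = FALSE)
          }
        }
      }
      # minus strand
      if (p >= 4L) {
        site <- oracle_revcomp(win)
        mm <- oracle_hamming(site, guide)
        if (mm <= budget) {
          cls <- oracle_pam_class(oracle_revcomp(substr(seq, p - 3L, p - 1L)))
          if (!is.na(cls) && cls %in% admitted) {
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom, start = p - 1L, end = p + 19L, strand = "-",
              site_seq = site, n_mismatches = mm, pam_class = cls,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_seq = character(0), n_mismatches = integer(0),
                      pam_class = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

# Per-position evaluator of the segmented score: walks left/right to find
# the run a mismatch belongs to, then applies the single/run/mean rule.
oracle_base_score <- function(mask, s, lengths = c(5L, 5L, 10L),
                              proximal_first = FALSE) {
  seg <- rep(1:3, lengths)
  if (proximal_first) seg <- rev(seg)
  total <- 0
  for (i in 1:20) {
    if (!mask[i]) {
      total <- total + s[seg[i]]
      next
    }
    left <- i > 1L && mask[i - 1L]
    right <- i < 20L && mask[i + 1L]
    if (!left && !right) {
      total <- total - s[seg[i]] / 2
      next
    }
    a <- i; while (a > 1L && mask[a - 1L]) a <- a - 1L
    b <- i; while (b < 20L && mask[b + 1L]) b <- b + 1L
    total <- total - mean(s[unique(seg[a:b])])
  }
  total
}

random_genome <- function(n, chroms = 1L, prefix = "chr") {
  out <- vapply(seq_len(chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  names(out) <- paste0(prefix, seq_len(chroms))
  out
}

random_mask <- function(p = 0.25) {
  runif(20) < p
}

mask_to_string <- function(mask) paste(as.integer(mask), collapse = "")

# --- weight-recovery fixture ------------------------------------------------
# Candidate table (no genome needed: the objective only reads coordinates,
# masks and PAM class) built so the top-N overlap objective is uniquely
# maximized at (s1, s2, s3) = (5, 70, 50) on the 5x5x5 grid
# {0,5,10,15,20} x {50,...,90} x {30,...,70}. Gold sites all carry one
# mask; three decoy mask types were chosen (by set cover over the score's
# per-segment coefficient vectors) so that at (5,70,50) every decoy scores
# strictly below the gold mask, while at every other grid point at least
# one decoy type scores strictly above it.
RECOVERY_GOLD_MASK <- "10000000111000000000"   # coefficients (3.5, 1.5, 7.5)
RECOVERY_DECOY_MASKS <- c(
  "00000100001101000000",  # coefficients (5.0,  3.5,  4.5)
  "00000110100000000000",  # coefficients (5.0, -0.5, 10.0)
  "11001111000000000000"   # coefficients (-2.0, 0.0, 10.0)
)
RECOVERY_GRID <- grid_spec(s1_values = c(0, 5, 10, 15, 20),
                           s2_values = c(50, 60, 70, 80, 90),
                           s3_values = c(30, 40, 50, 60, 70),
                           top_n = 8L)

recovery_fixture <- function(n_gold = 8L, n_per_decoy = 4L) {
  mk <- function(masks, start0, gold_flag) {
    n <- length(masks)
    data.frame(
      chrom = "chr1",
      start = start0 + (seq_len(n) - 1L) * 100L,
      end = start0 + (seq_len(n) - 1L) * 100L + 20L,
      strand = "+",
      site_seq = strrep("A", 20L), pam = "AGG", pam_class = "NGG",
      mismatch_mask = masks,
      n_mismatches = vapply(masks, function(m)
        sum(strsplit(m, "")[[1L]] == "1"), integer(1), USE.NAMES = FALSE),
      guide = "recovery", stringsAsFactors = FALSE)
  }
  gold_sites <- mk(rep(RECOVERY_GOLD_MASK, n_gold), 1000L, TRUE)
  decoy_sites <- mk(rep(RECOVERY_DECOY_MASKS, each = n_per_decoy),
                    100000L, FALSE)
  candidates <- rbind(gold_sites, decoy_sites)
  gold <- data.frame(chrom = "chr1",
                     start = gold_sites$start - 10L,
                     end = gold_sites$end + 10L)
  list(candidates = candidates, gold = gold, n_gold = n_gold)
}
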