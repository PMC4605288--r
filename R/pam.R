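#' Classify a PAM trinucleotide
#'
#' Assigns the 3-nt motif immediately 3' of a protospacer to one of three
#' admissible classes, in decreasing order of preference: `GGG` (literal
#' GGG), `NGG` (positions 2-3 are GG, position 1 is not G), `NNG`
#' (position 3 is G, position 2 is not G). Anything else, including an N at
#' a position the pattern requires to be G, is inadmissible.
#'
#' @param trinucleotide Character vector of 3-character strings (uppercase
#'   A/C/G/T/N).
#' @return Character vector with elements `"GGG"`, `"NGG"`, `"NNG"` or
#'   `NA_character_` (inadmissible).
#' @examples
#' classify_pam(c("GGG", "AGG", "ATG", "ACT"))
#' @export
classify_pam <- function(trinucleotide) {
  if (!is.character(trinucleotide))
    stop("`trinucleotide` must be character")
  if (any(nchar(trinucleotide) != 3L))
    stop("PAM trinucleotides must have length 3")
  if (any(grepl("[^ACGTN]", trinucleotide)))
    stop("PAM trinucleotides must contain only A, C, G, T, N")
  b1 <- substr(trinucleotide, 1L, 1L)
  b2 <- substr(trinucleotide, 2L, 2L)
  b3 <- substr(trinucleotide, 3L, 3L)
  out <- rep(NA_character_, length(trinucleotide))
  out[b3 == "G" & b2 != "G"] <- "NNG"
  out[b3 == "G" & b2 == "G" & b1 != "G"] <- "NGG"
  out[b3 == "G" & b2 == "G" & b1 == "G"] <- "GGG"
  out
}

# PAM class priority for tie-breaking: smaller is preferred.
PAM_PRIORITY <- c(GGG = 1L, NGG = 2L, NNG = 3L)

#' PAM admission policy
#'
#' The canonical S. pyogenes Cas9 PAM is NGG (with GGG its preferred
#' sub-class), which is always searched. Sites with the weaker NNG motif
#' can additionally be admitted.
#'
#' @param admit_nng Admit NNG-class sites in addition to GGG/NGG?
#' @return An object of class `pam_policy`.
#' @export
pam_policy <- function(admit_nng = FALSE) {
  stopifnot(is.logical(admit_nng), length(admit_nng) == 1L, !is.na(admit_nng))
  structure(list(admit_nng = admit_nng), class = "pam_policy")
}

admitted_classes <- function(policy) {
  if (policy$admit_nng) c("GGG", "NGG", "NNG") else c("GGG", "NGG")
}
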