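#' Construct a guide query
#'
#' Bundles a 20-nt protospacer with the prediction mode. The protospacer is
#' the DNA sequence targeted by the sgRNA spacer, written 5'->3' with
#' position 20 adjacent to the PAM.
#'
#' @param protospacer 20-character string over A/C/G/T (case-insensitive).
#'   Ambiguity codes are rejected: the query must be fully specified.
#' @param mode `"binding"` (dCas9 occupancy; mismatch budget 9) or
#'   `"cleavage"` (active Cas9 cutting; mismatch budget 6).
#' @param label Free-text identifier carried into outputs.
#' @return An object of class `guide_query`.
#' @examples
#' guide_query("GACGCATAAAGATGAGACGC", mode = "cleavage", label = "emx1")
#' @export
guide_query <- function(protospacer, mode = c("binding", "cleavage"),
                        label = "guide") {
  mode <- match.arg(mode)
  if (!is.character(protospacer) || length(protospacer) != 1L)
    stop("`protospacer` must be a single character string")
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 nt, got ", nchar(protospacer))
  if (grepl("[^ACGT]", protospacer))
    stop("protospacer must contain only A, C, G, T")
  structure(
    list(protospacer = protospacer, mode = mode, label = as.character(label)),
    class = "guide_query"
  )
}

#' @export
print.guide_query <- function(x, ...) {
  cat("guide_query '", x$label, "': ", x$protospacer,
      " [", x$mode, " mode]\n", sep = "")
  invisible(x)
}

#' Default mismatch budget for a prediction mode
#'
#' Binding tolerates up to 9 mismatches; cleavage up to 6, reflecting the
#' higher mismatch tolerance of dCas9 occupancy relative to cutting.
#'
#' @param mode `"binding"` or `"cleavage"`.
#' @return Integer mismatch budget.
#' @export
mismatch_budget <- function(mode = c("binding", "cleavage")) {
  mode <- match.arg(mode)
  if (mode == "binding") 9L else 6L
}
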