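#' Canonical DDI label vocabulary
#'
#' The five sentence-level relation labels of the DDI-2013 task, in canonical
#' order: `false` (no interaction asserted), `effect` (clinical outcome),
#' `mechanism` (pharmacokinetic explanation), `advise` (recommendation about
#' co-administration), `int` (interaction stated without detail). All label
#' vectors in the package are kept in this order; prediction ties are broken
#' toward the earlier label.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' ddi_labels()
ddi_labels <- function() c("false", "effect", "mechanism", "advise", "int")

#' The four positive (non-false) DDI labels
#'
#' @return Character vector of length four.
#' @export
ddi_positive_labels <- function() setdiff(ddi_labels(), "false")

# Factor with the canonical level order; errors on out-of-vocabulary labels.
as_ddi_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), ddi_labels())
  if (length(bad) > 0L) {
    stop("unknown DDI label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = ddi_labels())
}
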