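#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m p_(j) / j` for p-values sorted ascending, mapped
#' back to the input order. Delegates to [stats::p.adjust()] after
#' validating the inputs.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("bh_adjust: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' FDR control over a family of MR tests
#'
#' Applies [bh_adjust()] across one screen family (for example the 249
#' metabolite tests of a single exposure-outcome direction) and marks
#' significance at `alpha`.
#'
#' @param estimates data frame with one row per trait, containing columns
#'   `id` and `pval` (additional columns such as `beta` are carried
#'   through).
#' @param alpha family FDR threshold.
#' @return A `q_value_set`: the input with `qval` and `significant`
#'   columns appended and `alpha` stored as an attribute.
#' @export
family_filter <- function(estimates, alpha = 0.05) {
  estimates <- as.data.frame(estimates, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "pval") %in% names(estimates)))
  if (anyDuplicated(estimates$id)) {
    stop("family_filter: duplicate trait ids in the family", call. = FALSE)
  }
  estimates$qval <- bh_adjust(estimates$pval)
  estimates$significant <- estimates$qval < alpha
  structure(estimates, alpha = alpha,
            class = c("q_value_set", "data.frame"))
}

#' @export
print.q_value_set <- function(x, ...) {
  cat(sprintf("<q_value_set> %d tests, %d significant at q < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  NextMethod()
}
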