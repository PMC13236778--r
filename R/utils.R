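# internal validation helpers; kept terse on purpose

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", what, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, what, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", what, lo, hi))
  }
  invisible(as.numeric(x))
}

# Benjamini-Hochberg step-up; thin wrapper so p-value validation lives in one place
#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Adjusts a vector of p-values with the Benjamini-Hochberg step-up procedure,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("all p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
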