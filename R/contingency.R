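#' 2x2 contingency test result
#'
#' Container for the 2x2 counts, fold enrichment and two-tail p-value used
#' throughout the overlap and enrichment stages. `fold` is the ratio of the
#' observed count to the count expected under independence (or a ratio of
#' proportions, depending on the calling operation); it is `NA` and flagged
#' when an expected count is zero.
#'
#' @param counts 2x2 matrix of non-negative integers
#'   (`[in A & B, A only; B only, neither]` for overlap-style tests).
#' @param fold Numeric fold enrichment (>= 0, or `NA` when undefined).
#' @param p_two_tail Two-tailed p-value in `[0, 1]`.
#' @param method One of `"fisher_exact"`, `"chi_square"`, `"binomial"`.
#' @param fold_defined Logical; `FALSE` when an expected count was zero.
#' @return An object of class `"contingency_result"`.
#' @export
contingency_result <- function(counts, fold, p_two_tail,
                               method = c("fisher_exact", "chi_square",
                                          "binomial"),
                               fold_defined = !is.na(fold)) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stopf("counts must be a 2x2 matrix of non-negative integers")
  if (!is.na(p_two_tail) && (p_two_tail < 0 || p_two_tail > 1))
    stopf("p_two_tail must lie in [0, 1]")
  if (!is.na(fold) && fold < 0)
    stopf("fold must be non-negative")
  structure(list(counts = counts, fold = fold, p_two_tail = p_two_tail,
                 method = method, fold_defined = fold_defined),
            class = "contingency_result")
}

# run the configured two-tail test on a 2x2 count matrix
contingency_test <- function(counts, method = c("fisher_exact", "chi_square")) {
  method <- match.arg(method)
  if (method == "fisher_exact") {
    stats::fisher.test(counts)$p.value
  } else {
    # plain Pearson chi-square (no continuity correction; counts here are
    # large whole-genome tallies where Yates' correction is immaterial)
    suppressWarnings(stats::chisq.test(counts, correct = FALSE)$p.value)
  }
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 %s test\n", x$method))
  tab <- x$counts
  dimnames(tab) <- list(c("in A", "not A"), c("in B", "not B"))
  print(tab)
  fold <- if (x$fold_defined) sprintf("%.3g", x$fold) else "undefined"
  cat(sprintf("fold = %s, two-tail p = %s\n", fold,
              format_pvalue(x$p_two_tail)))
  invisible(x)
}
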