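#' Compare tail-class composition between two samples
#'
#' Pearson chi-square test (no continuity correction) on a 2 x k table
#' of class counts, k in 2..4; degrees of freedom k - 1.
#'
#' @param counts_a,counts_b named non-negative count vectors over the
#'   same classes.
#' @param labels length-2 character vector naming the two samples.
#' @return a `tail_test` object; see [tidy.tail_test()].
#' @export
#' @examples
#' compare_class_fractions(c(A = 90, AU = 10), c(A = 10, AU = 90))
compare_class_fractions <- function(counts_a, counts_b,
                                    labels = c("a", "b")) {
  if (!is.null(names(counts_a)) && !is.null(names(counts_b))) {
    counts_b <- counts_b[names(counts_a)]
  }
  k <- length(counts_a)
  if (length(counts_b) != k || k < 2L || k > 4L) {
    abort("counts must be two aligned vectors of 2-4 categories")
  }
  tab <- rbind(counts_a, counts_b)
  if (any(tab < 0) || any(is.na(tab))) abort("counts must be non-negative")
  if (any(colSums(tab) == 0)) {
    abort("a category has zero total count; pool it with a neighbour before testing")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(
    method = "Pearson chi-square (no continuity correction)",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = if (ht$statistic == 0) 1 else unname(ht$p.value),
    labels = labels, table = tab, htest = ht
  ), class = "tail_test")
}

#' Compare tail-length distributions between two samples
#'
#' Two-sided Mann-Whitney U test. The p-value is exact (full
#' enumeration) when the smaller sample has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie
#' correction is used (no continuity correction).
#'
#' @param lengths_a,lengths_b numeric vectors of tail lengths.
#' @param labels length-2 character vector naming the two samples.
#' @return a `tail_test` object with the U statistic.
#' @export
#' @examples
#' compare_length_distributions(c(1, 2, 3), c(4, 5, 6))
compare_length_distributions <- function(lengths_a, lengths_b,
                                         labels = c("a", "b")) {
  if (length(lengths_a) == 0L || length(lengths_b) == 0L) {
    abort("both samples must be non-empty")
  }
  exact <- min(length(lengths_a), length(lengths_b)) <= 8L &&
    !anyDuplicated(c(lengths_a, lengths_b))
  ht <- suppressWarnings(
    wilcox.test(lengths_a, lengths_b, exact = exact, correct = FALSE))
  p <- unname(ht$p.value)
  # degenerate identical samples: W at its null mean, p is 1
  if (is.nan(p)) p <- 1
  structure(list(
    method = paste0("Mann-Whitney U, two-sided (",
                    if (exact) "exact" else "normal approximation", ")"),
    statistic = unname(ht$statistic), df = NA_real_,
    p.value = min(p, 1), labels = labels, table = NULL, htest = ht
  ), class = "tail_test")
}

#' @export
print.tail_test <- function(x, ...) {
  cat("<tail_test> ", x$method, "\n", sep = "")
  cat("  ", x$labels[1], " vs ", x$labels[2],
      ": statistic = ", format(x$statistic),
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", format(x$p.value), "\n", sep = "")
  invisible(x)
}

#' Tidy a tail-test result
#'
#' @param x a `tail_test` object.
#' @param ... unused.
#' @return one-row tibble with `statistic`, `df`, `p.value`, `method`
#'   and the compared labels.
#' @export
tidy.tail_test <- function(x, ...) {
  tibble(label_a = x$labels[1], label_b = x$labels[2],
         statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' @rdname tidy.tail_test
#' @export
glance.tail_test <- function(x, ...) {
  tidy(x)
}

#' Benjamini-Hochberg adjust a table of comparisons
#'
#' @param tests tibble with a `p.value` column (for example row-bound
#'   [tidy.tail_test()] outputs).
#' @param method multiple-testing correction, see [stats::p.adjust()].
#' @return `tests` with a `p.adjusted` column.
#' @export
adjust_comparisons <- function(tests, method = "BH") {
  tests$p.adjusted <- stats::p.adjust(tests$p.value, method = method)
  tests
}
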