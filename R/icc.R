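#' Intraclass correlation for observer agreement
#'
#' Two-way, absolute-agreement, single-measure ICC -- ICC(A,1) in the
#' McGraw & Wong taxonomy -- from the variance-component decomposition of
#' the two-way ANOVA of paired ratings (subjects crossed with raters):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} the subject, rater and residual
#' mean squares, k = 2 raters and n subjects. This is the form used to
#' assess intra- and inter-observer reproducibility of a measurement.
#'
#' @param ratingsA,ratingsB equal-length paired measurements (n >= 3).
#' @return the ICC estimate, a number in [-1, 1].
#' @examples
#' reproducibilityICC(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
#' @export
reproducibilityICC <- function(ratingsA, ratingsB) {
  if (length(ratingsA) != length(ratingsB))
    lgeError("rating vectors must have equal length", "inputError")
  n <- length(ratingsA)
  if (n < 3) lgeError("need at least 3 paired ratings", "inputError")
  X <- cbind(ratingsA, ratingsB)
  if (anyNA(X)) lgeError("ratings must not contain NA", "inputError")
  k <- 2L
  grand <- mean(X)
  rowM <- rowMeans(X)
  colM <- colMeans(X)
  ssTot <- sum((X - grand)^2)
  if (ssTot <= .Machine$double.eps * n)
    lgeError("total variance is zero; ICC undefined",
             "undefinedValueError")
  msR <- k * sum((rowM - grand)^2) / (n - 1)
  msC <- n * sum((colM - grand)^2) / (k - 1)
  msE <- (ssTot - k * sum((rowM - grand)^2) - n * sum((colM - grand)^2)) /
    ((n - 1) * (k - 1))
  (msR - msE) / (msR + (k - 1) * msE + k * (msC - msE) / n)
}
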