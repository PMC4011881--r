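# Inter-rater agreement statistics over four-tier score tables.

asCounts <- function(t) {
  if (is(t, "ContingencyTable")) return(t@counts)
  if (is.matrix(t) && nrow(t) == ncol(t)) {
    if (any(!is.finite(t)) || any(t < 0)) {
      stop("counts must be non-negative and finite", call. = FALSE)
    }
    return(t)
  }
  stop("expected a ContingencyTable or a square count matrix",
       call. = FALSE)
}

#' Percent agreement of two raters
#'
#' The percentage of samples on which the two raters assign the same
#' tier: 100 times the diagonal sum over the grand total.
#'
#' @param table a \code{\linkS4class{ContingencyTable}} or square count
#'   matrix.
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' percentAgreement(diag(c(5, 5, 5, 5)))  # 100
percentAgreement <- function(table) {
  cnt <- asCounts(table)
  n <- sum(cnt)
  if (n <= 0) stop("table has zero total count", call. = FALSE)
  100 * sum(diag(cnt)) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement of two raters over categorical labels,
#' \code{kappa = (p_o - p_e) / (1 - p_e)}, with observed agreement
#' \code{p_o} the diagonal proportion and expected agreement \code{p_e}
#' the sum of products of the row and column marginal proportions.
#'
#' @inheritParams percentAgreement
#' @return Kappa in [-1, 1].
#' @seealso \code{\link{kappaCI}}
#' @export
#' @examples
#' cohenKappa(diag(c(5, 8, 6, 2)))  # 1: perfect agreement
cohenKappa <- function(table) {
  cnt <- asCounts(table)
  n <- sum(cnt)
  if (n <= 0) stop("table has zero total count", call. = FALSE)
  p <- cnt / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (abs(1 - pe) < 1e-12) {
    stop("kappa undefined: expected agreement equals 1 (degenerate margins)",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Large-sample confidence interval for Cohen's kappa
#'
#' Normal-approximation interval using the Fleiss-Cohen-Everitt
#' asymptotic standard error of kappa (the non-null SE used by standard
#' statistics packages). Bounds are clamped to [-1, 1]; perfect
#' agreement yields the degenerate interval at 1.
#'
#' @inheritParams percentAgreement
#' @param level confidence level, default 0.95.
#' @return Named numeric(2): \code{lower}, \code{upper}.
#' @export
kappaCI <- function(table, level = 0.95) {
  cnt <- asCounts(table)
  n <- sum(cnt)
  k <- cohenKappa(cnt)
  p <- cnt / n
  r <- rowSums(p)
  cc <- colSums(p)
  pe <- sum(r * cc)
  A <- sum(diag(p) * (1 - (r + cc) * (1 - k))^2)
  B <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (i != j) B <- B + p[i, j] * (cc[i] + r[j])^2
    }
  }
  B <- (1 - k)^2 * B
  C <- (k - pe * (1 - k))^2
  se <- sqrt(max(A + B - C, 0)) / ((1 - pe) * sqrt(n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(k - z * se, -1), upper = min(k + z * se, 1))
}

#' Pearson chi-square test of independence for a score table
#'
#' Two-tailed Pearson chi-square of the rater-by-rater table. Rows or
#' columns with zero total (tiers never used by a rater) are dropped with
#' a warning before testing, reducing the degrees of freedom accordingly;
#' a full 4x4 table has 9 degrees of freedom.
#'
#' @inheritParams percentAgreement
#' @return List with \code{statistic}, \code{dof} and \code{p}.
#' @export
chiSquareTest <- function(table) {
  cnt <- asCounts(table)
  if (sum(cnt) <= 0) stop("table has zero total count", call. = FALSE)
  keepR <- rowSums(cnt) > 0
  keepC <- colSums(cnt) > 0
  if (!all(keepR) || !all(keepC)) {
    warning("dropping ", sum(!keepR), " empty row(s) and ",
            sum(!keepC), " empty column(s) before chi-square")
    cnt <- cnt[keepR, keepC, drop = FALSE]
  }
  if (nrow(cnt) < 2L || ncol(cnt) < 2L) {
    stop("fewer than two non-empty rows or columns; chi-square undefined",
         call. = FALSE)
  }
  ct <- stats::chisq.test(cnt, correct = FALSE)
  list(statistic = unname(ct$statistic),
       dof = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Read a four-tier score contingency table from CSV
#'
#' Expects a header row naming the four tiers and four rows of counts;
#' an optional leading label column (row tiers) is detected and used.
#' Rows are the first rater, columns the second.
#'
#' @param path CSV file path.
#' @param raters character(2) rater names.
#' @return A \code{\linkS4class{ContingencyTable}}.
#' @export
#' @examples
#' path <- system.file("extdata", "agreement_manual_vs_automated.csv",
#'                     package = "ihcscore")
#' readContingencyTable(path)
readContingencyTable <- function(path, raters = c("rater1", "rater2")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) == 5L && !is.numeric(df[[1L]])) {
    df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) != 4L || nrow(df) != 4L) {
    stop("expected a 4x4 count table (with tier header row)", call. = FALSE)
  }
  ContingencyTable(as.matrix(df), raters = raters)
}
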