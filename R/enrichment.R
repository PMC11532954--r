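# Fisher 2x2 tests and enrichment-factor arithmetic.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Row 1 is the focal class (in / out of pG4), row 2 the background. The
#' two-sided p-value sums the hypergeometric point probabilities not
#' exceeding that of the observed table, computed in log space so
#' genome-scale counts survive. For tables whose smallest expected cell
#' exceeds `max_exact_expected` a chi-squared approximation with continuity
#' correction is substituted (announced via a message).
#'
#' @param a,b,c,d Table cells (row-wise), or pass a 2x2 matrix as `a`.
#' @param max_exact_expected Expected-cell threshold above which the
#'   chi-squared approximation is used (default 1e4).
#' @return Two-sided p-value.
#' @examples
#' fisher_2x2(5, 5, 5, 5)  # 1
#' @export
fisher_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                       max_exact_expected = 1e4) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) stop("table cells must be >= 0")
  rs <- c(a + b, c + d); cs <- c(a + c, b + d); N <- sum(cells)
  if (any(rs == 0) || any(cs == 0)) stop("empty margin in 2x2 table")
  expected <- outer(rs, cs) / N
  if (min(expected) > max_exact_expected) {
    message("fisher_2x2: all expected cells > ", max_exact_expected,
            "; using chi-squared approximation with continuity correction")
    p <- suppressWarnings(stats::chisq.test(
      matrix(cells, 2L, 2L, byrow = TRUE), correct = TRUE))$p.value
    return(unname(p))
  }
  # hypergeometric over cell a with margins fixed
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  lp <- stats::dhyper(support, m, n_, k, log = TRUE)
  lobs <- stats::dhyper(a, m, n_, k, log = TRUE)
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

#' Enrichment factor from two percentages
#'
#' Ratio of a focal-class pG4 percentage to the genomic background
#' percentage, e.g. the percentage of EST start sites inside pG4 over the
#' percentage of the genome covered by pG4.
#'
#' @param focal_pct,background_pct Percentages; `background_pct` must be
#'   positive.
#' @param digits Decimals to round to (default 2).
#' @return The rounded ratio.
#' @examples
#' enrichment_factor(0.63, 0.34)  # 1.85
#' @export
enrichment_factor <- function(focal_pct, background_pct, digits = 2) {
  if (!is.finite(background_pct) || background_pct <= 0) {
    stop("background_pct must be positive")
  }
  round(focal_pct / background_pct, digits)
}

#' Fold enrichment of a focal class inside pG4 versus genome average
#'
#' `fold = (n_focal_in / n_focal_total) / (pg4_bp / genome_bp)` plus the
#' Fisher p-value on the 2x2 table
#' `[[n_focal_in, n_focal_total - n_focal_in], [pg4_bp, genome_bp -
#' pg4_bp]]`. Note the table mixes units (events in row 1, bases in
#' row 2); the construction is flagged in the result.
#'
#' @param n_focal_in Focal events inside pG4.
#' @param n_focal_total All focal events.
#' @param pg4_bp Strand-merged pG4 base pairs.
#' @param genome_bp Ungapped genome length.
#' @return List `fold`, `p`, `table` (2x2 matrix) and `note` describing the
#'   table construction.
#' @export
overlap_enrichment <- function(n_focal_in, n_focal_total, pg4_bp,
                               genome_bp) {
  if (n_focal_total <= 0 || pg4_bp <= 0 || genome_bp <= 0) {
    stop("totals must be positive")
  }
  if (n_focal_in > n_focal_total) {
    stop("n_focal_in cannot exceed n_focal_total")
  }
  fold <- (n_focal_in / n_focal_total) / (pg4_bp / genome_bp)
  tab <- matrix(c(n_focal_in, n_focal_total - n_focal_in,
                  pg4_bp, genome_bp - pg4_bp), 2L, 2L, byrow = TRUE)
  p <- fisher_2x2(tab)
  list(fold = fold, p = p, table = tab,
       note = "2x2 mixes event counts (row 1) and base counts (row 2)")
}
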