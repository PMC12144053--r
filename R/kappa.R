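#' Inter-rater agreement (kappa) for nominal category codings
#'
#' Chance-corrected agreement among the independent coders who assign apps to
#' social-media categories. With exactly two raters this is Cohen's kappa
#' (expected agreement from the two raters' own marginal label frequencies,
#' `pe = sum_j p1j * p2j`); with three or more raters it is Fleiss' kappa
#' (expected agreement from the pooled label proportions, `pe = sum_j pj^2`,
#' observed agreement averaged over item-wise pairwise agreement
#' `Pi = (sum_j nij^2 - n) / (n (n - 1))`). Fleiss' multi-rater statistic is
#' the standard generalization when a paper reports a single kappa for five
#' coders; the two-rater Cohen reduction is documented separately because the
#' two formulas differ in how chance agreement is estimated.
#'
#' Degenerate case: when every cell carries one identical label, expected
#' agreement is 1 and the usual ratio is 0/0; by convention the function
#' returns 1 (perfect agreement is observed, there is nothing to correct).
#'
#' @param ratings matrix or data.frame, items in rows, raters in columns,
#'   nominal labels (character/factor/integer) in cells; no missing cells.
#' @return an object of class `sm_kappa`: list with `kappa`, `method`
#'   (`"fleiss"` or `"cohen"`), `n_items`, `n_raters`, `labels`.
#' @export
#' @examples
#' r <- cbind(c("a", "a", "b"), c("a", "a", "b"), c("a", "b", "b"))
#' inter_rater_kappa(r)
inter_rater_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("rating matrix has missing cells", call. = FALSE)
  n_items <- nrow(m)
  n_raters <- ncol(m)
  if (is.null(n_items) || n_items < 2L) {
    stop("need at least 2 items", call. = FALSE)
  }
  if (n_raters < 2L) stop("need at least 2 raters", call. = FALSE)
  labels <- sort(unique(as.vector(m)))

  if (n_raters == 2L) {
    po <- mean(m[, 1L] == m[, 2L])
    p1 <- table(factor(m[, 1L], levels = labels)) / n_items
    p2 <- table(factor(m[, 2L], levels = labels)) / n_items
    pe <- sum(p1 * p2)
    k <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
    method <- "cohen"
  } else {
    # n_ij: raters assigning label j to item i
    nij <- vapply(labels, function(l) rowSums(m == l), numeric(n_items))
    nij <- matrix(nij, nrow = n_items)
    Pi <- (rowSums(nij^2) - n_raters) / (n_raters * (n_raters - 1))
    pbar <- mean(Pi)
    pj <- colSums(nij) / (n_items * n_raters)
    pe <- sum(pj^2)
    k <- if (pe >= 1) 1 else (pbar - pe) / (1 - pe)
    method <- "fleiss"
  }
  structure(list(kappa = k, method = method, n_items = n_items,
                 n_raters = n_raters, labels = labels),
            class = "sm_kappa")
}

#' @export
print.sm_kappa <- function(x, ...) {
  cat(sprintf("kappa (%s) = %.4f (%d items, %d raters, %d labels)\n",
              x$method, x$kappa, x$n_items, x$n_raters, length(x$labels)))
  invisible(x)
}
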