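#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. When both masks are empty the
#' coefficient is defined as 1: two raters who both mark a component (for
#' example thrombus) as absent are in perfect agreement. Set
#' `na_when_empty = TRUE` to instead return `NA`, which reproduces the
#' convention of scoring a component only on cases where it is present.
#'
#' @param a,b Logical arrays (or anything coercible) of identical shape.
#' @param na_when_empty Return `NA` instead of 1 when both masks are empty.
#' @return Dice coefficient in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' dice_coefficient(m, m)
dice_coefficient <- function(a, b, na_when_empty = FALSE) {
  if (!identical(dim(a), dim(b))) abort("masks must share the same shape")
  a <- as.logical(a); b <- as.logical(b)
  na_ <- sum(a); nb <- sum(b)
  if (na_ + nb == 0) {
    return(if (na_when_empty) NA_real_ else 1)
  }
  2 * sum(a & b) / (na_ + nb)
}

#' Paired volume-error metrics (MAE, bias, bias significance)
#'
#' Compares candidate volumes against paired reference volumes: mean
#' absolute error, signed bias (candidate minus reference), and the p-value
#' of a paired two-sided Student's t-test on the bias.
#'
#' @param reference,candidate Equal-length numeric vectors of paired volumes
#'   (mL), `n >= 2`.
#' @return A one-row tibble with columns `mae`, `bias`, `bias_p`, `n`.
#' @export
#' @examples
#' volume_error_metrics(c(10, 20), c(12, 18))
volume_error_metrics <- function(reference, candidate) {
  if (length(reference) != length(candidate)) {
    abort("reference and candidate must be paired (equal length)")
  }
  n <- length(reference)
  if (n < 2) abort("need at least 2 paired cases")
  diffs <- candidate - reference
  bias_p <- if (all(diffs == diffs[1])) {
    # zero-variance differences: identical bias in every case
    if (diffs[1] == 0) 1 else 0
  } else {
    t.test(candidate, reference, paired = TRUE)$p.value
  }
  tibble::tibble(
    mae = mean(abs(diffs)),
    bias = mean(diffs),
    bias_p = bias_p,
    n = n
  )
}
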