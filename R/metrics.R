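# Affinity transform and evaluation statistics.

#' Transform a dissociation constant to pKd
#'
#' `pKd = -log10(Kd / 1e9)` for `Kd` in nanomolar, i.e. the negative log10 of
#' the molar dissociation constant. 10 uM (10000 nM) maps to 5, 1 nM to 9.
#'
#' @param kd_nm Dissociation constant(s) in nM; must be positive.
#' @return pKd value(s).
#' @examples
#' pkd_transform(10000) # 5
#' @export
pkd_transform <- function(kd_nm) {
  if (!is.numeric(kd_nm) || any(!is.finite(kd_nm)) || any(kd_nm <= 0)) {
    stop("Kd must be positive and finite (nM)")
  }
  -log10(kd_nm / 1e9)
}

#' Mean squared error
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return `mean((pred - truth)^2)`.
#' @export
mse <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    stop("pred and truth must be equal-length, non-empty vectors")
  }
  mean((pred - truth)^2)
}

#' Concordance index
#'
#' The fraction of pairs with strictly different true affinities whose
#' predictions are ordered the same way; prediction ties count 1/2. Formally
#' `CI = (1/Z) * sum_{d_x > d_y} h(b_x - b_y)` with `h = 1, 1/2, 0` for
#' positive, zero, negative arguments and `Z` the number of pairs with
#' strictly greater true affinity. 1 is perfect ordering, 0.5 is
#' uninformative.
#'
#' @param pred Numeric predictions.
#' @param truth Numeric true affinities, same length, with at least two
#'   distinct values.
#' @return CI in `[0, 1]`.
#' @export
concordance_index <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2L) {
    stop("need at least two paired observations")
  }
  if (length(unique(truth)) < 2L) {
    stop("concordance index undefined: all true values are equal")
  }
  # vectorized over all ordered pairs (i, j) with truth_i > truth_j
  gt <- outer(truth, truth, ">")
  diff_pred <- outer(pred, pred, "-")
  h <- (diff_pred > 0) + 0.5 * (diff_pred == 0)
  sum(h[gt]) / sum(gt)
}
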