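#' Proportion-of-maximum rescaling (POMS)
#'
#' Linearly maps a bounded score from its instrument scale to a common target
#' range, by default 1--7.  The transformation uses the instrument's
#' *theoretical* minimum and maximum, so that the rescaled scores span exactly
#' the target range whenever the instrument bounds are attained.
#'
#' @param x Numeric vector; may contain `NA`.
#' @param scale_min,scale_max Theoretical bounds of the instrument scale.
#' @param target Length-2 numeric, the target range (default `c(1, 7)`).
#' @return Numeric vector of the same length as `x`, on the target scale.
#'   Missing values are passed through.
#' @examples
#' poms_rescale(c(1, 3, 5), 1, 5)  # -> 1 4 7
#' @export
poms_rescale <- function(x, scale_min, scale_max, target = c(1, 7)) {
  if (!is.numeric(scale_min) || !is.numeric(scale_max) || scale_min >= scale_max)
    stop("'scale_min' must be strictly less than 'scale_max'")
  bad <- which(!is.na(x) & (x < scale_min | x > scale_max))
  if (length(bad))
    stop(sprintf("values outside [%g, %g] at row(s) %s", scale_min, scale_max,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  target[1L] + diff(target) * (x - scale_min) / (scale_max - scale_min)
}

#' Center a score vector at its mean
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @return List with `values` (centered vector, mean 0) and `mean`
#'   (the removed mean, retained for back-transformation).
#' @export
center_scores <- function(x) {
  if (sum(!is.na(x)) < 2L) stop("need at least 2 non-missing values to center")
  m <- mean(x, na.rm = TRUE)
  list(values = x - m, mean = m)
}
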