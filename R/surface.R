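#' Response-surface auxiliary coefficients
#'
#' Classic response-surface parameters of the second-order polynomial:
#' slope `a1 = b1 + b2` and curvature `a2 = b3 + b4 + b5` along the line of
#' congruence (E = N), and slope `a3 = b1 - b2` and curvature
#' `a4 = b3 - b4 + b5` along the line of incongruence (E = -N).
#'
#' @param coefficients Named numeric with `b1 ... b5` (e.g.
#'   `fit$coefficients`).
#' @return Named numeric `a1, a2, a3, a4`.
#' @export
rsa_coefficients <- function(coefficients) {
  b <- coefficients
  c(a1 = unname(b["b1"] + b["b2"]),
    a2 = unname(b["b3"] + b["b4"] + b["b5"]),
    a3 = unname(b["b1"] - b["b2"]),
    a4 = unname(b["b3"] - b["b4"] + b["b5"]))
}

predict_surface <- function(b, e, n) {
  b["b0"] + b["b1"] * e + b["b2"] * n + b["b3"] * e^2 + b["b4"] * e * n +
    b["b5"] * n^2
}

#' Evaluate a fitted surface on a grid restricted to the data region
#'
#' Exact polynomial evaluation of a fitted model over a regular grid
#' spanning the range box.  Each grid point is masked by whether it falls
#' inside the convex hull of the observed (E, N) points: the surface carries
#' interpretation only over the region where data were actually observed.
#'
#' @param fit A converged `"poly_fit"`.
#' @param range_box Range box (defaults to the box spanned by the fit's own
#'   data).
#' @param resolution Grid points per axis (default 50, minimum 2).
#' @return A `data.frame` of class `"surface_grid"` with columns `e`, `n`,
#'   `prediction`, `in_region`, plus the stationary point of the surface in
#'   `attr(, "stationary_point")` (`NA` when the surface has no curvature).
#' @export
predict_grid <- function(fit, range_box = NULL, resolution = 50L) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (resolution < 2L) stop("resolution must be at least 2")
  en <- fit$data_en
  if (is.null(range_box))
    range_box <- c(e_lo = min(en[, "E"]), e_hi = max(en[, "E"]),
                   n_lo = min(en[, "N"]), n_hi = max(en[, "N"]))
  b <- fit$coefficients
  g <- expand.grid(
    e = seq(range_box[["e_lo"]], range_box[["e_hi"]], length.out = resolution),
    n = seq(range_box[["n_lo"]], range_box[["n_hi"]], length.out = resolution))
  g$prediction <- as.numeric(predict_surface(b, g$e, g$n))

  hull <- grDevices::chull(en)
  poly <- en[c(hull, hull[1L]), , drop = FALSE]
  g$in_region <- mgcv::in.out(poly, as.matrix(g[, c("e", "n")]))

  structure(g, range_box = range_box,
            stationary_point = stationary_point(b),
            coefficients = b,
            class = c("surface_grid", "data.frame"))
}

# vertex of the quadratic surface; undefined when curvature is (near) zero
stationary_point <- function(b, tol = 1e-8) {
  H <- matrix(c(2 * b[["b3"]], b[["b4"]], b[["b4"]], 2 * b[["b5"]]), 2L)
  if (abs(det(H)) < tol) return(c(e = NA_real_, n = NA_real_))
  sp <- solve(H, -c(b[["b1"]], b[["b2"]]))
  c(e = sp[1L], n = sp[2L])
}

#' Classify the shape of a fitted surface per trait
#'
#' Analyses the sign of each trait's slope (evaluated at the sample mean of
#' the other trait) across the observed range box.  A trait's effect is
#' `"linear"` when it has no curvature, `"saturating"` when the slope
#' magnitude shrinks towards higher trait levels, `"exponential"` when it
#' grows, and `"non-monotone"` when the slope changes sign inside the box --
#' in which case the fraction of observed persons on each side of the
#' reversal point is reported (e.g. a positive-but-saturating effect for
#' most persons that turns negative at the extreme end of the trait).
#'
#' @param fit A converged `"poly_fit"`.
#' @param range_box Optional range box (defaults to the box of the fit's
#'   data).
#' @param tol Curvature below which an effect counts as linear.
#' @return List with elements `E` and `N` (each: `label`, `slope_lo`,
#'   `slope_hi`, `vertex`, `fraction_below`, `fraction_above`) and
#'   `interaction` (`"positive"`, `"negative"` or `"none"`).
#' @export
classify_shape <- function(fit, range_box = NULL, tol = 1e-8) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  en <- fit$data_en
  if (is.null(range_box))
    range_box <- c(e_lo = min(en[, "E"]), e_hi = max(en[, "E"]),
                   n_lo = min(en[, "N"]), n_hi = max(en[, "N"]))
  b <- fit$coefficients

  one_trait <- function(lin, quad, lo, hi, obs) {
    s_lo <- b[[lin]] + 2 * b[[quad]] * lo
    s_hi <- b[[lin]] + 2 * b[[quad]] * hi
    vertex <- if (abs(b[[quad]]) > tol) -b[[lin]] / (2 * b[[quad]]) else NA_real_
    res <- list(slope_lo = s_lo, slope_hi = s_hi, vertex = vertex,
                fraction_below = NA_real_, fraction_above = NA_real_)
    if (abs(b[[quad]]) <= tol) {
      res$label <- "linear"
    } else if (!is.na(vertex) && vertex > lo && vertex < hi &&
               sign(s_lo) != sign(s_hi) && abs(s_lo) > tol && abs(s_hi) > tol) {
      res$label <- "non-monotone"
      res$fraction_below <- mean(obs < vertex)
      res$fraction_above <- mean(obs >= vertex)
    } else {
      # monotone over the box: slope magnitude growing towards high trait
      # levels = exponential, shrinking = saturating
      res$label <- if (abs(s_hi) >= abs(s_lo)) "exponential" else "saturating"
    }
    res
  }

  list(E = one_trait("b1", "b3", range_box[["e_lo"]], range_box[["e_hi"]],
                     en[, "E"]),
       N = one_trait("b2", "b5", range_box[["n_lo"]], range_box[["n_hi"]],
                     en[, "N"]),
       interaction = if (abs(b[["b4"]]) <= tol) "none"
                     else if (b[["b4"]] > 0) "positive" else "negative")
}

#' @export
print.surface_grid <- function(x, ...) {
  rb <- attr(x, "range_box")
  cat(sprintf("Surface grid: %d points over E [%.2f, %.2f] x N [%.2f, %.2f]; %d in data region\n",
              nrow(x), rb[["e_lo"]], rb[["e_hi"]], rb[["n_lo"]], rb[["n_hi"]],
              sum(x$in_region)))
  sp <- attr(x, "stationary_point")
  if (!anyNA(sp))
    cat(sprintf("Stationary point at (E = %.3f, N = %.3f)\n", sp["e"], sp["n"]))
  invisible(x)
}

#' Plot a surface grid as a filled contour of predicted outcome levels
#'
#' Points outside the observed data region are blanked.
#'
#' @param x A `"surface_grid"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.surface_grid <- function(x, ...) {
  e <- sort(unique(x$e)); n <- sort(unique(x$n))
  z <- matrix(ifelse(x$in_region, x$prediction, NA_real_),
              nrow = length(e), ncol = length(n))
  graphics::image(e, n, z, xlab = "Extraversion (centered)",
                  ylab = "Neuroticism (centered)",
                  col = grDevices::hcl.colors(24, "Lajolla"), ...)
  graphics::contour(e, n, z, add = TRUE)
  invisible(x)
}
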