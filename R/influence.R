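#' Screen for influential cases under the full polynomial model
#'
#' Computes the three standard regression influence diagnostics -- DFFITS,
#' Cook's distance and the hat (leverage) value -- from an ordinary
#' least-squares fit of the full second-order polynomial on complete cases,
#' and flags rows that combine high leverage with high influence.  A row is
#' flagged when its hat value exceeds `2p/n` *and* at least one of
#' `|DFFITS| > 2*sqrt(p/n)` or `Cook's D > 4/n` holds, with `p` the number of
#' design columns including the intercept.  Flagged rows are reported, never
#' removed.
#'
#' @param prepared A `"prepared_data"` object from [build_design()].
#' @param outcome Which outcome to screen on, `"L1"` (default) or `"L2"`.
#' @return A `data.frame` of class `"influence_report"` with per-row
#'   `dffits`, `cooks_d`, `hat` and `flagged`, and the cutoffs used in
#'   `attr(, "cutoffs")`.
#' @export
flag_influential <- function(prepared, outcome = c("L1", "L2")) {
  outcome <- match.arg(outcome)
  y <- prepared[[outcome]]
  keep <- !is.na(y)
  df <- data.frame(y = y[keep], E = prepared$E[keep], N = prepared$N[keep],
                   E2 = prepared$E2[keep], EN = prepared$EN[keep],
                   N2 = prepared$N2[keep])
  qrX <- qr(cbind(1, as.matrix(df[-1L])))
  if (qrX$rank < 6L)
    stop("singular full-model design; inspect predictor variance")
  fit <- stats::lm(y ~ E + N + E2 + EN + N2, data = df)
  n <- nrow(df)
  p <- length(stats::coef(fit))
  cutoffs <- c(dffits = 2 * sqrt(p / n), cooks_d = 4 / n, hat = 2 * p / n)
  dff <- stats::dffits(fit)
  cd <- stats::cooks.distance(fit)
  h <- stats::hatvalues(fit)
  flag <- (h > cutoffs["hat"]) &
    (abs(dff) > cutoffs["dffits"] | cd > cutoffs["cooks_d"])
  rep <- data.frame(person_id = prepared$person_id[keep],
                    dffits = as.numeric(dff), cooks_d = as.numeric(cd),
                    hat = as.numeric(h), flagged = as.logical(flag))
  structure(rep, cutoffs = cutoffs, p = p, n = n,
            class = c("influence_report", "data.frame"))
}

#' @export
print.influence_report <- function(x, ...) {
  co <- attr(x, "cutoffs")
  cat(sprintf("Influence screen (full polynomial, n = %d, p = %d)\n",
              attr(x, "n"), attr(x, "p")))
  cat(sprintf("Cutoffs: |DFFITS| > %.3f, Cook's D > %.4f, hat > %.4f\n",
              co["dffits"], co["cooks_d"], co["hat"]))
  nf <- sum(x$flagged)
  if (nf == 0L) cat("No influential cases identified.\n")
  else {
    cat(nf, "influential case(s):\n")
    print.data.frame(x[x$flagged, ], row.names = FALSE)
  }
  invisible(x)
}
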