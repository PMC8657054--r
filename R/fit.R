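# Constrained Gaussian maximum likelihood.  For every catalogue model the
# log-likelihood profile over the regression coefficients is (up to a
# monotone transform) a least-squares criterion, and the model's equality
# ties are absorbed into the parameter map, so estimation reduces to least
# squares under a handful of linear inequality constraints.  That problem is
# solved exactly by enumerating active sets of the (at most four)
# constraints and solving the corresponding KKT systems -- no iterative
# optimizer, hence deterministic and reproducible.

# min ||y - Z theta||^2  s.t.  A theta <= 0.  Exact active-set enumeration.
constrained_ls <- function(Z, y, A = NULL, tol = 1e-9) {
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  q <- ncol(Z)
  k <- if (is.null(A)) 0L else nrow(A)
  unconstrained <- tryCatch(solve(ZtZ, Zty), error = function(e) NULL)
  if (is.null(unconstrained))
    stop("singular design; inspect predictor variance")
  scale_ref <- max(abs(ZtZ))

  feasible <- function(theta)
    k == 0L || all(A %*% theta <= tol * (1 + max(abs(theta))))
  if (feasible(unconstrained)) {
    theta <- drop(unconstrained)
    return(list(theta = theta, rss = sum((y - Z %*% theta)^2),
                active = integer(0), ok = TRUE))
  }

  best <- NULL
  subsets <- seq_len(2^k) - 1L
  for (s in subsets[-1L]) {            # the empty set was infeasible
    act <- which(bitwAnd(s, 2^(seq_len(k) - 1L)) > 0L)
    Aa <- A[act, , drop = FALSE]
    kkt <- rbind(cbind(ZtZ, t(Aa)),
                 cbind(Aa, matrix(0, length(act), length(act))))
    rhs <- c(Zty, rep(0, length(act)))
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    theta <- sol[seq_len(q)]
    lambda <- sol[-seq_len(q)]
    # dual feasibility: for minimization with A theta <= 0 the multipliers
    # of active constraints must be nonnegative
    if (any(lambda < -tol * scale_ref)) next
    if (!feasible(theta)) next
    rss <- sum((y - Z %*% theta)^2)
    if (is.null(best) || rss < best$rss - tol)
      best <- list(theta = drop(theta), rss = rss, active = act, ok = TRUE)
  }
  if (is.null(best))
    stop("no feasible KKT point found; constraint set may be degenerate")
  best
}

#' Fit one candidate model by constrained maximum likelihood
#'
#' Maximizes the Gaussian conditional likelihood of the outcome given the
#' polynomial design, subject to the model's constraint system.  Rows with a
#' missing outcome contribute no conditional-likelihood term (their marginal
#' trait likelihood is model-independent and drops out of all comparisons)
#' but remain counted in `n_obs`, which is the sample size used by the AICc
#' small-sample correction.  When no constraint is active the estimates are
#' exactly ordinary least squares.
#'
#' @param spec A `"model_spec"` from [build_catalog()].
#' @param prepared A `"prepared_data"` object.
#' @param outcome `"L1"` (baseline, default) or `"L2"` (follow-up).  A
#'   longitudinal spec requires `outcome = "L2"` and uses `L1` as the freely
#'   estimated covariate.
#' @return A list of class `"poly_fit"`: `name`, `coefficients` (full named
#'   vector `b0..b5` and `c_cov` if longitudinal), `theta` (free
#'   parameters), `sigma2` (ML residual variance), `LL`, `K`, `n_obs`,
#'   `n_complete`, `R2`, `adj_R2`, `se` (observed-information standard
#'   errors of the free parameters, reported for convenience),
#'   `active_constraints`, `converged`.
#' @export
fit_spec <- function(spec, prepared, outcome = c("L1", "L2")) {
  outcome <- match.arg(outcome)
  if (spec$longitudinal && outcome != "L2")
    stop("longitudinal spec '", spec$name, "' requires outcome = 'L2'")
  if (!spec$longitudinal && outcome == "L2")
    stop("outcome 'L2' requires a longitudinal catalogue (baseline outcome as covariate)")
  y_all <- prepared[[outcome]]
  X_all <- cbind(b0 = 1, b1 = prepared$E, b2 = prepared$N,
                 b3 = prepared$E2, b4 = prepared$EN, b5 = prepared$N2)
  if (spec$longitudinal) X_all <- cbind(X_all, c_cov = prepared$L1)
  complete <- !is.na(y_all)
  y <- y_all[complete]
  X <- X_all[complete, , drop = FALSE]
  m <- length(y)

  Z <- X %*% spec$map
  A_theta <- if (nrow(spec$A)) spec$A %*% spec$map else NULL
  ls <- constrained_ls(Z, y, A_theta)

  theta <- stats::setNames(ls$theta, colnames(spec$map))
  b <- stats::setNames(as.numeric(spec$map %*% ls$theta), rownames(spec$map))
  sigma2 <- ls$rss / m
  LL <- if (sigma2 > 0) -m / 2 * (log(2 * pi * sigma2) + 1) else Inf
  tss <- sum((y - mean(y))^2)
  R2 <- if (tss > 0) 1 - ls$rss / tss else NA_real_
  p <- spec$K - 2L   # free slopes, excluding intercept and residual variance
  adj_R2 <- if (!is.na(R2) && m > p + 1L)
    1 - (1 - R2) * (m - 1) / (m - p - 1) else NA_real_
  se <- tryCatch(sqrt(diag(solve(crossprod(Z))) * sigma2),
                 error = function(e) rep(NA_real_, length(theta)))

  structure(list(name = spec$name, spec = spec, coefficients = b,
                 theta = theta, sigma2 = sigma2, LL = LL, K = spec$K,
                 n_obs = nrow(prepared), n_complete = m, R2 = R2,
                 adj_R2 = adj_R2, se = stats::setNames(se, names(theta)),
                 active_constraints = rownames(spec$A)[ls$active],
                 converged = isTRUE(ls$ok),
                 data_en = cbind(E = prepared$E, N = prepared$N)[complete, , drop = FALSE],
                 fitted = as.numeric(Z %*% ls$theta), y = y),
            class = "poly_fit")
}

#' Fit every model of a catalogue
#'
#' @param catalog A `"model_catalog"`.
#' @inheritParams fit_spec
#' @return Named list of `"poly_fit"` objects (class `"poly_fit_list"`).
#' @export
fit_catalog <- function(catalog, prepared,
                        outcome = if (attr(catalog, "longitudinal")) "L2" else "L1") {
  fits <- lapply(catalog, fit_spec, prepared = prepared, outcome = outcome)
  structure(fits, class = "poly_fit_list")
}

#' Adjusted R-squared of a fitted model
#'
#' `1 - (1 - R2) (m - 1) / (m - p - 1)` over the `m` complete cases, with
#' `p` the number of free slopes, i.e. excluding the intercept and the
#' residual variance (the one-parameter composite interaction surfaces
#' count `p = 1`).
#'
#' @param fit A `"poly_fit"`, or the raw `R2` value.
#' @param n_complete,p Complete-case count and free slope count; taken from
#'   `fit` when it is a `"poly_fit"`.
#' @return Adjusted R-squared, or `NA` when `n_complete <= p + 1`.
#' @export
adjusted_r2 <- function(fit, n_complete = NULL, p = NULL) {
  if (inherits(fit, "poly_fit")) {
    R2 <- fit$R2; n_complete <- fit$n_complete; p <- fit$K - 2L
  } else R2 <- fit
  if (is.na(R2) || n_complete <= p + 1L) return(NA_real_)
  1 - (1 - R2) * (n_complete - 1) / (n_complete - p - 1)
}

#' Chi-square likelihood-ratio gate for the omnibus full-vs-null test
#'
#' The analysis proceeds to the catalogue comparison only when the full
#' polynomial model explains significantly more outcome variance than the
#' intercept-only model.  The statistic is `2 (LL_full - LL_null)` referred
#' to a chi-square distribution with `K_full - K_null` degrees of freedom.
#'
#' @param full_fit,null_fit `"poly_fit"` objects for the Full and Null
#'   models on identical rows.
#' @param alpha Test level (default 0.05).
#' @return List with `statistic`, `df`, `p`, `proceed`.
#' @export
lr_gate <- function(full_fit, null_fit, alpha = 0.05) {
  if (full_fit$n_complete != null_fit$n_complete)
    stop("fits are not on identical rows")
  stat <- 2 * (full_fit$LL - null_fit$LL)
  if (stat < -1e-6)
    stop("full-model likelihood below null-model likelihood: internal inconsistency")
  stat <- max(stat, 0)
  df <- full_fit$K - null_fit$K
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, proceed = p < alpha, alpha = alpha)
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("%s: K = %d, LL = %.3f, n_obs = %d (complete %d), adj R2 = %s\n",
              x$name, x$K, x$LL, x$n_obs, x$n_complete,
              ifelse(is.na(x$adj_R2), "NA", sprintf("%.3f", x$adj_R2))))
  print(round(x$coefficients, 4))
  if (length(x$active_constraints))
    cat("Active constraints:", paste(x$active_constraints, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize fit results to JSON
#'
#' @param fits A `"poly_fit_list"` or a single `"poly_fit"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
fits_to_json <- function(fits, path = NULL) {
  if (inherits(fits, "poly_fit")) fits <- list(fits)
  items <- lapply(fits, function(f)
    list(name = f$name, coefficients = as.list(f$coefficients),
         sigma2 = f$sigma2, LL = f$LL, K = f$K, n_obs = f$n_obs,
         n_complete = f$n_complete, adj_R2 = f$adj_R2,
         active_constraints = f$active_constraints, converged = f$converged))
  js <- jsonlite::toJSON(unname(items), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
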