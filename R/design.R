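#' Build the polynomial design from a cohort
#'
#' Rescales all variables to the common 1--7 range (POMS, using the
#' theoretical instrument bounds stored in the cohort), centers the traits at
#' their sample means, and derives the second-order terms.  Squared and
#' product terms are computed *after* rescaling and centering.  Outcomes are
#' rescaled but not centered.  The observed range box of the centered traits
#' is recorded: all range-dependent model constraints downstream are anchored
#' to it.
#'
#' @param cohort A `"cohort"` object.
#' @param rescale Apply POMS rescaling to 1--7 (set `FALSE` if the data are
#'   already on the target scale; centering is always applied).
#' @return A `data.frame` of class `"prepared_data"` with columns `E`, `N`,
#'   `E2`, `EN`, `N2`, `L1`, `L2`, and attributes `range_box`
#'   (`e_lo`, `e_hi`, `n_lo`, `n_hi`), `means` (removed trait means) and
#'   `scales`.
#' @export
build_design <- function(cohort, rescale = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) < 10L)
    stop("fewer than 10 rows: refusing a degenerate fit")
  sc <- attr(cohort, "scales")
  tr <- function(x, s) if (rescale && !is.null(s)) poms_rescale(x, s[1L], s[2L]) else x
  E <- tr(cohort$E, sc$E)
  N <- tr(cohort$N, sc$N)
  L1 <- tr(cohort$L1, sc$L)
  L2 <- tr(cohort$L2, sc$L)
  cE <- center_scores(E)
  cN <- center_scores(N)
  E <- cE$values; N <- cN$values
  out <- data.frame(person_id = cohort$person_id,
                    E = E, N = N, E2 = E * E, EN = E * N, N2 = N * N,
                    L1 = L1, L2 = L2)
  structure(out,
            range_box = c(e_lo = min(E), e_hi = max(E),
                          n_lo = min(N), n_hi = max(N)),
            means = c(E = cE$mean, N = cN$mean),
            scales = sc,
            class = c("prepared_data", "data.frame"))
}

#' @export
print.prepared_data <- function(x, ...) {
  rb <- attr(x, "range_box")
  cat(sprintf("Prepared data: %d persons, %d with follow-up outcome\n",
              nrow(x), sum(!is.na(x$L2))))
  cat(sprintf("Centered trait range box: E [%.2f, %.2f], N [%.2f, %.2f]\n",
              rb["e_lo"], rb["e_hi"], rb["n_lo"], rb["n_hi"]))
  invisible(x)
}

range_box_of <- function(prepared) {
  rb <- attr(prepared, "range_box")
  if (is.null(rb)) stop("object carries no range box; use build_design()")
  rb
}
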