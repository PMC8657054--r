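# Candidate-model catalogue: each model is a constraint system on the
# coefficients of the full second-order polynomial
#   L = b0 + b1 E + b2 N + b3 E^2 + b4 E N + b5 N^2 (+ c_cov L1 when
# longitudinal).  A model is held as (i) a linear map from its free
# parameters to the b-space, which encodes zero restrictions and equality
# ties, and (ii) a set of linear inequality constraints A b <= 0, which
# encode direction and shape (the shape constraints are anchored to the
# observed range box so the claimed monotonicity holds over all realistic
# trait values).

B_NAMES <- c("b0", "b1", "b2", "b3", "b4", "b5")

new_model_spec <- function(name, map, A, code, range_dependent) {
  structure(list(name = name, map = map, A = A, code = code,
                 range_dependent = range_dependent,
                 longitudinal = "c_cov" %in% rownames(map),
                 K = ncol(map) + 1L),   # + residual variance
            class = "model_spec")
}

# map for a plain polynomial model: b0 plus the named free coefficients
poly_map <- function(free) {
  free <- c("b0", free)
  m <- matrix(0, nrow = 6L, ncol = length(free),
              dimnames = list(B_NAMES, free))
  m[cbind(free, free)] <- 1
  m
}

# one inequality row over the b-space; constraints are of the form w'b <= 0
ineq_row <- function(label, ...) {
  w <- stats::setNames(numeric(6L), B_NAMES)
  vals <- c(...)
  w[names(vals)] <- vals
  matrix(w, nrow = 1L, dimnames = list(label, B_NAMES))
}

shape_parts <- function(shape, trait, rb) {
  # returns list(free coefficients, inequality rows) for one trait's
  # main-effect shape; extraversion is protective (negative slope),
  # neuroticism is a risk factor (positive slope)
  lin <- if (trait == "E") "b1" else "b2"
  quad <- if (trait == "E") "b3" else "b5"
  lo <- if (trait == "E") rb[["e_lo"]] else rb[["n_lo"]]
  hi <- if (trait == "E") rb[["e_hi"]] else rb[["n_hi"]]
  sgn <- if (trait == "E") 1 else -1   # flips <= constraints for N (slope >= 0)
  pre <- if (trait == "E") "E" else "N"
  switch(shape,
    lin = list(free = lin,
               A = ineq_row(paste0(pre, ": slope sign"),
                            stats::setNames(sgn, lin))),
    sat = list(free = c(lin, quad),
               A = rbind(
                 ineq_row(paste0(pre, ": curvature opposes slope"),
                          stats::setNames(-sgn, quad)),
                 ineq_row(paste0(pre, ": slope sign at flattest end"),
                          stats::setNames(c(sgn, sgn * 2 * hi),
                                          c(lin, quad))))),
    exp = list(free = c(lin, quad),
               A = rbind(
                 ineq_row(paste0(pre, ": curvature reinforces slope"),
                          stats::setNames(sgn, quad)),
                 ineq_row(paste0(pre, ": slope sign at flattest end"),
                          stats::setNames(c(sgn, sgn * 2 * lo),
                                          c(lin, quad))))),
    stop("unknown shape: ", shape))
}

shape_adjective <- c(lin = "Linear", sat = "Saturating", exp = "Exponential")

#' Build the catalogue of 19 candidate models
#'
#' Constructs the full candidate set: the Null (intercept-only) and Full
#' (unconstrained polynomial) models; three single-trait shape models per
#' trait (linear, saturating, exponential main effect, with extraversion
#' protective and neuroticism a risk factor); the nine two-trait shape
#' combinations; and the two one-parameter interaction surfaces
#' (Mutual Compensation and Optimal Constellation).  Shape constraints are
#' anchored to the observed range box so that each model's claimed
#' monotonicity holds over the entire observed trait region.  In the
#' longitudinal variant every model additionally frees the slope of the
#' baseline outcome.
#'
#' @param range_box Named numeric `(e_lo, e_hi, n_lo, n_hi)`: observed
#'   min/max of the centered traits, as produced by [build_design()], or a
#'   `"prepared_data"` object.
#' @param longitudinal Add a freely estimated baseline-outcome slope to
#'   every model (used when the follow-up outcome is analysed).
#' @return A list of class `"model_catalog"` with 19 `"model_spec"`
#'   elements, named by model.
#' @export
build_catalog <- function(range_box, longitudinal = FALSE) {
  if (inherits(range_box, "prepared_data")) range_box <- range_box_of(range_box)
  rb <- range_box
  need <- c("e_lo", "e_hi", "n_lo", "n_hi")
  if (!all(need %in% names(rb))) stop("range_box must name ", paste(need, collapse = ", "))
  if (rb[["e_lo"]] >= rb[["e_hi"]] || rb[["n_lo"]] >= rb[["n_hi"]])
    stop("degenerate range box")

  empty_A <- matrix(numeric(0), nrow = 0L, ncol = 6L,
                    dimnames = list(NULL, B_NAMES))
  specs <- list()

  specs[["Null Model"]] <- new_model_spec(
    "Null Model", poly_map(character(0)), empty_A,
    code = list(e = "none", n = "none", int = "zero"), range_dependent = FALSE)

  specs[["Full Model"]] <- new_model_spec(
    "Full Model", poly_map(c("b1", "b2", "b3", "b4", "b5")), empty_A,
    code = list(e = "full", n = "full", int = "free"), range_dependent = FALSE)

  e_only_names <- c(lin = "Linear Main Effect of Extraversion Model",
                    sat = "Saturating Effect of Extraversion Model",
                    exp = "Exponential Effect of Extraversion Model")
  n_only_names <- c(lin = "Linear Main Effect of Neuroticism Model",
                    sat = "Saturating Effect of Neuroticism Model",
                    exp = "Exponential Effect of Neuroticism Model")

  for (sh in c("lin", "sat", "exp")) {
    pe <- shape_parts(sh, "E", rb)
    specs[[e_only_names[[sh]]]] <- new_model_spec(
      e_only_names[[sh]], poly_map(pe$free), pe$A,
      code = list(e = sh, n = "none", int = "zero"),
      range_dependent = sh != "lin")
    pn <- shape_parts(sh, "N", rb)
    specs[[n_only_names[[sh]]]] <- new_model_spec(
      n_only_names[[sh]], poly_map(pn$free), pn$A,
      code = list(e = "none", n = sh, int = "zero"),
      range_dependent = sh != "lin")
  }

  for (she in c("lin", "sat", "exp")) {
    for (shn in c("lin", "sat", "exp")) {
      nm <- if (she == "lin" && shn == "lin") "Linear Main Effects Model"
      else sprintf("%s Extraversion and %s Neuroticism Effects Model",
                   shape_adjective[[she]], shape_adjective[[shn]])
      pe <- shape_parts(she, "E", rb)
      pn <- shape_parts(shn, "N", rb)
      specs[[nm]] <- new_model_spec(
        nm, poly_map(c(pe$free, pn$free)), rbind(pe$A, pn$A),
        code = list(e = she, n = shn, int = "zero"),
        range_dependent = she != "lin" || shn != "lin")
    }
  }

  # Mutual Compensation: L = b0 + c (E - e_hi)(N - n_lo), c <= 0.
  # The outcome sits at baseline whenever E is maximal or N minimal and is
  # elevated only in the low-E/high-N corner; implies b4 = c < 0 with
  # b1 = -c n_lo, b2 = -c e_hi.
  mc_map <- matrix(0, nrow = 6L, ncol = 2L,
                   dimnames = list(B_NAMES, c("b0", "c")))
  mc_map["b0", "b0"] <- 1
  mc_map[c("b1", "b2", "b4"), "c"] <- c(-rb[["n_lo"]], -rb[["e_hi"]], 1)
  specs[["Mutual Compensation Model"]] <- new_model_spec(
    "Mutual Compensation Model", mc_map,
    ineq_row("interaction sign", b4 = 1),
    code = list(e = "mc", n = "mc", int = "mc"), range_dependent = TRUE)

  # Optimal Constellation: L = b0 + c (E - e_lo)(N - n_hi), c >= 0.
  # Outcome lowered only in the high-E/low-N corner; implies b4 = c > 0.
  oc_map <- mc_map
  oc_map[c("b1", "b2", "b4"), "c"] <- c(-rb[["n_hi"]], -rb[["e_lo"]], 1)
  specs[["Optimal Constellation Model"]] <- new_model_spec(
    "Optimal Constellation Model", oc_map,
    ineq_row("interaction sign", b4 = -1),
    code = list(e = "oc", n = "oc", int = "oc"), range_dependent = TRUE)

  if (longitudinal) specs <- lapply(specs, add_covariate)
  structure(specs, range_box = rb, longitudinal = longitudinal,
            class = "model_catalog")
}

add_covariate <- function(spec) {
  map <- rbind(spec$map, c_cov = 0)
  map <- cbind(map, c_cov = 0)
  map["c_cov", "c_cov"] <- 1
  A <- cbind(spec$A, c_cov = rep(0, nrow(spec$A)))
  new_model_spec(spec$name, map, A, spec$code, spec$range_dependent)
}

zero_set <- function(spec) {
  rows <- setdiff(rownames(spec$map), c("b0", "c_cov"))
  rows[rowSums(abs(spec$map[rows, , drop = FALSE])) == 0]
}

#' Evaluate a model's constraint system at a coefficient vector
#'
#' Checks whether a full coefficient vector satisfies the zero/equality
#' restrictions (within tolerance) and the inequality constraints of a
#' model, returning the margin of each inequality (nonnegative when
#' satisfied).  For the monotone-shape models this is equivalent to sign
#' conditions on the trait slopes at the relevant corner of the range box.
#'
#' @param spec A `"model_spec"`.
#' @param coefficients Named numeric with `b0 ... b5` (and `c_cov` when
#'   longitudinal; an absent `c_cov` is treated as free).
#' @param tol Tolerance for the equality restrictions.
#' @return List with `satisfied` (logical), `eq_residual` (distance of the
#'   coefficient vector from the model's linear subspace) and `margins`
#'   (named numeric, one per inequality; `>= 0` means satisfied).
#' @export
shape_predicate <- function(spec, coefficients, tol = 1e-8) {
  b <- coefficients
  rows <- rownames(spec$map)
  if (!"c_cov" %in% names(b) && "c_cov" %in% rows) b <- c(b, c_cov = 0)
  b <- b[rows]
  if (anyNA(b)) stop("coefficients must name ", paste(rows, collapse = ", "))
  # equality restrictions: b must lie in the column space of the map
  theta <- qr.coef(qr(spec$map), b)
  resid <- sqrt(sum((b - as.numeric(spec$map %*% theta))^2))
  margins <- if (nrow(spec$A)) -as.numeric(spec$A %*% b) else numeric(0)
  names(margins) <- rownames(spec$A)
  list(satisfied = resid <= tol && all(margins >= -tol),
       eq_residual = resid, margins = margins)
}

shape_le <- function(a, b) {
  if (a == b) return(TRUE)
  if (b == "full") return(TRUE)
  if (a == "none") return(b %in% c("lin", "sat", "exp", "full"))
  if (a == "lin") return(b %in% c("sat", "exp", "full"))
  FALSE
}

is_nested_spec <- function(a, b) {
  # TRUE when a's feasible coefficient set is strictly contained in b's
  if (a$name == b$name) return(FALSE)
  if (b$code$int == "free") return(TRUE)                  # everything in Full
  if (a$code$e == "none" && a$code$n == "none" && a$code$int == "zero")
    return(TRUE)                                          # Null in everything
  if (a$code$int %in% c("mc", "oc") || b$code$int %in% c("mc", "oc"))
    return(FALSE)
  shape_le(a$code$e, b$code$e) && shape_le(a$code$n, b$code$n)
}

#' Nesting relation of a catalogue
#'
#' Model A is nested in model B when A's feasible coefficient set is
#' contained in B's; the relation is decided structurally from the models'
#' zero sets and shape constraints and is transitively closed by
#' construction.  Every model is nested in the Full Model and the Null Model
#' is nested in every other model.
#'
#' @param catalog A `"model_catalog"`.
#' @return List with `pairs` (data.frame of `inner`, `outer`) and `matrix`
#'   (logical, `[i, j]` true when model i is nested in model j).
#' @export
nesting <- function(catalog) {
  nm <- names(catalog)
  M <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in nm) for (j in nm)
    M[i, j] <- is_nested_spec(catalog[[i]], catalog[[j]])
  idx <- which(M, arr.ind = TRUE)
  list(pairs = data.frame(inner = nm[idx[, 1L]], outer = nm[idx[, 2L]],
                          stringsAsFactors = FALSE),
       matrix = M)
}

#' Export a catalogue as JSON
#'
#' @param catalog A `"model_catalog"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
catalog_to_json <- function(catalog, path = NULL) {
  items <- lapply(catalog, function(s) {
    cons <- lapply(seq_len(nrow(s$A)), function(i) {
      w <- s$A[i, ]
      list(label = rownames(s$A)[i], weights = as.list(w[w != 0]), rhs = 0,
           relation = "<=")
    })
    list(name = s$name, K = s$K, zero_set = zero_set(s),
         free = colnames(s$map), constraints = cons,
         range_dependent = s$range_dependent)
  })
  js <- jsonlite::toJSON(unname(items), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.model_catalog <- function(x, ...) {
  cat(sprintf("Candidate-model catalogue: %d models%s\n", length(x),
              if (attr(x, "longitudinal")) " (longitudinal)" else ""))
  for (s in x)
    cat(sprintf("  %-55s K = %d, %d inequality constraint(s)\n",
                s$name, s$K, nrow(s$A)))
  invisible(x)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model: %s (K = %d)\n", x$name, x$K))
  zs <- zero_set(x)
  if (length(zs)) cat("  fixed at zero:", paste(zs, collapse = ", "), "\n")
  cat("  free parameters:", paste(colnames(x$map), collapse = ", "),
      "+ residual variance\n")
  if (nrow(x$A))
    for (i in seq_len(nrow(x$A))) {
      w <- x$A[i, ]; w <- w[w != 0]
      cat(sprintf("  %s: %s <= 0\n", rownames(x$A)[i],
                  paste(sprintf("%+.3g %s", w, names(w)), collapse = " ")))
    }
  invisible(x)
}
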