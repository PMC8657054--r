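#' Second-order Akaike information criterion
#'
#' `AICc = -2 LL + 2 K + 2 K (K + 1) / (n - K - 1)`.  The sample size `n` is
#' the number of retained persons (all rows entering the likelihood,
#' including those with a missing follow-up outcome), matching the
#' full-information estimation contract.
#'
#' @param LL Maximized log-likelihood.
#' @param K Number of estimated parameters (including the residual variance).
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(LL, K, n) {
  if (any(n <= K + 1)) stop("AICc undefined: n must exceed K + 1")
  -2 * LL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' Normalized model likelihoods `exp(-delta/2)` with `delta = AICc - min
#' AICc`; the weight of a model is the likelihood that it is the best model
#' in the candidate set.  Invariant under adding a constant to all AICc
#' values.
#'
#' @param aiccs Numeric vector of AICc values (all finite).
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) == 0L) stop("no AICc values supplied")
  if (any(!is.finite(aiccs))) stop("all AICc values must be finite")
  rel <- exp(-(aiccs - min(aiccs)) / 2)
  rel / sum(rel)
}

#' Evidence ratio of two models
#'
#' @param w_i,w_j Akaike weights.
#' @return `w_i / w_j`; `Inf` when `w_j` is zero.
#' @export
evidence_ratio <- function(w_i, w_j) {
  if (w_j == 0) return(Inf)
  w_i / w_j
}

#' Remove redundant models before computing Akaike weights
#'
#' When the maximized log-likelihood of a more complex model exceeds that of
#' a model nested within it by less than `threshold` (default 1), the extra
#' parameters buy essentially no fit and the more complex model is excluded.
#' Models are processed in order of increasing complexity (`K`, ties broken
#' by catalogue order): each retained simpler model is compared against
#' every more complex model that nests it, so the rule is deterministic.
#'
#' @param fits Named list of `"poly_fit"` objects.
#' @param nesting_rel Result of [nesting()] for the same catalogue.
#' @param threshold Log-likelihood gain below which the more complex model
#'   is dropped.
#' @return List with `retained` (character), `excluded` (character) and
#'   `log` (data.frame of exclusions with the triggering nested pair and
#'   log-likelihood gain).
#' @export
prune_redundant <- function(fits, nesting_rel, threshold = 1) {
  nm <- names(fits)
  Ks <- vapply(fits, `[[`, numeric(1), "K")
  LLs <- vapply(fits, `[[`, numeric(1), "LL")
  ord <- nm[order(Ks)]
  M <- nesting_rel$matrix
  retained <- nm
  log <- data.frame(simple = character(0), complex = character(0),
                    gain = numeric(0), stringsAsFactors = FALSE)
  for (a in ord) {
    if (!a %in% retained) next
    outers <- nm[M[a, ]]
    for (b in intersect(outers, retained)) {
      gain <- LLs[[b]] - LLs[[a]]
      if (gain < threshold) {
        retained <- setdiff(retained, b)
        log <- rbind(log, data.frame(simple = a, complex = b, gain = gain,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  list(retained = retained, excluded = setdiff(nm, retained), log = log)
}

#' Confidence set of models
#'
#' The smallest AICc-ordered prefix of models whose cumulative Akaike weight
#' exceeds `level`.
#'
#' @param weights Numeric weights in AICc order (best model first).
#' @param level Cumulative-weight level (default 0.95).
#' @return Integer indices of the models in the confidence set.
#' @export
confidence_set <- function(weights, level = 0.95) {
  cum <- cumsum(weights)
  seq_len(which(cum > level)[1L])
}

#' Build the model-comparison table
#'
#' Turns a set of fitted candidate models into the full comparison product:
#' AICc per model, redundancy pruning of nested near-duplicates, Akaike
#' weights over the retained set, the confidence set, and adjusted R2.
#'
#' @param fits A `"poly_fit_list"` (or named list of `"poly_fit"`).
#' @param catalog The `"model_catalog"` the fits came from (used for the
#'   nesting relation); may be omitted when `fits` carry their specs.
#' @param level Confidence-set level (default 0.95).
#' @param threshold Redundancy log-likelihood threshold (default 1).
#' @param renormalize Also report weights renormalized within the confidence
#'   set (`w_set` column), the convention used when a table lists only the
#'   confidence set.
#' @return A `data.frame` of class `"comparison_table"`, sorted by AICc,
#'   with columns `model`, `K`, `LL`, `AICc`, `delta`, `weight`,
#'   `cum_weight`, `in_confidence_set`, `redundant_excluded`, `adj_R2` (and
#'   `w_set` when `renormalize`).  Excluded models keep their AICc but carry
#'   `NA` weights.  The exclusion log is in `attr(, "exclusions")`.
#' @export
compare_models <- function(fits, catalog = NULL, level = 0.95, threshold = 1,
                           renormalize = FALSE) {
  if (is.null(catalog)) {
    specs <- lapply(fits, `[[`, "spec")
    class(specs) <- "model_catalog"
    attr(specs, "longitudinal") <- any(vapply(specs, `[[`, logical(1), "longitudinal"))
    catalog <- specs
  }
  if (!all(vapply(fits, `[[`, logical(1), "converged")))
    warning("non-converged fits present; their rows are flagged")
  nest <- nesting(catalog)
  pr <- prune_redundant(fits, nest, threshold = threshold)

  tab <- data.frame(
    model = names(fits),
    K = vapply(fits, `[[`, numeric(1), "K"),
    LL = vapply(fits, `[[`, numeric(1), "LL"),
    n = vapply(fits, `[[`, numeric(1), "n_obs"),
    adj_R2 = vapply(fits, `[[`, numeric(1), "adj_R2"),
    stringsAsFactors = FALSE)
  tab$AICc <- aicc(tab$LL, tab$K, tab$n)
  tab$redundant_excluded <- !(tab$model %in% pr$retained)

  ret <- tab[!tab$redundant_excluded, , drop = FALSE]
  ret <- ret[order(ret$AICc), , drop = FALSE]
  ret$delta <- ret$AICc - min(ret$AICc)
  ret$weight <- akaike_weights(ret$AICc)
  ret$cum_weight <- cumsum(ret$weight)
  ret$in_confidence_set <- FALSE
  ret$in_confidence_set[confidence_set(ret$weight, level)] <- TRUE
  if (renormalize) {
    ret$w_set <- NA_real_
    cs <- ret$in_confidence_set
    ret$w_set[cs] <- ret$weight[cs] / sum(ret$weight[cs])
  }

  exc <- tab[tab$redundant_excluded, , drop = FALSE]
  if (nrow(exc)) {
    exc <- exc[order(exc$AICc), , drop = FALSE]
    exc$delta <- exc$AICc - min(ret$AICc)
    exc$weight <- NA_real_
    exc$cum_weight <- NA_real_
    exc$in_confidence_set <- FALSE
    if (renormalize) exc$w_set <- NA_real_
  }
  out <- rbind(ret, exc)
  cols <- c("model", "K", "LL", "AICc", "delta", "weight", "cum_weight",
            "in_confidence_set", "redundant_excluded", "adj_R2",
            if (renormalize) "w_set")
  out <- out[, cols]
  rownames(out) <- NULL
  structure(out, exclusions = pr$log, level = level, threshold = threshold,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison (confidence level %.2f, redundancy threshold %g)\n",
              attr(x, "level"), attr(x, "threshold")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  exc <- attr(x, "exclusions")
  if (nrow(exc)) {
    cat("\nRedundancy exclusions (complex model dropped):\n")
    print(exc, row.names = FALSE)
  }
  invisible(x)
}

#' Export a comparison table
#'
#' @param table A `"comparison_table"`.
#' @param csv,json Optional output file paths.
#' @return The table, invisibly.
#' @export
export_comparison <- function(table, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(table = as.data.frame(table),
                              exclusions = attr(table, "exclusions")),
                         json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(table)
}
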