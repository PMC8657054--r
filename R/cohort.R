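#' Construct a cohort table
#'
#' A cohort is a person-level `data.frame` with trait scores at baseline
#' (extraversion `E`, neuroticism `N`), the outcome at baseline (`L1`) and
#' optionally at follow-up (`L2`, missing values allowed), together with the
#' theoretical bounds of each instrument scale.  Rows missing `L1`, `E` or `N`
#' are dropped (with counts recorded as attributes); only the follow-up
#' outcome may remain missing, since the likelihood machinery downstream
#' handles it.
#'
#' @param data A data.frame with columns `E`, `N`, `L1` and optionally `L2`
#'   and `person_id`.
#' @param scales Named list of length-2 numeric vectors giving the
#'   theoretical `(min, max)` of the `E`, `N` and `L` instruments.
#' @return A `data.frame` of class `"cohort"` with columns `person_id`, `E`,
#'   `N`, `L1`, `L2`, scale bounds in `attr(, "scales")` and dropped-row
#'   counts in `attr(, "dropped")`.
#' @export
cohort <- function(data,
                   scales = list(E = c(1, 7), N = c(1, 7), L = c(1, 7))) {
  stopifnot(is.data.frame(data))
  need <- c("E", "N", "L1")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$L2)) data$L2 <- NA_real_
  if (is.null(data$person_id)) data$person_id <- seq_len(nrow(data))
  for (s in scales) {   # a NULL scale means: unbounded, already on target scale
    if (!is.null(s) && (length(s) != 2L || s[1L] >= s[2L]))
      stop("each scale must be (min, max) with min < max, or NULL")
  }

  drop_l1 <- is.na(data$L1)
  drop_en <- !drop_l1 & (is.na(data$E) | is.na(data$N))
  keep <- !(drop_l1 | drop_en)
  out <- data[keep, c("person_id", "E", "N", "L1", "L2")]
  rownames(out) <- NULL

  chk <- function(x, bounds, what) {
    if (is.null(bounds)) return(invisible())
    bad <- !is.na(x) & (x < bounds[1L] | x > bounds[2L])
    if (any(bad))
      stop(sprintf("%s outside its scale [%g, %g] at row(s) %s", what,
                   bounds[1L], bounds[2L],
                   paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  chk(out$E, scales$E, "E")
  chk(out$N, scales$N, "N")
  chk(out$L1, scales$L, "L1")
  chk(out$L2, scales$L, "L2")

  structure(out, scales = scales,
            dropped = c(missing_L1 = sum(drop_l1), missing_EN = sum(drop_en)),
            class = c("cohort", "data.frame"))
}

#' Read a cohort from a CSV file
#'
#' @param path Path to a CSV file with a header row.
#' @param config Column mapping and scale bounds: either a list with elements
#'   `columns` (named list mapping `E`, `N`, `L1`, and optionally `L2`,
#'   `person_id`, to column names in the file), `scales` (as in [cohort()])
#'   and `na` (strings treated as missing, default empty cell and `"NA"`), or
#'   the path to a YAML/JSON file holding that list.  Defaults assume the
#'   canonical column names and 1--7 scales.
#' @return A `"cohort"` object.
#' @export
read_cohort <- function(path, config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cols <- utils::modifyList(
    list(E = "E", N = "N", L1 = "L1", L2 = "L2", person_id = "person_id"),
    as.list(config$columns %||% list()))
  scales <- utils::modifyList(list(E = c(1, 7), N = c(1, 7), L = c(1, 7)),
                              lapply(as.list(config$scales %||% list()), as.numeric))
  na_strings <- config$na %||% c("", "NA")

  raw <- utils::read.csv(path, na.strings = na_strings, check.names = FALSE)
  pick <- function(nm) if (!is.null(cols[[nm]]) && cols[[nm]] %in% names(raw)) raw[[cols[[nm]]]] else NULL
  df <- data.frame(E = as.numeric(pick("E")), N = as.numeric(pick("N")),
                   L1 = as.numeric(pick("L1")))
  l2 <- pick("L2"); if (!is.null(l2)) df$L2 <- as.numeric(l2)
  id <- pick("person_id"); if (!is.null(id)) df$person_id <- id
  cohort(df, scales = scales)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
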