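#' Fit the design-matrix encoding on training rows
#'
#' Categorical variables expand to full one-hot indicators (one column per
#' schema category, no reference level dropped — the downstream ridge
#' penalty absorbs the collinearity); numeric columns are z-scored with
#' training-row statistics (population-SD convention, divide by N). A
#' zero-variance numeric column is recorded with a unit-SD sentinel and
#' flagged, so its standardized values are all zero.
#'
#' @param train a complete (post-imputation) [cohort_table()].
#' @return an `encoding_ledger` with `onehot_maps`, `numeric_stats`,
#'   `column_names` and `zero_variance` flags.
#' @export
fit_encoding <- function(train) {
  stopifnot(inherits(train, "cohort_table"))
  schema <- train$schema
  if (any(is.na(as.matrix(train$values))))
    stop("fit_encoding requires a complete (imputed) cohort")

  onehot_maps <- list()
  numeric_stats <- list()
  column_names <- character(0)
  zero_variance <- character(0)

  for (v in schema$variables) {
    if (v$kind == "categorical") {
      cols <- paste0(v$name, "=", v$categories)
      onehot_maps[[v$name]] <- setNames(seq_along(v$categories) - 1L +
                                          length(column_names) + 1L,
                                        v$categories)
      column_names <- c(column_names, cols)
    } else {
      for (el in element_names(v)) {
        x <- train$values[[el]]
        mu <- mean(x)
        sdv <- sqrt(mean((x - mu)^2))      # population convention
        if (sdv == 0) {
          zero_variance <- c(zero_variance, el)
          sdv <- 1                         # sentinel: output all zeros
        }
        numeric_stats[[el]] <- c(mean = mu, sd = sdv)
        column_names <- c(column_names, el)
      }
    }
  }

  structure(list(schema = schema, onehot_maps = onehot_maps,
                 numeric_stats = numeric_stats,
                 column_names = column_names,
                 zero_variance = zero_variance),
            class = "encoding_ledger")
}

#' Encode a complete cohort into a design matrix and target vector
#'
#' @param ledger an `encoding_ledger` from [fit_encoding()].
#' @param cohort a complete [cohort_table()]; categories should be known to
#'   the ledger (an unseen category yields all-zero indicators for that
#'   variable, with a warning).
#' @return list with `X` (N x n numeric matrix, n = 73 under the default
#'   schema), `y` (integer 0/1 target vector) and `pid`.
#' @export
encode <- function(ledger, cohort) {
  stopifnot(inherits(ledger, "encoding_ledger"),
            inherits(cohort, "cohort_table"))
  schema <- ledger$schema
  if (any(is.na(as.matrix(cohort$values))))
    stop("encode requires a complete (imputed) cohort")
  n <- nrow(cohort$values)
  X <- matrix(0, n, length(ledger$column_names),
              dimnames = list(NULL, ledger$column_names))

  for (v in schema$variables) {
    if (v$kind == "categorical") {
      x <- cohort$values[[v$name]]
      unseen <- !(x %in% v$categories)
      if (any(unseen))
        warning("unseen category in variable '", v$name, "': ",
                paste(unique(x[unseen]), collapse = ", "),
                " (encoded as all-zero indicators)")
      for (cat in v$categories)
        X[, paste0(v$name, "=", cat)] <- as.numeric(x == cat)
    } else {
      for (el in element_names(v)) {
        st <- ledger$numeric_stats[[el]]
        X[, el] <- (cohort$values[[el]] - st[["mean"]]) / st[["sd"]]
      }
    }
  }
  list(X = X, y = cohort$labels, pid = cohort$pid)
}
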