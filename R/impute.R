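#' Winsorized mean
#'
#' Robust location estimate: with `m = floor(alpha * n)`, the `m` smallest
#' values are replaced by the `(m+1)`-th smallest and the `m` largest by the
#' `(m+1)`-th largest before averaging. `alpha = 0` gives the arithmetic
#' mean.
#'
#' @param values non-empty vector of finite numbers.
#' @param alpha per-tail replacement fraction in \[0, 0.5).
#' @return the Winsorized mean (scalar).
#' @export
winsorized_mean <- function(values, alpha = 0.10) {
  if (length(values) == 0L) stop("winsorized_mean: empty input")
  if (any(!is.finite(values))) stop("winsorized_mean: non-finite input")
  if (alpha < 0 || alpha >= 0.5) stop("winsorized_mean: alpha must be in [0, 0.5)")
  n <- length(values)
  m <- floor(alpha * n)
  x <- sort(values)
  if (m > 0L) {
    x[seq_len(m)] <- x[m + 1L]
    x[seq(n - m + 1L, n)] <- x[n - m]
  }
  mean(x)
}

#' Imputation strategy specification
#'
#' @param numeric_method one of `"zero"`, `"mean"`, `"median"`, `"wmean"`,
#'   `"knn"`, `"em"`. Categorical gaps are always filled with the training
#'   mode, whatever the numeric method.
#' @param alpha Winsorization fraction for `"wmean"` (default 0.10).
#' @param k neighbour count for `"knn"` (default 5).
#' @param em_tol convergence tolerance on the change in observed-data
#'   log-likelihood (default 1e-6).
#' @param em_max_iter iteration cap for EM (default 200).
#' @param em_ridge diagonal regularization added to the EM covariance
#'   (default 1e-6).
#' @param fallback_fill constant used for numeric columns with zero
#'   observed training values (default 0, with a warning at fit time).
#' @return an `imputer_spec` object.
#' @export
imputer_spec <- function(numeric_method = c("zero", "mean", "median",
                                            "wmean", "knn", "em"),
                         alpha = 0.10, k = 5L, em_tol = 1e-6,
                         em_max_iter = 200L, em_ridge = 1e-6,
                         fallback_fill = 0) {
  numeric_method <- match.arg(numeric_method)
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)")
  if (k < 1L) stop("k must be >= 1")
  if (em_tol <= 0) stop("em_tol must be > 0")
  structure(list(numeric_method = numeric_method, alpha = alpha,
                 k = as.integer(k), em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter),
                 em_ridge = em_ridge, fallback_fill = fallback_fill),
            class = "imputer_spec")
}

# modal category of observed values, ties broken lexicographically
modal_category <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1L]
}

#' Fit an imputer on training rows
#'
#' Computes categorical modes (equal-weight over non-missing training
#' values, ties broken lexicographically) and the numeric state of the
#' chosen strategy: constant fills (zero/mean/median/Winsorized mean), the
#' training numeric matrix (KNN), or a multivariate-normal `(mu, Sigma)`
#' maximizing the observed-data likelihood via EM.
#'
#' @param train a [cohort_table()] of training rows.
#' @param spec an [imputer_spec()].
#' @return a `fitted_imputer` object, to be applied with `predict()`.
#' @export
fit_imputer <- function(train, spec = imputer_spec()) {
  stopifnot(inherits(train, "cohort_table"), inherits(spec, "imputer_spec"))
  schema <- train$schema

  modes <- vapply(categorical_variable_names(schema),
                  function(v) modal_category(train$values[[v]]),
                  character(1))
  if (any(is.na(modes)))
    stop("categorical variable(s) with no observed training values: ",
         paste(names(modes)[is.na(modes)], collapse = ", "))

  num_cols <- numeric_column_names(schema)
  X <- as.matrix(train$values[num_cols])
  n_obs <- colSums(!is.na(X))
  dead <- num_cols[n_obs == 0L]
  if (length(dead))
    warning("numeric column(s) entirely missing in training data, ",
            "using fallback fill ", spec$fallback_fill, ": ",
            paste(dead, collapse = ", "))
  live <- num_cols[n_obs > 0L]

  col_means <- colMeans(X, na.rm = TRUE)
  col_means[dead] <- spec$fallback_fill

  state <- switch(spec$numeric_method,
    zero = list(fill = setNames(rep(0, length(num_cols)), num_cols)),
    mean = list(fill = col_means),
    median = {
      f <- apply(X, 2, median, na.rm = TRUE)
      f[dead] <- spec$fallback_fill
      list(fill = f)
    },
    wmean = {
      f <- vapply(num_cols, function(cl) {
        x <- X[, cl]
        x <- x[!is.na(x)]
        if (!length(x)) spec$fallback_fill
        else winsorized_mean(x, spec$alpha)
      }, numeric(1))
      list(fill = f)
    },
    knn = list(train_matrix = X, col_means = col_means),
    em = {
      fit <- em_mvnorm(X[, live, drop = FALSE], tol = spec$em_tol,
                       max_iter = spec$em_max_iter, ridge = spec$em_ridge)
      list(em = fit, live = live, col_means = col_means)
    })

  structure(list(spec = spec, schema = schema, modes = modes,
                 numeric_state = state, dead_columns = dead,
                 col_means = col_means),
            class = "fitted_imputer")
}

#' Fill every missing cell of a cohort
#'
#' Observed cells pass through untouched; categorical gaps get the training
#' mode; numeric gaps are filled per the fitted strategy (constant fill,
#' mean of the k nearest training rows under the partial Euclidean
#' distance, or the conditional expectation of the missing coordinates
#' given the observed ones under the fitted Gaussian).
#'
#' @param object a `fitted_imputer` from [fit_imputer()].
#' @param cohort a [cohort_table()] conforming to the imputer's schema.
#' @param ... unused.
#' @return a complete [cohort_table()] (no missing cells).
#' @export
predict.fitted_imputer <- function(object, cohort, ...) {
  stopifnot(inherits(cohort, "cohort_table"))
  vals <- cohort$values
  for (v in names(object$modes)) {
    na <- is.na(vals[[v]])
    if (any(na)) vals[[v]][na] <- object$modes[[v]]
  }

  num_cols <- numeric_column_names(object$schema)
  X <- as.matrix(vals[num_cols])
  st <- object$numeric_state
  method <- object$spec$numeric_method

  if (method %in% c("zero", "mean", "median", "wmean")) {
    for (cl in num_cols) {
      na <- is.na(X[, cl])
      if (any(na)) X[na, cl] <- st$fill[[cl]]
    }
  } else if (method == "knn") {
    X <- knn_impute(X, st$train_matrix, object$spec$k, st$col_means,
                    fallback = object$col_means)
  } else {  # em
    X <- em_impute(X, st$em$mu, st$em$sigma, st$live, object$col_means)
  }

  vals[num_cols] <- as.data.frame(X, check.names = FALSE)
  cohort_table(vals, cohort$labels, object$schema, pid = cohort$pid)
}

# partial Euclidean distance: squared distance over mutually observed
# numeric coordinates, scaled to the full dimension by p / n_shared
partial_distances <- function(x, obs_x, train, train_obs) {
  p <- length(x)
  shared <- train_obs & matrix(obs_x, nrow(train), p, byrow = TRUE)
  n_shared <- rowSums(shared)
  diff <- sweep(train, 2, x)
  diff[!shared | is.na(diff)] <- 0
  d2 <- rowSums(diff^2) * p / pmax(n_shared, 1L)
  d2[n_shared == 0L] <- Inf
  sqrt(d2)
}

knn_impute <- function(X, train, k, train_col_means, fallback) {
  obs <- !is.na(X)
  train_obs <- !is.na(train)
  rows_missing <- which(rowSums(!obs) > 0L)
  for (i in rows_missing) {
    if (!any(obs[i, ])) {
      # no observed numeric coordinate: fall back to training column means
      message("knn imputation: row with all numeric values missing, ",
              "falling back to column means")
      X[i, ] <- fallback
      next
    }
    d <- partial_distances(X[i, ], obs[i, ], train, train_obs)
    for (j in which(!obs[i, ])) {
      cand <- which(train_obs[, j] & is.finite(d))
      if (!length(cand)) {
        X[i, j] <- fallback[j]
        next
      }
      nn <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      X[i, j] <- mean(train[nn, j])
    }
  }
  X
}

# conditional expectation of missing coordinates under N(mu, sigma),
# restricted to the columns the EM model covers; dead columns get the
# fallback constant
em_impute <- function(X, mu, sigma, live, fallback) {
  dead <- setdiff(colnames(X), live)
  for (j in dead) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- fallback[j]
  }
  Xl <- X[, live, drop = FALSE]
  obs <- !is.na(Xl)
  key <- apply(obs, 1, paste, collapse = "")
  for (pat in unique(key)) {
    rows <- which(key == pat)
    o <- obs[rows[1L], ]
    if (all(o)) next
    m <- !o
    if (!any(o)) {
      Xl[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE)
      next
    }
    ch <- chol(sigma[o, o, drop = FALSE])
    B <- backsolve(ch, forwardsolve(t(ch), sigma[o, m, drop = FALSE]))
    dev <- Xl[rows, o, drop = FALSE] -
      matrix(mu[o], length(rows), sum(o), byrow = TRUE)
    Xl[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
      dev %*% B
  }
  X[, live] <- Xl
  X
}

#' Multivariate-normal EM on an incomplete matrix
#'
#' Maximizes the observed-data Gaussian log-likelihood by
#' expectation-maximization: the E-step fills each row's missing block with
#' its conditional mean and accumulates the conditional covariance; the
#' M-step re-estimates `mu` and `Sigma` (maximum-likelihood `1/n`
#' convention) with `ridge` added to the diagonal for stability under
#' near-singular patterns. Columns are standardized internally by their
#' observed SD so the ridge acts relative to each column's variance; the
#' returned parameters and log-likelihood are on the original scale.
#' Iterates until the absolute log-likelihood change drops below `tol` or
#' `max_iter` is reached.
#'
#' @param X numeric matrix with `NA` for missing entries; every column
#'   needs at least one observed value.
#' @param tol,max_iter,ridge see [imputer_spec()].
#' @return list with `mu`, `sigma`, `loglik` (per-iteration observed-data
#'   log-likelihood trace), `iterations`, `converged`.
#' @export
em_mvnorm <- function(X, tol = 1e-6, max_iter = 200L, ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0L))
    stop("em_mvnorm: column with zero observed values")

  # internal standardization: EM is exactly equivariant under per-column
  # scaling, and a unit scale makes the covariance ridge meaningful
  sc <- apply(X, 2, function(x) {
    x <- x[!is.na(x)]
    s <- sqrt(mean((x - mean(x))^2))
    if (s > 0) s else 1
  })
  Xs <- sweep(X, 2, sc, "/")
  Xs[!obs] <- 0   # placeholder, ignored through the obs mask
  ll_shift <- -sum(log(sc) * colSums(obs))

  mu <- colSums(Xs * obs) / colSums(obs)
  v <- vapply(seq_len(p), function(j) {
    x <- Xs[obs[, j], j]
    mean((x - mean(x))^2)
  }, numeric(1))
  sigma <- diag(pmax(v, ridge), p)

  storage.mode(obs) <- "integer"
  fit <- em_fit_cpp(Xs, obs, mu, sigma, tol, as.integer(max_iter), ridge)

  mu <- as.numeric(fit$mu) * sc
  sigma <- fit$sigma * tcrossprod(sc)
  names(mu) <- colnames(X)
  dimnames(sigma) <- list(colnames(X), colnames(X))
  list(mu = mu, sigma = sigma, loglik = fit$loglik + ll_shift,
       iterations = length(fit$loglik), converged = fit$converged)
}
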