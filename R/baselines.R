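#' Thin adapters around established baseline classifiers
#'
#' Optional comparators for the rank analysis; their internals live in the
#' wrapped packages. Each returns a [baseline_model_spec()] whose grid is
#' tuned by the same stratified cross-validation as the RVFL variants.
#'
#' @param k_grid,cost_grid,ntree tuning grids / settings.
#' @return a [baseline_model_spec()].
#' @name baselines
NULL

#' @rdname baselines
#' @export
baseline_logistic <- function() {
  baseline_model_spec(
    "logistic",
    fit = function(X, y, params) {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      df$.y <- y
      suppressWarnings(glm(.y ~ ., binomial(), df))
    },
    predict = function(fit, X) {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      as.integer(predict(fit, df, type = "response") >= 0.5)
    })
}

#' @rdname baselines
#' @export
baseline_svm <- function(cost_grid = c(0.5, 0.75, 1, 1.25, 1.5)) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("baseline_svm requires the e1071 package")
  baseline_model_spec(
    "svm",
    fit = function(X, y, params) {
      # balanced class weights: n / (2 * n_class)
      w <- length(y) / (2 * table(factor(y, levels = 0:1)))
      e1071::svm(X, factor(y, levels = 0:1), cost = params$cost,
                 class.weights = w)
    },
    predict = function(fit, X)
      as.integer(as.character(predict(fit, X))),
    grid = data.frame(cost = cost_grid))
}

#' @rdname baselines
#' @export
baseline_random_forest <- function(ntree = 151L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("baseline_random_forest requires the randomForest package")
  baseline_model_spec(
    "random_forest",
    fit = function(X, y, params)
      randomForest::randomForest(X, factor(y, levels = 0:1),
                                 ntree = params$ntree),
    predict = function(fit, X)
      as.integer(as.character(predict(fit, X))),
    grid = data.frame(ntree = ntree))
}

#' @rdname baselines
#' @export
baseline_knn <- function(k_grid = c(1L, 5L, 15L, 25L)) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("baseline_knn requires the e1071 package")
  baseline_model_spec(
    "knn",
    fit = function(X, y, params)
      e1071::gknn(X, factor(y, levels = 0:1), k = params$k),
    predict = function(fit, X)
      as.integer(as.character(predict(fit, X))),
    grid = data.frame(k = k_grid))
}
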