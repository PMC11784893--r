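#' RVFL network configuration
#'
#' Hyperparameters for the three randomized functional-link variants. The
#' hidden weights are drawn uniformly on `weight_range` and the biases on
#' `bias_range`; they are fixed after initialization and only the output
#' weights are learned, by a closed-form ridge solve.
#'
#' @param h hidden (enhancement) neurons per layer.
#' @param L number of hidden layers (1 for plain RVFL).
#' @param eta ridge regularization >= 0.
#' @param activation `"relu"` (default) or `"sigmoid"`.
#' @param weight_range,bias_range uniform sampling ranges, default
#'   `c(-1, 1)` and `c(0, 1)`.
#' @param seed master seed; one independent stream per layer is derived
#'   from it.
#' @param aggregation ensemble rule for the deep ensemble variant:
#'   `"mean_score"` (default) averages base-model scores before
#'   thresholding; `"majority_vote"` thresholds each base model at 0.5 and
#'   takes the modal vote (ties toward label 1).
#' @param threshold decision cutoff on the (mean) score, default 0.5.
#' @return an `rvfl_config` object.
#' @export
rvfl_config <- function(h = 100L, L = 1L, eta = 2^-6,
                        activation = c("relu", "sigmoid"),
                        weight_range = c(-1, 1), bias_range = c(0, 1),
                        seed = 1L,
                        aggregation = c("mean_score", "majority_vote"),
                        threshold = 0.5) {
  activation <- match.arg(activation)
  aggregation <- match.arg(aggregation)
  h <- as.integer(h); L <- as.integer(L)
  if (h < 1L) stop("h must be >= 1")
  if (L < 1L) stop("L must be >= 1")
  if (eta < 0) stop("eta must be >= 0")
  if (weight_range[1] >= weight_range[2]) stop("invalid weight_range")
  if (bias_range[1] > bias_range[2]) stop("invalid bias_range")
  structure(list(h = h, L = L, eta = eta, activation = activation,
                 weight_range = weight_range, bias_range = bias_range,
                 seed = as.integer(seed), aggregation = aggregation,
                 threshold = threshold),
            class = "rvfl_config")
}

activation_fun <- function(name) {
  switch(name,
         relu = function(z) pmax(z, 0),
         sigmoid = function(z) 1 / (1 + exp(-z)))
}

#' Initialize the fixed random hidden layers
#'
#' Layer 1 takes the `n_input` original features. For deeper layers the
#' input width follows the variant: the stacked deep network feeds only the
#' previous hidden activations (`h`), while each deep-ensemble layer feeds
#' the previous activations concatenated with the original features
#' (`h + n_input`).
#'
#' @param config an [rvfl_config()].
#' @param n_input number of input features.
#' @param variant `"rvfl"`, `"drvfl"` or `"edrvfl"`.
#' @return list of layers, each with matrices `W` (in-width x h) and bias
#'   vector `b` (length h).
#' @export
init_layers <- function(config, n_input, variant = c("rvfl", "drvfl",
                                                     "edrvfl")) {
  variant <- match.arg(variant)
  stopifnot(n_input >= 1L)
  L <- if (variant == "rvfl") 1L else config$L
  seeds <- derive_seeds(config$seed, L)
  lapply(seq_len(L), function(l) {
    in_w <- if (l == 1L) n_input
            else if (variant == "drvfl") config$h
            else config$h + n_input
    with_seed(seeds[l], {
      W <- matrix(runif(in_w * config$h, config$weight_range[1],
                        config$weight_range[2]), in_w, config$h)
      b <- runif(config$h, config$bias_range[1], config$bias_range[2])
      list(W = W, b = b)
    })
  })
}

#' Forward pass through the fixed hidden layers
#'
#' `H1 = g(X W1 + 1 b1')`; deeper layers follow the variant rule (previous
#' activations only for the stacked deep network, previous activations plus
#' the original features for the deep ensemble). `D` is the concatenation
#' `[H1 ... HL X]` used as the solve matrix for the rvfl/drvfl variants.
#'
#' @param X numeric design matrix (finite entries).
#' @param layers output of [init_layers()].
#' @param variant `"rvfl"`, `"drvfl"` or `"edrvfl"`.
#' @param activation activation name.
#' @return list with `H_list` (per-layer activation matrices) and `D`.
#' @export
forward_hidden <- function(X, layers, variant = c("rvfl", "drvfl", "edrvfl"),
                           activation = "relu") {
  variant <- match.arg(variant)
  g <- activation_fun(activation)
  H_list <- vector("list", length(layers))
  inp <- X
  for (l in seq_along(layers)) {
    W <- layers[[l]]$W
    if (ncol(inp) != nrow(W))
      stop("layer ", l, " width mismatch: input has ", ncol(inp),
           " columns, W expects ", nrow(W))
    Z <- inp %*% W
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    H_list[[l]] <- g(Z)
    inp <- if (variant == "edrvfl") cbind(H_list[[l]], X) else H_list[[l]]
  }
  list(H_list = H_list, D = do.call(cbind, c(H_list, list(X))))
}

#' Closed-form ridge solve
#'
#' Returns the minimizer of `||M beta - Y||^2 / 2 + eta ||beta||^2 / 2`.
#' The primal form `(M'M + eta I)^{-1} M'Y` is used when columns <= rows
#' and the algebraically identical dual form `M'(MM' + eta I)^{-1} Y`
#' otherwise. At `eta = 0` a singular system falls back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param M feature matrix (rows = samples).
#' @param Y target matrix (or vector, treated as one column).
#' @param eta ridge penalty >= 0.
#' @return coefficient matrix `beta`, `ncol(M)` x `ncol(Y)`.
#' @export
ridge_solve <- function(M, Y, eta) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  stopifnot(nrow(M) == nrow(Y), eta >= 0)
  p <- ncol(M); n <- nrow(M)
  if (eta > 0) {
    if (p <= n) {
      solve(crossprod(M) + diag(eta, p), crossprod(M, Y))
    } else {
      crossprod(M, solve(tcrossprod(M) + diag(eta, n), Y))
    }
  } else {
    tryCatch(
      solve(crossprod(M), crossprod(M, Y)),
      error = function(e) {
        warning("singular system at eta = 0; using pseudo-inverse")
        MASS::ginv(M) %*% Y
      })
  }
}

#' Fit a randomized functional-link classifier
#'
#' All three variants keep the random hidden parameters fixed and solve
#' only for output weights: the plain network solves once on `[H1 X]`, the
#' stacked deep network once on `[H1 ... HL X]`, and the deep ensemble
#' solves one base model per layer on `[Hl X]` (each base model sees its
#' own randomized features plus the original features through direct
#' links).
#'
#' @param X numeric design matrix.
#' @param y 0/1 target vector (row-aligned with `X`).
#' @param config an [rvfl_config()].
#' @param variant `"rvfl"`, `"drvfl"` or `"edrvfl"`.
#' @return a `fitted_rvfl` object.
#' @export
rvfl_fit <- function(X, y, config = rvfl_config(),
                     variant = c("rvfl", "drvfl", "edrvfl")) {
  variant <- match.arg(variant)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L)
    warning("training data contains a single class")
  Y <- matrix(as.numeric(y), ncol = 1L)
  layers <- init_layers(config, ncol(X), variant)
  fwd <- forward_hidden(X, layers, variant, config$activation)
  betas <- switch(variant,
    rvfl = list(ridge_solve(fwd$D, Y, config$eta)),
    drvfl = list(ridge_solve(fwd$D, Y, config$eta)),
    edrvfl = lapply(fwd$H_list, function(H)
      ridge_solve(cbind(H, X), Y, config$eta)))
  structure(list(variant = variant, layers = layers, betas = betas,
                 config = config, n_input = ncol(X),
                 depth = length(layers)),
            class = "fitted_rvfl")
}

#' @export
print.fitted_rvfl <- function(x, ...) {
  cat("fitted_rvfl:", x$variant, "- h =", x$config$h, ", depth =", x$depth,
      ", eta =", format(x$config$eta), "\n")
  invisible(x)
}

# restrict a fitted deep model to its first `depth` layers; drvfl needs the
# per-depth output weights solved on the truncated concatenation
truncate_rvfl <- function(model, depth, beta = NULL) {
  stopifnot(depth >= 1L, depth <= length(model$layers))
  model$layers <- model$layers[seq_len(depth)]
  model$depth <- depth
  if (model$variant == "edrvfl") {
    model$betas <- model$betas[seq_len(depth)]
  } else if (!is.null(beta)) {
    model$betas <- list(beta)
  }
  model
}

#' Per-base-model scores
#'
#' @param model a `fitted_rvfl`.
#' @param X design matrix, column-compatible with the model.
#' @return score matrix with one column for the rvfl/drvfl variants and one
#'   column per base model (layer) for the deep ensemble.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "fitted_rvfl"))
  if (ncol(X) != model$n_input)
    stop("X has ", ncol(X), " columns; model expects ", model$n_input)
  fwd <- forward_hidden(X, model$layers, model$variant,
                        model$config$activation)
  if (model$variant == "edrvfl") {
    do.call(cbind, lapply(seq_along(model$betas), function(l)
      cbind(fwd$H_list[[l]], X) %*% model$betas[[l]]))
  } else {
    fwd$D %*% model$betas[[1L]]
  }
}

#' Predict class labels
#'
#' Mean-score aggregation averages the base-model scores and labels 1 iff
#' the mean reaches the threshold; majority vote thresholds each column at
#' 0.5 and takes the modal vote, ties broken toward label 1.
#'
#' @param object a `fitted_rvfl`.
#' @param X design matrix.
#' @param type `"class"` (default) or `"score"` (mean score).
#' @param ... unused.
#' @return integer 0/1 labels, or mean scores.
#' @export
predict.fitted_rvfl <- function(object, X, type = c("class", "score"), ...) {
  type <- match.arg(type)
  S <- predict_scores(object, X)
  if (type == "score") return(rowMeans(S))
  if (object$config$aggregation == "mean_score" || ncol(S) == 1L) {
    as.integer(rowMeans(S) >= object$config$threshold)
  } else {
    votes <- rowMeans(S >= 0.5)
    as.integer(votes >= 0.5)   # tie -> label 1
  }
}
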