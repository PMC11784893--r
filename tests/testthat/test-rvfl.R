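test_that("layer initialization has the variant-specific shapes and ranges", {
  cfg <- rvfl_config(h = 10, L = 1, seed = 1)
  ly <- init_layers(cfg, 73, "rvfl")
  expect_length(ly, 1L)
  expect_equal(dim(ly[[1]]$W), c(73L, 10L))
  expect_true(all(ly[[1]]$W >= -1 & ly[[1]]$W <= 1))
  expect_true(all(ly[[1]]$b >= 0 & ly[[1]]$b <= 1))
  # same seed, same parameters
  expect_identical(init_layers(cfg, 73, "rvfl"), ly)

  cfg2 <- rvfl_config(h = 4, L = 2, seed = 2)
  # stacked deep variant: layer 2 sees only the h previous activations
  expect_equal(dim(init_layers(cfg2, 5, "drvfl")[[2]]$W), c(4L, 4L))
  # deep ensemble: layer 2 sees [H X], width h + n = 9
  expect_equal(dim(init_layers(cfg2, 5, "edrvfl")[[2]]$W), c(9L, 4L))
})

test_that("the hidden forward pass matches hand computation", {
  # 2 rows, 2 features, 2 neurons, relu
  X <- matrix(c(1, -1,
                2,  0), 2, 2, byrow = TRUE)
  W <- matrix(c(0.5, -1,
                1,    2), 2, 2, byrow = TRUE)
  b <- c(0.1, 0.4)
  layers <- list(list(W = W, b = b))
  H <- forward_hidden(X, layers, "rvfl", "relu")$H_list[[1]]
  # row 1: (1*0.5 + (-1)*1 + 0.1, 1*(-1) + (-1)*2 + 0.4) = (-0.4, -2.6) -> 0
  expect_equal(H[1, ], c(0, 0))
  # row 2: (2*0.5 + 0.1, 2*(-1) + 0.4) = (1.1, -1.6) -> (1.1, 0)
  expect_equal(H[2, ], c(1.1, 0))
  # all-negative pre-activations give an all-zero relu layer
  Hneg <- forward_hidden(-10 * abs(X) - 1,
                         list(list(W = abs(W), b = c(0, 0))),
                         "rvfl", "relu")$H_list[[1]]
  expect_true(all(Hneg == 0))
  expect_error(forward_hidden(X[, 1, drop = FALSE], layers, "rvfl"),
               "width mismatch")
})

test_that("single-layer stacks coincide across variants", {
  d <- separable_xy(30, 5, gap = 1, seed = 3)
  cfg <- rvfl_config(h = 8, L = 1, seed = 4)
  ly <- init_layers(cfg, 5, "rvfl")
  for (v in c("drvfl", "edrvfl")) {
    expect_identical(forward_hidden(d$X, ly, v)$D,
                     forward_hidden(d$X, ly, "rvfl")$D)
  }
})

test_that("ridge solve: identity system, shrinkage limit, primal = dual", {
  Y <- matrix(c(1, -2, 0.5, 3), 4, 1)
  expect_equal(ridge_solve(diag(4), Y, 1), Y / 2)

  set.seed(5)
  for (rep in 1:5) {
    M1 <- matrix(rnorm(40), 8, 5)     # tall: primal branch
    M2 <- matrix(rnorm(40), 5, 8)     # wide: dual branch
    Yt <- matrix(rnorm(8), 8, 1)
    Yw <- matrix(rnorm(5), 5, 1)
    # algebraic identity (M'M + eta I)^{-1} M' = M'(MM' + eta I)^{-1}
    b1p <- solve(crossprod(M1) + diag(0.1, 5), crossprod(M1, Yt))
    expect_equal(ridge_solve(M1, Yt, 0.1), b1p, tolerance = 1e-8)
    b2d <- crossprod(M2, solve(tcrossprod(M2) + diag(0.1, 5), Yw))
    expect_equal(ridge_solve(M2, Yw, 0.1), b2d, tolerance = 1e-8)
    b2p <- solve(crossprod(M2) + diag(0.1, 8), crossprod(M2, Yw))
    expect_equal(ridge_solve(M2, Yw, 0.1), b2p, tolerance = 1e-8)
  }

  M <- matrix(rnorm(60), 12, 5)
  Y12 <- matrix(rnorm(12))
  expect_true(all(abs(ridge_solve(M, Y12, 1e12)) < 1e-6))
})

test_that("ridge solve matches a generic least-squares oracle on the augmented system", {
  set.seed(6)
  for (rep in 1:5) {
    M <- matrix(rnorm(15 * 6), 15, 6)
    Y <- matrix(rnorm(15))
    eta <- runif(1, 0.01, 10)
    want <- qr.solve(rbind(M, sqrt(eta) * diag(6)),
                     rbind(Y, matrix(0, 6, 1)))
    expect_equal(ridge_solve(M, Y, eta), want, tolerance = 1e-8)
  }
})

test_that("singular unpenalized systems fall back to the pseudo-inverse", {
  M <- cbind(1, c(1, 2, 3), c(2, 4, 6))   # rank 2
  Y <- matrix(c(1, 2, 3))
  expect_warning(beta <- ridge_solve(M, Y, 0), "pseudo-inverse")
  expect_equal(as.numeric(M %*% beta), as.numeric(Y), tolerance = 1e-8)
})

test_that("separable data is fit perfectly and the ensemble degenerates to the plain network at L = 1", {
  d <- separable_xy(200, 10, gap = 5, seed = 7)
  cfg <- rvfl_config(h = 50, L = 1, eta = 2^-6, seed = 8)
  fit_r <- rvfl_fit(d$X, d$y, cfg, "rvfl")
  expect_equal(mean(predict(fit_r, d$X) == d$y), 1.0)
  fit_e <- rvfl_fit(d$X, d$y, cfg, "edrvfl")
  expect_identical(predict(fit_e, d$X), predict(fit_r, d$X))
  fit_d <- rvfl_fit(d$X, d$y, cfg, "drvfl")
  expect_identical(predict(fit_d, d$X), predict(fit_r, d$X))
})

test_that("all-zero inputs give constant predictions through the bias columns", {
  X0 <- matrix(0, 30, 4)
  y <- rep(c(0L, 1L), 15)
  fit <- rvfl_fit(X0, y, rvfl_config(h = 10, eta = 0.5, seed = 9), "rvfl")
  expect_equal(length(unique(predict(fit, X0))), 1L)
})

test_that("hidden parameters are never modified by fitting", {
  d <- separable_xy(50, 5, gap = 2, seed = 10)
  cfg <- rvfl_config(h = 12, L = 2, seed = 11)
  fit <- rvfl_fit(d$X, d$y, cfg, "edrvfl")
  expect_identical(fit$layers, init_layers(cfg, 5, "edrvfl"))
})

test_that("unpenalized full-rank training scores interpolate the targets", {
  set.seed(12)
  X <- matrix(rnorm(15 * 5), 15, 5)
  y <- rep(c(0, 1), length.out = 15)
  cfg <- rvfl_config(h = 40, eta = 0, seed = 13)
  expect_warning(fit <- rvfl_fit(X, y, cfg, "rvfl"), "pseudo-inverse")
  expect_lt(max(abs(predict_scores(fit, X) - y)), 1e-6)
})

test_that("rvfl scores equal the direct [H X] beta product", {
  d <- separable_xy(20, 4, gap = 1, seed = 14)
  cfg <- rvfl_config(h = 6, eta = 0.3, seed = 15)
  fit <- rvfl_fit(d$X, d$y, cfg, "rvfl")
  fwd <- forward_hidden(d$X, fit$layers, "rvfl")
  expect_equal(predict_scores(fit, d$X), fwd$D %*% fit$betas[[1]])
})

test_that("each ensemble score column is that base model in isolation", {
  d <- separable_xy(40, 6, gap = 2, seed = 16)
  cfg <- rvfl_config(h = 9, L = 3, eta = 0.2, seed = 17)
  fit <- rvfl_fit(d$X, d$y, cfg, "edrvfl")
  S <- predict_scores(fit, d$X)
  expect_equal(ncol(S), 3L)
  fwd <- forward_hidden(d$X, fit$layers, "edrvfl")
  for (l in 1:3) {
    expect_equal(S[, l],
                 as.numeric(cbind(fwd$H_list[[l]], d$X) %*% fit$betas[[l]]))
  }
})

test_that("aggregation rules: unanimity agrees, vote ties go to label 1", {
  # hand-built 2-base-model ensemble with constant scores 0.9 and 0.1
  layers <- list(list(W = matrix(0, 1, 1), b = 0.9),
                 list(W = matrix(0, 2, 1), b = 0.9))
  mk <- function(beta2, aggregation) {
    structure(list(variant = "edrvfl", layers = layers,
                   betas = list(matrix(c(1, 0)), beta2),
                   config = rvfl_config(h = 1, L = 2,
                                        aggregation = aggregation),
                   n_input = 1L, depth = 2L),
              class = "fitted_rvfl")
  }
  X <- matrix(c(-1, 2), 2, 1)
  # both bases score 0.9: label 1 under both rules
  expect_equal(predict(mk(matrix(c(1, 0)), "mean_score"), X), c(1L, 1L))
  expect_equal(predict(mk(matrix(c(1, 0)), "majority_vote"), X), c(1L, 1L))
  # scores 0.9 and 0.1: vote splits 1-1, tie resolves to label 1
  tied <- mk(matrix(c(1 / 9, 0)), "majority_vote")
  expect_equal(unname(predict_scores(tied, X)[1, ]), c(0.9, 0.1))
  expect_equal(predict(tied, X), c(1L, 1L))
})

test_that("training residuals are monotone in the ridge penalty", {
  set.seed(18)
  M <- matrix(rnorm(40 * 12), 40, 12)
  Y <- matrix(rnorm(40))
  res <- vapply(2^seq(-6, 12, 2), function(eta)
    sum((M %*% ridge_solve(M, Y, eta) - Y)^2), numeric(1))
  expect_true(all(diff(res) >= -1e-10))
})

test_that("fit + predict is a pure function of (X, y, config)", {
  d <- separable_xy(50, 5, gap = 1, seed = 19)
  cfg <- rvfl_config(h = 15, L = 2, eta = 0.1, seed = 20)
  p1 <- predict(rvfl_fit(d$X, d$y, cfg, "edrvfl"), d$X)
  p2 <- predict(rvfl_fit(d$X, d$y, cfg, "edrvfl"), d$X)
  expect_identical(p1, p2)
})
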