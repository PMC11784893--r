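test_that("winsorized mean replaces floor(alpha*n) values per tail", {
  expect_equal(winsorized_mean(c(4, 1, 9), 0), 14 / 3)
  # 1 -> 2 and 10 -> 9: sum 55, mean 5.5
  expect_equal(winsorized_mean(1:10, 0.10), 5.5)
  # 100 -> 1, minimum replaced by itself
  expect_equal(winsorized_mean(c(1, 1, 1, 100), 0.25), 1.0)
  expect_error(winsorized_mean(numeric(0), 0.1), "empty")
  expect_error(winsorized_mean(1:5, 0.5), "alpha")
})

test_that("winsorized mean is translation-equivariant and bounded", {
  set.seed(1)
  for (rep in 1:20) {
    x <- rnorm(sample(3:40, 1), sd = 5)
    a <- runif(1, 0, 0.45)
    w <- winsorized_mean(x, a)
    expect_gte(w, min(x))
    expect_lte(w, max(x))
    shift <- rnorm(1)
    expect_equal(winsorized_mean(x + shift, a), w + shift)
  }
})

test_that("constant-fill imputers learn their fills from training rows only", {
  set.seed(2)
  X <- matrix(rnorm(80), 20, 4)
  co <- numeric_cohort(X)
  fit_m <- fit_imputer(co, imputer_spec("mean"))
  expect_equal(unname(fit_m$numeric_state$fill), unname(colMeans(X)))
  fit_md <- fit_imputer(co, imputer_spec("median"))
  expect_equal(unname(fit_md$numeric_state$fill),
               unname(apply(X, 2, median)))
  fit_w <- fit_imputer(co, imputer_spec("wmean", alpha = 0.2))
  expect_equal(unname(fit_w$numeric_state$fill),
               unname(apply(X, 2, winsorized_mean, alpha = 0.2)))
  # a single missing cell under zero fill; everything else untouched
  Xm <- X; Xm[3, 2] <- NA
  com <- numeric_cohort(Xm)
  out <- predict(fit_imputer(com, imputer_spec("zero")), com)
  expect_equal(out$values[[2]][3], 0)
  expect_equal(as.matrix(out$values)[-(3 + 20)],
               as.matrix(com$values)[-(3 + 20)])
})

test_that("categorical gaps take the training mode, ties lexicographic", {
  sc <- tiny_schema()
  co <- generate_cohort(sc, 10, 10, seed = 3)
  co$values$grp <- c(rep("a", 8), rep("b", 8), rep(NA, 4))
  imp <- fit_imputer(co, imputer_spec("mean"))
  expect_equal(unname(imp$modes[["grp"]]), "a")   # 8-8 tie -> "a"
  out <- predict(imp, co)
  expect_equal(out$values$grp[17:20], rep("a", 4))
})

test_that("transform is the identity on complete data and never alters observed cells", {
  sc <- tiny_schema()
  co <- generate_cohort(sc, 25, 25, seed = 4)
  for (mth in c("zero", "mean", "median", "wmean", "knn", "em")) {
    imp <- fit_imputer(co, imputer_spec(mth))
    expect_identical(predict(imp, co)$values, co$values)
  }
  pat <- missingness_pattern(list(demographic = c(0.2, 0.2),
                                  cognitive = c(0.3, 0.3),
                                  MRI = c(0.3, 0.3)))
  com <- apply_missingness(co, pat, seed = 5)
  obs <- !missing_mask(com)
  raw <- as.matrix(com$values)
  for (mth in c("zero", "mean", "median", "wmean", "knn", "em")) {
    out <- predict(fit_imputer(com, imputer_spec(mth)), com)
    filled <- as.matrix(out$values)
    expect_false(any(is.na(filled)))
    expect_identical(filled[obs], raw[obs])
  }
})

test_that("knn with k = 1 copies the masked cell from a duplicated row", {
  set.seed(6)
  train <- matrix(rnorm(40), 10, 4)
  query <- train[7, , drop = FALSE]
  query[1, 3] <- NA
  imp <- fit_imputer(numeric_cohort(train), imputer_spec("knn", k = 1))
  out <- predict(imp, numeric_cohort(query, labels = 0L))
  expect_equal(out$values[[3]][1], train[7, 3])
})

test_that("knn matches the exhaustive-search oracle on small tables", {
  set.seed(7)
  for (n in c(10L, 30L, 50L)) {
    train <- matrix(rnorm(n * 4), n, 4)
    train[runif(length(train)) < 0.2] <- NA
    train <- train[rowSums(!is.na(train)) > 0, , drop = FALSE]
    X <- matrix(rnorm(10 * 4), 10, 4)
    X[runif(length(X)) < 0.3] <- NA
    for (k in c(1L, 3L, 5L, 10L)) {
      imp <- fit_imputer(numeric_cohort(train), imputer_spec("knn", k = k))
      got <- as.matrix(predict(imp, numeric_cohort(X,
        labels = rep(0L, nrow(X))))$values)
      want <- knn_oracle(X, train, k)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("a row with every numeric cell missing falls back to column means", {
  set.seed(8)
  train <- matrix(rnorm(40), 10, 4)
  X <- matrix(NA_real_, 1, 4)
  imp <- fit_imputer(numeric_cohort(train), imputer_spec("knn"))
  expect_message(
    out <- predict(imp, numeric_cohort(X, labels = 0L)),
    "column means")
  expect_equal(unname(as.matrix(out$values)[1, ]), unname(colMeans(train)))
})

test_that("EM on complete data is the Gaussian maximum likelihood fit", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3) %*% matrix(c(1, .5, 0, 0, 1, .3, 0, 0, 1), 3)
  f <- em_mvnorm(X, tol = 1e-8)
  expect_equal(unname(f$mu), unname(colMeans(X)), tolerance = 1e-8)
  expect_equal(unname(f$sigma), unname(crossprod(sweep(X, 2, colMeans(X))) /
                                         nrow(X)),
               tolerance = 1e-4)
})

test_that("EM log-likelihood is non-decreasing and recovers parameters", {
  set.seed(10)
  n <- 800
  A <- matrix(c(1, 0.6, 0.3, 0, 0.8, 0.5, 0, 0, 0.7), 3, 3)
  mu_true <- c(1, -2, 0.5)
  X <- matrix(rnorm(3 * n), n, 3) %*% t(A) +
    matrix(mu_true, n, 3, byrow = TRUE)
  Xm <- X
  Xm[runif(length(X)) < 0.3] <- NA
  f <- em_mvnorm(Xm, tol = 1e-8, max_iter = 500)
  expect_true(all(diff(f$loglik) >= -1e-8))
  sig_true <- tcrossprod(A)
  for (j in 1:3) {
    se <- sqrt(sig_true[j, j] / sum(!is.na(Xm[, j])))
    expect_lt(abs(f$mu[j] - mu_true[j]), 3 * se)
  }
})

test_that("EM imputation equals the closed-form Gaussian conditional mean", {
  set.seed(11)
  A <- matrix(c(1, 0.7, 0.2, 0, 0.9, 0.4, 0, 0, 0.6), 3, 3)
  X <- matrix(rnorm(3 * 400), 400, 3) %*% t(A)
  Xm <- X
  Xm[runif(length(X)) < 0.25] <- NA
  imp <- fit_imputer(numeric_cohort(Xm[, 1:3]), imputer_spec("em"))
  out <- as.matrix(predict(imp, numeric_cohort(Xm[, 1:3]))$values)
  st <- imp$numeric_state$em
  for (i in sample(which(rowSums(is.na(Xm)) > 0), 25)) {
    o <- which(!is.na(Xm[i, ]))
    if (!length(o)) next
    m <- setdiff(1:3, o)
    want <- cond_mean_oracle(Xm[i, ], o, st$mu, st$sigma)
    expect_equal(unname(out[i, m]), as.numeric(want), tolerance = 1e-8)
  }
})

test_that("an entirely missing numeric column warns and takes the fallback fill", {
  X <- matrix(rnorm(40), 10, 4)
  X[, 2] <- NA
  co <- numeric_cohort(X)
  expect_warning(imp <- fit_imputer(co, imputer_spec("em")),
                 "entirely missing")
  out <- predict(imp, co)
  expect_true(all(out$values[[2]] == 0))
  expect_warning(imp2 <- fit_imputer(co, imputer_spec("mean",
                                                      fallback_fill = -1)),
                 "entirely missing")
  expect_true(all(predict(imp2, co)$values[[2]] == -1))
})

test_that("imputer specs validate their fields", {
  expect_error(imputer_spec("mean", alpha = 0.6), "alpha")
  expect_error(imputer_spec("knn", k = 0), "k must be")
  expect_error(imputer_spec("em", em_tol = 0), "em_tol")
  expect_error(imputer_spec("typo"), "arg")
})
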