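# small schemas and cohorts used across the suite

# one categorical + three numeric columns (one vector-valued), two
# modalities, strong class separation through the latent factor
tiny_schema <- function(separation = 2) {
  feature_schema(list(
    variable_spec("grp", "categorical", "demographic",
                  categories = c("a", "b"),
                  gen_params = list(prob = cbind(CN = c(0.5, 0.5),
                                                 MCI = c(0.3, 0.7)))),
    variable_spec("score", "numeric", "cognitive",
                  gen_params = list(mean = c(0, separation), sd = c(1, 1),
                                    loading = 0.5)),
    variable_spec("vol", "numeric", "MRI", dim = 2L,
                  gen_params = list(mean = cbind(CN = c(10, 20),
                                                 MCI = c(10 - separation,
                                                         20 - separation)),
                                    sd = cbind(CN = c(1, 1),
                                               MCI = c(1, 1)),
                                    loading = 0.5))
  ))
}

# numeric-only schema used for imputation oracles
numeric_schema <- function(p = 4L) {
  feature_schema(lapply(seq_len(p), function(j)
    variable_spec(paste0("x", j), "numeric", "CSF",
                  gen_params = list(mean = c(j, j + 1), sd = c(1, 1),
                                    loading = 0.3))))
}

# cohort_table directly from a numeric matrix (NAs allowed)
numeric_cohort <- function(X, labels = NULL) {
  p <- ncol(X)
  sc <- numeric_schema(p)
  if (is.null(labels)) labels <- rep_len(c(0L, 1L), nrow(X))
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(p))
  cohort_table(df, labels, sc)
}

# linearly separable two-Gaussian design matrix
separable_xy <- function(n_per_class = 200L, p = 10L, gap = 5,
                         seed = 42L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
  y <- rep(0:1, each = n_per_class)
  list(X = X, y = y)
}

# exhaustive-search KNN imputation oracle (loops, independent of the
# vectorized implementation)
knn_oracle <- function(X, train, k) {
  p <- ncol(X)
  out <- X
  for (i in seq_len(nrow(X))) {
    miss <- which(is.na(X[i, ]))
    if (!length(miss)) next
    if (length(miss) == p) {
      out[i, ] <- colMeans(train, na.rm = TRUE)
      next
    }
    d <- vapply(seq_len(nrow(train)), function(r) {
      sh <- which(!is.na(X[i, ]) & !is.na(train[r, ]))
      if (!length(sh)) return(Inf)
      sqrt(sum((X[i, sh] - train[r, sh])^2) * p / length(sh))
    }, numeric(1))
    for (j in miss) {
      cand <- which(!is.na(train[, j]) & is.finite(d))
      if (!length(cand)) {
        out[i, j] <- mean(train[, j], na.rm = TRUE)
        next
      }
      nn <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(train[nn, j])
    }
  }
  out
}

# closed-form Gaussian conditional mean, independent of the EM code path
cond_mean_oracle <- function(x, obs_idx, mu, sigma) {
  m <- setdiff(seq_along(mu), obs_idx)
  mu[m] + sigma[m, obs_idx, drop = FALSE] %*%
    solve(sigma[obs_idx, obs_idx, drop = FALSE],
          x[obs_idx] - mu[obs_idx])
}
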