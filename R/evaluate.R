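#' Experimental protocol plan
#'
#' Bundles the repeated-holdout protocol settings: `n_repeats` stratified
#' 80/20 splits, `cv_folds`-fold stratified internal tuning,
#' `committee_size` random initializations per final model with a
#' `val_frac` validation carve-out of the training split for early
#' stopping/member selection, all driven by one `master_seed` through a
#' documented deterministic seed hierarchy (master -> per-repeat ->
#' per-stage -> per-member).
#'
#' @param n_repeats outer holdout repetitions (default 100).
#' @param train_frac training fraction of each split (default 0.8).
#' @param cv_folds internal stratified folds (default 5).
#' @param committee_size random-initialization committee size (default 11).
#' @param val_frac validation fraction carved from the training split
#'   (default 0.2).
#' @param master_seed integer master seed.
#' @return a `split_plan` object.
#' @export
split_plan <- function(n_repeats = 100L, train_frac = 0.8, cv_folds = 5L,
                       committee_size = 11L, val_frac = 0.2,
                       master_seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, val_frac > 0, val_frac < 1,
            cv_folds >= 2L, committee_size >= 1L, n_repeats >= 1L)
  structure(list(n_repeats = as.integer(n_repeats),
                 train_frac = train_frac, cv_folds = as.integer(cv_folds),
                 committee_size = as.integer(committee_size),
                 val_frac = val_frac, master_seed = as.integer(master_seed)),
            class = "split_plan")
}

#' Stratified holdout split
#'
#' Per-class proportions are preserved to within one sample; the two index
#' sets are disjoint and exhaustive.
#'
#' @param labels 0/1 label vector (both classes present, each with >= 2
#'   members).
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_holdout <- function(labels, train_frac = 0.8, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present")
  with_seed(seed, {
    train <- integer(0)
    for (cl in classes) {
      ids <- which(labels == cl)
      if (length(ids) < 2L)
        stop("class ", cl, " has fewer than 2 members")
      n_tr <- round(train_frac * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      train <- c(train, sample(ids)[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Stratified fold assignment
#'
#' @param labels 0/1 label vector.
#' @param k number of folds; class ratios are preserved to within one
#'   sample per fold.
#' @param seed integer seed.
#' @return integer fold id (1..k) per row.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      ids <- sample(which(labels == cl))
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
    fold
  })
}

#' Binary classification metrics
#'
#' Confusion counts and derived rates with class 1 (MCI) as positive:
#' accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' their harmonic mean F1. A rate with an empty denominator is reported as
#' 0 and flagged in `undefined`.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return a `metric_set` list with `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f1`, `undefined`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  undefined <- character(0)
  if (tp + fp == 0) { precision <- 0; undefined <- c(undefined, "precision") }
  else precision <- tp / (tp + fp)
  if (tp + fn == 0) { recall <- 0; undefined <- c(undefined, "recall") }
  else recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined),
            class = "metric_set")
}

#' Default hyperparameter grids
#'
#' Neurons 10..100 by 10 and ridge penalties `2^{-6,-4,...,12}` for all
#' variants; the deep variants additionally tune 2 vs 3 layers.
#'
#' @param variant `"rvfl"`, `"drvfl"` or `"edrvfl"`.
#' @param L_grid layer counts for the deep variants (default `c(2, 3)`).
#' @return data.frame with columns `h`, `eta`, `L`.
#' @export
default_hyper_grid <- function(variant = c("rvfl", "drvfl", "edrvfl"),
                               L_grid = c(2L, 3L)) {
  variant <- match.arg(variant)
  if (variant == "rvfl") L_grid <- 1L
  expand.grid(h = seq(10L, 100L, 10L), eta = 2^seq(-6, 12, 2), L = L_grid,
              KEEP.OUT.ATTRS = FALSE)
}

#' Model specifications for the evaluation pipeline
#'
#' `rvfl_model_spec()` describes one of the three randomized
#' functional-link variants with its tuning grid; `baseline_model_spec()`
#' wraps an external classifier behind `fit(X, y, params)` /
#' `predict(fit, X)` closures (internals out of the package's scope).
#'
#' @param variant `"rvfl"`, `"drvfl"` or `"edrvfl"`.
#' @param grid tuning grid (`h`, `eta`, `L` columns), defaults to
#'   [default_hyper_grid()].
#' @param name display name.
#' @param base_config an [rvfl_config()] supplying activation, sampling
#'   ranges, aggregation and threshold (its `h`/`L`/`eta`/`seed` are
#'   overridden during tuning).
#' @return a model spec object.
#' @export
rvfl_model_spec <- function(variant = c("rvfl", "drvfl", "edrvfl"),
                            grid = NULL, name = NULL,
                            base_config = rvfl_config()) {
  variant <- match.arg(variant)
  if (is.null(grid)) grid <- default_hyper_grid(variant)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("h", "eta") %in% names(grid)))
  if (is.null(grid$L)) grid$L <- if (variant == "rvfl") 1L else 2L
  structure(list(kind = "rvfl", variant = variant, grid = grid,
                 name = if (is.null(name)) variant else name,
                 base_config = base_config),
            class = "model_spec")
}

#' @rdname rvfl_model_spec
#' @param fit function `(X, y, params)` returning a fitted object.
#' @param predict function `(fit, X)` returning 0/1 labels.
#' @export
baseline_model_spec <- function(name, fit, predict,
                                grid = data.frame(.cand = 1L)) {
  stopifnot(is.function(fit), is.function(predict), is.data.frame(grid),
            nrow(grid) >= 1L)
  structure(list(kind = "baseline", name = name, fit_fn = fit,
                 predict_fn = predict, grid = grid),
            class = "model_spec")
}

# fit imputer + encoder on in-fold training rows and encode both sides;
# the only thing test/validation rows ever reach is transform/encode
prepare_split <- function(train_cohort, eval_cohort, imp_spec) {
  imp <- suppressWarnings(fit_imputer(train_cohort, imp_spec))
  tr_full <- predict(imp, train_cohort)
  ev_full <- predict(imp, eval_cohort)
  led <- fit_encoding(tr_full)
  enc_tr <- suppressWarnings(encode(led, tr_full))
  enc_ev <- suppressWarnings(encode(led, ev_full))
  list(X_tr = enc_tr$X, y_tr = enc_tr$y, X_ev = enc_ev$X, y_ev = enc_ev$y)
}

make_cv_data <- function(train_cohort, imp_spec, cv_folds, seed) {
  fold <- stratified_folds(train_cohort$labels, cv_folds, seed)
  lapply(seq_len(cv_folds), function(f) {
    prepare_split(cohort_rows(train_cohort, which(fold != f)),
                  cohort_rows(train_cohort, which(fold == f)),
                  imp_spec)
  })
}

# per-candidate mean validation accuracy on pre-encoded folds
cv_accuracy_rvfl <- function(cv_data, spec, seed) {
  grid <- spec$grid
  acc <- matrix(NA_real_, nrow(grid), length(cv_data))
  groups <- split(seq_len(nrow(grid)),
                  paste(grid$h, grid$L, sep = "/"))
  for (f in seq_along(cv_data)) {
    d <- cv_data[[f]]
    for (g in groups) {
      cfg <- spec$base_config
      cfg$h <- grid$h[g[1L]]; cfg$L <- grid$L[g[1L]]
      cfg$seed <- seed + f   # random features shared across eta candidates
      layers <- init_layers(cfg, ncol(d$X_tr), spec$variant)
      fwd_tr <- forward_hidden(d$X_tr, layers, spec$variant, cfg$activation)
      fwd_ev <- forward_hidden(d$X_ev, layers, spec$variant, cfg$activation)
      for (i in g) {
        eta <- grid$eta[i]
        pred <- if (spec$variant == "edrvfl") {
          S <- vapply(seq_along(layers), function(l) {
            beta <- ridge_solve(cbind(fwd_tr$H_list[[l]], d$X_tr),
                                d$y_tr, eta)
            as.numeric(cbind(fwd_ev$H_list[[l]], d$X_ev) %*% beta)
          }, numeric(nrow(d$X_ev)))
          S <- matrix(S, nrow = nrow(d$X_ev))
          as.integer(rowMeans(S) >= cfg$threshold)
        } else {
          beta <- ridge_solve(fwd_tr$D, d$y_tr, eta)
          as.integer(fwd_ev$D %*% beta >= cfg$threshold)
        }
        acc[i, f] <- mean(pred == d$y_ev)
      }
    }
  }
  rowMeans(acc)
}

cv_accuracy_baseline <- function(cv_data, spec) {
  grid <- spec$grid
  acc <- matrix(NA_real_, nrow(grid), length(cv_data))
  for (f in seq_along(cv_data)) {
    d <- cv_data[[f]]
    for (i in seq_len(nrow(grid))) {
      fit <- spec$fit_fn(d$X_tr, d$y_tr, grid[i, , drop = FALSE])
      acc[i, f] <- mean(spec$predict_fn(fit, d$X_ev) == d$y_ev)
    }
  }
  rowMeans(acc)
}

select_best <- function(grid, acc) {
  ord <- order(-acc,
               if (!is.null(grid$h)) grid$h else seq_len(nrow(grid)),
               if (!is.null(grid$eta)) -grid$eta else seq_len(nrow(grid)),
               seq_len(nrow(grid)))
  grid[ord[1L], , drop = FALSE]
}

#' Tune a model by stratified cross-validation
#'
#' Imputation and encoding are re-fit inside every fold (no leakage); the
#' candidate with the best mean validation accuracy wins, ties broken
#' toward smaller `h`, then larger `eta`, then grid order (parsimony).
#'
#' @param train_cohort training-rows [cohort_table()] (raw, with missing
#'   cells).
#' @param imp_spec an [imputer_spec()].
#' @param model_spec an [rvfl_model_spec()] or [baseline_model_spec()].
#' @param cv_folds number of stratified folds (default 5).
#' @param seed integer seed.
#' @return list with `best` (the winning grid row) and `cv_accuracy` (mean
#'   validation accuracy per candidate, grid order).
#' @export
tune <- function(train_cohort, imp_spec, model_spec, cv_folds = 5L,
                 seed = 1L) {
  stopifnot(inherits(model_spec, "model_spec"), nrow(model_spec$grid) >= 1L)
  cv_data <- make_cv_data(train_cohort, imp_spec, cv_folds, seed)
  tune_prepared(cv_data, model_spec, seed)
}

tune_prepared <- function(cv_data, model_spec, seed) {
  acc <- if (model_spec$kind == "rvfl")
    cv_accuracy_rvfl(cv_data, model_spec, seed)
  else
    cv_accuracy_baseline(cv_data, model_spec)
  list(best = select_best(model_spec$grid, acc), cv_accuracy = acc)
}

# validation mean squared error of the depth-d prediction for one member
member_depth_losses <- function(model, fwd_tr, fwd_val, X_tr, y_tr,
                                X_val, y_val, eta) {
  L <- length(model$layers)
  if (model$variant == "edrvfl") {
    S <- vapply(seq_len(L), function(l)
      as.numeric(cbind(fwd_val$H_list[[l]], X_val) %*% model$betas[[l]]),
      numeric(nrow(X_val)))
    S <- matrix(S, nrow = nrow(X_val))
    vapply(seq_len(L), function(d)
      mean((rowMeans(S[, seq_len(d), drop = FALSE]) - y_val)^2),
      numeric(1))
  } else if (model$variant == "drvfl") {
    h <- model$config$h
    n <- model$n_input
    vapply(seq_len(L), function(d) {
      cols <- c(seq_len(h * d), h * L + seq_len(n))
      beta <- ridge_solve(fwd_tr$D[, cols, drop = FALSE], y_tr, eta)
      mean((fwd_val$D[, cols, drop = FALSE] %*% beta - y_val)^2)
    }, numeric(1))
  } else {
    mean((fwd_val$D %*% model$betas[[1L]] - y_val)^2)
  }
}

#' Train a random-initialization committee with depth early stopping
#'
#' Fits `committee_size` models with distinct derived seeds. For the deep
#' variants each member's effective depth is truncated at the depth
#' minimizing validation squared loss (early stopping over layers 1..L);
#' the member with minimal validation loss is returned (ties toward the
#' first member).
#'
#' @param X_tr,y_tr training design matrix and labels.
#' @param X_val,y_val disjoint validation set used for early stopping and
#'   member selection.
#' @param config an [rvfl_config()] (the tuned hyperparameters).
#' @param variant `"rvfl"`, `"drvfl"` or `"edrvfl"`.
#' @param committee_size number of members (default 11).
#' @param seed integer seed for the member-seed derivation.
#' @return list with `model` (the selected, depth-truncated `fitted_rvfl`),
#'   `val_loss` (per member, at its best depth) and `depths`.
#' @export
train_committee <- function(X_tr, y_tr, X_val, y_val, config,
                            variant = c("rvfl", "drvfl", "edrvfl"),
                            committee_size = 11L, seed = 1L) {
  variant <- match.arg(variant)
  seeds <- derive_seeds(seed, committee_size)
  best <- NULL; best_loss <- Inf
  losses <- numeric(committee_size)
  depths <- integer(committee_size)
  for (mbr in seq_len(committee_size)) {
    cfg <- config
    cfg$seed <- seeds[mbr]
    model <- rvfl_fit(X_tr, y_tr, cfg, variant)
    fwd_tr <- forward_hidden(X_tr, model$layers, variant, cfg$activation)
    fwd_val <- forward_hidden(X_val, model$layers, variant, cfg$activation)
    dl <- member_depth_losses(model, fwd_tr, fwd_val, X_tr, y_tr,
                              X_val, y_val, cfg$eta)
    d <- which.min(dl)
    depths[mbr] <- d
    losses[mbr] <- dl[d]
    if (dl[d] < best_loss) {
      best_loss <- dl[d]
      if (variant == "drvfl" && d < length(model$layers)) {
        h <- model$config$h; n <- model$n_input; L <- length(model$layers)
        cols <- c(seq_len(h * d), h * L + seq_len(n))
        beta <- ridge_solve(fwd_tr$D[, cols, drop = FALSE], y_tr, cfg$eta)
        best <- truncate_rvfl(model, d, beta)
      } else {
        best <- truncate_rvfl(model, d)
      }
    }
  }
  list(model = best, val_loss = losses, depths = depths)
}

fit_final <- function(model_spec, best, split_data, plan, seed) {
  if (model_spec$kind == "rvfl") {
    sub <- stratified_holdout(split_data$y_tr, 1 - plan$val_frac, seed)
    cfg <- model_spec$base_config
    cfg$h <- best$h; cfg$eta <- best$eta; cfg$L <- best$L
    comm <- train_committee(split_data$X_tr[sub$train, , drop = FALSE],
                            split_data$y_tr[sub$train],
                            split_data$X_tr[sub$test, , drop = FALSE],
                            split_data$y_tr[sub$test],
                            cfg, model_spec$variant,
                            plan$committee_size, seed)
    predict(comm$model, split_data$X_ev)
  } else {
    fit <- model_spec$fit_fn(split_data$X_tr, split_data$y_tr, best)
    model_spec$predict_fn(fit, split_data$X_ev)
  }
}

#' Run the full imputation x model experiment grid
#'
#' For each repeat: stratified 80/20 split, then per imputation method
#' fit imputer/encoder on the training rows, tune each model by internal
#' cross-validation, train the final committee, and score the held-out
#' test rows. Cell statistics aggregate mean and SD over repeats. Fully
#' deterministic given `plan$master_seed`. A stage error aborts that cell
#' with a recorded diagnostic; other cells proceed.
#'
#' @param cohort a raw [cohort_table()] (with missing cells).
#' @param imputer_specs named list of [imputer_spec()] objects.
#' @param model_specs named list of model specs ([rvfl_model_spec()] /
#'   [baseline_model_spec()]).
#' @param plan a [split_plan()].
#' @return a `result_grid`: list with `cells` (method, model, metric,
#'   mean, sd), `records` (per-repeat raw metrics) and `errors`.
#' @export
run_experiment <- function(cohort, imputer_specs, model_specs,
                           plan = split_plan()) {
  stopifnot(length(imputer_specs) >= 1L, length(model_specs) >= 1L)
  if (is.null(names(imputer_specs)) || is.null(names(model_specs)))
    stop("imputer_specs and model_specs must be named lists")
  repeat_seeds <- derive_seeds(plan$master_seed, plan$n_repeats)
  records <- list()
  errors <- list()

  for (r in seq_len(plan$n_repeats)) {
    ss <- derive_seeds(repeat_seeds[r], 4L)  # split, tune, final, reserve
    split <- stratified_holdout(cohort$labels, plan$train_frac, ss[1])
    train_cohort <- cohort_rows(cohort, split$train)
    test_cohort <- cohort_rows(cohort, split$test)

    for (mth in names(imputer_specs)) {
      cell_err <- function(model_name, e) {
        errors[[length(errors) + 1L]] <<-
          data.frame(repeat_ = r, method = mth, model = model_name,
                     message = conditionMessage(e))
      }
      cv_data <- tryCatch(
        make_cv_data(train_cohort, imputer_specs[[mth]], plan$cv_folds,
                     ss[2]),
        error = function(e) { cell_err("<cv>", e); NULL })
      if (is.null(cv_data)) next
      split_data <- tryCatch({
        d <- prepare_split(train_cohort, test_cohort, imputer_specs[[mth]])
        list(X_tr = d$X_tr, y_tr = d$y_tr, X_ev = d$X_ev, y_ev = d$y_ev)
      }, error = function(e) { cell_err("<encode>", e); NULL })
      if (is.null(split_data)) next

      for (mdl in names(model_specs)) {
        rec <- tryCatch({
          tuned <- tune_prepared(cv_data, model_specs[[mdl]], ss[2])
          pred <- fit_final(model_specs[[mdl]], tuned$best, split_data,
                            plan, ss[3])
          m <- compute_metrics(split_data$y_ev, pred)
          data.frame(repeat_ = r, method = mth, model = mdl,
                     accuracy = m$accuracy, precision = m$precision,
                     recall = m$recall, f1 = m$f1)
        }, error = function(e) { cell_err(mdl, e); NULL })
        if (!is.null(rec)) records[[length(records) + 1L]] <- rec
      }
    }
  }

  records <- if (length(records)) do.call(rbind, records) else
    data.frame(repeat_ = integer(), method = character(),
               model = character(), accuracy = numeric(),
               precision = numeric(), recall = numeric(), f1 = numeric())
  structure(list(cells = aggregate_records(records), records = records,
                 errors = if (length(errors)) do.call(rbind, errors) else
                   NULL,
                 plan = plan),
            class = "result_grid")
}

aggregate_records <- function(records) {
  metrics <- c("accuracy", "precision", "recall", "f1")
  out <- list()
  for (mth in unique(records$method)) for (mdl in unique(records$model)) {
    sub <- records[records$method == mth & records$model == mdl, ]
    if (!nrow(sub)) next
    for (met in metrics) {
      out[[length(out) + 1L]] <- data.frame(
        method = mth, model = mdl, metric = met,
        mean = mean(sub[[met]]),
        sd = if (nrow(sub) > 1L) sd(sub[[met]]) else 0,
        n_repeats = nrow(sub))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(method = character(), model = character(),
               metric = character(), mean = numeric(), sd = numeric(),
               n_repeats = integer())
}

#' @export
print.result_grid <- function(x, ...) {
  acc <- x$cells[x$cells$metric == "accuracy", ]
  cat("result_grid:", nrow(acc), "cells,",
      length(unique(x$records$repeat_)), "repeats\n")
  if (nrow(acc)) print(acc[order(acc$method, acc$model),
                           c("method", "model", "mean", "sd")],
                       row.names = FALSE)
  invisible(x)
}

#' Accuracy surface over the (eta, h) hyperparameter grid
#'
#' Mean held-out accuracy per (eta, h) cell over a reduced repeat count,
#' in long format for heatmap plotting.
#'
#' @param cohort raw [cohort_table()].
#' @param variant RVFL variant.
#' @param h_grid,eta_grid hyperparameter values to sweep.
#' @param imp_spec an [imputer_spec()].
#' @param n_repeats holdout repetitions per cell (default 3).
#' @param L layer count for deep variants (default 2).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer master seed.
#' @return data.frame with columns `h`, `eta`, `accuracy`.
#' @export
sweep_surface <- function(cohort, variant = c("rvfl", "drvfl", "edrvfl"),
                          h_grid = seq(10L, 100L, 10L),
                          eta_grid = 2^seq(-6, 12, 2),
                          imp_spec = imputer_spec("mean"),
                          n_repeats = 3L, L = 2L, train_frac = 0.8,
                          seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(h_grid) >= 1L, length(eta_grid) >= 1L)
  seeds <- derive_seeds(seed, n_repeats)
  acc <- array(NA_real_, c(length(h_grid), length(eta_grid), n_repeats))
  for (r in seq_len(n_repeats)) {
    split <- stratified_holdout(cohort$labels, train_frac, seeds[r])
    d <- prepare_split(cohort_rows(cohort, split$train),
                       cohort_rows(cohort, split$test),
                       imp_spec)
    for (hi in seq_along(h_grid)) {
      cfg <- rvfl_config(h = h_grid[hi], L = L, seed = seeds[r])
      layers <- init_layers(cfg, ncol(d$X_tr), variant)
      fwd_tr <- forward_hidden(d$X_tr, layers, variant, cfg$activation)
      fwd_ev <- forward_hidden(d$X_ev, layers, variant, cfg$activation)
      for (ei in seq_along(eta_grid)) {
        pred <- if (variant == "edrvfl") {
          S <- vapply(seq_along(layers), function(l) {
            beta <- ridge_solve(cbind(fwd_tr$H_list[[l]], d$X_tr),
                                d$y_tr, eta_grid[ei])
            as.numeric(cbind(fwd_ev$H_list[[l]], d$X_ev) %*% beta)
          }, numeric(nrow(d$X_ev)))
          as.integer(rowMeans(matrix(S, nrow = nrow(d$X_ev))) >= 0.5)
        } else {
          beta <- ridge_solve(fwd_tr$D, d$y_tr, eta_grid[ei])
          as.integer(fwd_ev$D %*% beta >= 0.5)
        }
        acc[hi, ei, r] <- mean(pred == d$y_ev)
      }
    }
  }
  out <- expand.grid(h = h_grid, eta = eta_grid, KEEP.OUT.ATTRS = FALSE)
  out$accuracy <- as.numeric(apply(acc, c(1, 2), mean))
  out
}
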