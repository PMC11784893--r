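#' Cohort tables
#'
#' A cohort table holds one row per participant: raw variable values (one
#' column per categorical variable, one per numeric element), a binary
#' diagnosis label (0 = CN, 1 = MCI), and explicit missingness (`NA` cells).
#' The generating schema travels with the table.
#'
#' @param values data.frame of raw columns in schema order (character for
#'   categoricals, numeric otherwise); `NA` marks a missing cell.
#' @param labels integer vector of 0/1 diagnoses, one per row.
#' @param schema the [feature_schema()] the columns conform to.
#' @param pid participant identifiers (defaults to row numbers).
#' @return a `cohort_table` object.
#' @export
cohort_table <- function(values, labels, schema, pid = NULL) {
  stopifnot(is.data.frame(values), inherits(schema, "feature_schema"))
  cols <- schema_columns(schema)
  if (!identical(names(values), cols))
    stop("cohort columns must match the schema exactly")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels and values must have the same number of rows")
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must all be 0 (CN) or 1 (MCI)")
  if (is.null(pid)) pid <- seq_len(nrow(values))
  structure(list(values = values, labels = labels, schema = schema,
                 pid = pid),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$values), "participants (",
      sum(x$labels == 0L), "CN /", sum(x$labels == 1L), "MCI ),",
      ncol(x$values), "raw columns,",
      sum(is.na(as.matrix(x$values))), "missing cells\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Per-cell missingness mask
#'
#' @param cohort a [cohort_table()].
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(cohort) {
  m <- is.na(as.matrix(cohort$values))
  dimnames(m) <- list(NULL, names(cohort$values))
  m
}

# subset rows, keeping class/schema
cohort_rows <- function(cohort, idx) {
  cohort_table(cohort$values[idx, , drop = FALSE], cohort$labels[idx],
               cohort$schema, pid = cohort$pid[idx])
}

#' Generate a synthetic class-conditional cohort
#'
#' Draws a fully observed cohort from the schema's per-class generation
#' parameters. Each participant carries a latent severity score
#' `s ~ N(0, 1)`; a numeric element with per-class mean `mu`, SD `sigma`
#' and loading `lambda` is drawn as
#' `mu + sigma * (lambda * s + sqrt(1 - lambda^2) * e)`, `e ~ N(0, 1)`, so
#' per-class means and SDs match the schema exactly while all loaded
#' variables co-vary through the shared factor. Categorical values are
#' drawn independently from the per-class category probabilities.
#'
#' @param schema a [feature_schema()].
#' @param n_cn,n_mci participants per class (>= 1).
#' @param seed integer seed; output is a pure function of
#'   `(schema, n_cn, n_mci, seed)`.
#' @return a fully observed [cohort_table()] with `n_cn + n_mci` rows
#'   (CN rows first).
#' @export
generate_cohort <- function(schema, n_cn, n_mci, seed) {
  stopifnot(inherits(schema, "feature_schema"), n_cn >= 1L, n_mci >= 1L)
  n <- n_cn + n_mci
  labels <- c(rep(0L, n_cn), rep(1L, n_mci))
  cls <- class_names()[labels + 1L]

  with_seed(seed, {
    s <- rnorm(n)
    out <- vector("list", 0L)
    for (v in schema$variables) {
      if (v$kind == "categorical") {
        x <- character(n)
        for (k in seq_along(class_names())) {
          idx <- which(cls == class_names()[k])
          if (length(idx))
            x[idx] <- sample(v$categories, length(idx), replace = TRUE,
                             prob = v$gen_params$prob[, k])
        }
        out[[v$name]] <- x
      } else {
        lam <- v$gen_params$loading
        for (j in seq_len(v$dim)) {
          mu <- v$gen_params$mean[j, cls]
          sg <- v$gen_params$sd[j, cls]
          e <- rnorm(n)
          out[[element_names(v)[j]]] <-
            mu + sg * (lam * s + sqrt(1 - lam^2) * e)
        }
      }
    }
    cohort_table(as.data.frame(out, check.names = FALSE,
                               stringsAsFactors = FALSE),
                 labels, schema)
  })
}

#' Block missingness patterns
#'
#' Describes missing-completely-at-random masking applied per
#' (modality, class): `rates` maps each modality to a length-2 vector
#' `c(CN = , MCI = )` of masking probabilities in \[0, 1\]. With
#' `unit = "per_cell"` each cell of the modality is masked independently;
#' with `unit = "per_block"` all columns of the modality go missing jointly
#' for a selected participant.
#'
#' @param rates named list, modality -> `c(CN, MCI)` rates in \[0, 1\].
#' @param unit `"per_cell"` (default) or `"per_block"`.
#' @return a `missingness_pattern` object.
#' @export
missingness_pattern <- function(rates, unit = c("per_cell", "per_block")) {
  unit <- match.arg(unit)
  stopifnot(is.list(rates), length(names(rates)) == length(rates))
  bad <- setdiff(names(rates), modality_tags())
  if (length(bad))
    stop("unknown modality in missingness rates: ", paste(bad, collapse = ", "))
  rates <- lapply(rates, function(r) {
    r <- rep_len(as.numeric(r), 2L)
    if (any(is.na(r)) || any(r < 0) || any(r > 1))
      stop("missingness rates must lie in [0, 1]")
    names(r) <- class_names()
    r
  })
  structure(list(rates = rates, mechanism = "MCAR_block", unit = unit),
            class = "missingness_pattern")
}

#' Published per-modality baseline missingness rates
#'
#' The degree of missingness (fraction, per class) observed in each data
#' modality of the reference baseline study population; demographic and
#' genotype variables are fully observed.
#'
#' @param unit passed to [missingness_pattern()].
#' @return a [missingness_pattern()].
#' @export
table4_missingness <- function(unit = "per_cell") {
  missingness_pattern(list(
    demographic = c(0, 0),
    genotype    = c(0, 0),
    clinical    = c(0.7974, 0.3259),
    cognitive   = c(0.0720, 0.0733),
    CSF         = c(0.4435, 0.2639),
    MRI         = c(0.0611, 0.0916),
    FDG         = c(0.5726, 0.1794),
    AV45        = c(1.0000, 0.9842),
    PIB         = c(0.9194, 0.3931)
  ), unit = unit)
}

#' Apply MCAR block missingness to a cohort
#'
#' Masks cells (or whole modality blocks) independently at the pattern's
#' (modality, class) rates. Already-missing cells stay missing.
#'
#' @param cohort a [cohort_table()].
#' @param pattern a [missingness_pattern()]; rates must cover every
#'   modality present in the cohort's schema.
#' @param seed integer seed; deterministic given `(cohort, pattern, seed)`.
#' @return a [cohort_table()] with additional `NA` cells.
#' @export
apply_missingness <- function(cohort, pattern, seed) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(pattern, "missingness_pattern"))
  ci <- column_info(cohort$schema)
  present <- unique(ci$modality)
  absent <- setdiff(present, names(pattern$rates))
  if (length(absent))
    stop("pattern lacks rates for modality: ", paste(absent, collapse = ", "))

  vals <- cohort$values
  n <- nrow(vals)
  cls_idx <- cohort$labels + 1L

  with_seed(seed, {
    for (mod in present) {
      cols <- ci$column[ci$modality == mod]
      r <- pattern$rates[[mod]][cls_idx]     # per-row rate
      if (all(r == 0)) next
      if (pattern$unit == "per_block") {
        hit <- runif(n) < r
        if (any(hit)) vals[hit, cols] <- NA
      } else {
        for (cl in cols) {
          hit <- runif(n) < r
          if (any(hit)) vals[hit, cl] <- NA
        }
      }
    }
    cohort_table(vals, cohort$labels, cohort$schema, pid = cohort$pid)
  })
}

#' Read and write cohort CSV files
#'
#' One row per participant with columns `pid,label,<schema columns>`;
#' missing cells are written as empty fields and read back from empty
#' fields or the literal token `NA`. `read_cohort_csv()` after
#' [write_cohort_csv()] is the identity on (values, missingness, labels).
#'
#' @param path file path.
#' @param schema the [feature_schema()] the file must conform to.
#' @param cohort a [cohort_table()].
#' @return `read_cohort_csv()` returns a [cohort_table()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  cols <- schema_columns(schema)
  expected <- c("pid", "label", cols)
  if (!identical(names(raw), expected)) {
    extra <- setdiff(names(raw), expected)
    miss <- setdiff(expected, names(raw))
    stop("cohort CSV header mismatch",
         if (length(extra)) paste0("; unknown column(s): ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing column(s): ",
                                  paste(miss, collapse = ", ")))
  }
  as_missing <- function(x) x == "" | x == "NA" | is.na(x)

  lab_chr <- raw$label
  if (any(as_missing(lab_chr)))
    stop("missing label in row ", which(as_missing(lab_chr))[1])
  lab <- suppressWarnings(as.integer(lab_chr))
  bad <- is.na(lab) | !(lab %in% c(0L, 1L))
  if (any(bad))
    stop("label outside {0,1} in row ", which(bad)[1],
         " (value '", lab_chr[which(bad)[1]], "')")

  ci <- column_info(schema)
  vals <- vector("list", length(cols))
  names(vals) <- cols
  for (cl in cols) {
    x <- raw[[cl]]
    na <- as_missing(x)
    if (ci$kind[ci$column == cl] == "numeric") {
      num <- suppressWarnings(as.numeric(x))
      bad <- !na & is.na(num)
      if (any(bad))
        stop("non-numeric value '", x[which(bad)[1]], "' in numeric column '",
             cl, "', row ", which(bad)[1])
      num[na] <- NA_real_
      vals[[cl]] <- num
    } else {
      x[na] <- NA_character_
      vals[[cl]] <- x
    }
  }
  cohort_table(as.data.frame(vals, check.names = FALSE,
                             stringsAsFactors = FALSE),
               lab, schema, pid = raw$pid)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cbind(data.frame(pid = cohort$pid, label = cohort$labels),
              cohort$values)
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
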