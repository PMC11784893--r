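#' @name schema
#' @title Cohort feature schemas
#'
#' @description A feature schema is an ordered list of variable
#' specifications describing a mixed categorical/numeric baseline cohort
#' table: each variable has a modality tag (demographic, genotype, clinical,
#' cognitive, CSF, MRI, FDG, AV45, PIB), a kind, and per-class generation
#' parameters used by [generate_cohort()].
NULL

modality_tags <- function() {
  c("demographic", "genotype", "clinical", "cognitive",
    "CSF", "MRI", "FDG", "AV45", "PIB")
}

class_names <- function() c("CN", "MCI")

#' Describe one cohort variable
#'
#' @param name variable name (unique within a schema).
#' @param kind `"categorical"` or `"numeric"`.
#' @param modality one of the modality tags (see [modality_tags()]).
#' @param categories category labels (categorical variables only, >= 2).
#' @param dim element count for vector-valued numeric variables (1 for
#'   scalars).
#' @param gen_params per-class generation parameters. For categoricals a
#'   list with `prob`, a `length(categories) x 2` matrix of per-class
#'   category probabilities (columns `CN`, `MCI`, each summing to 1). For
#'   numerics a list with `mean` and `sd` (`dim x 2` matrices, or length-2
#'   vectors recycled over elements; columns `CN`, `MCI`) and a scalar
#'   `loading` in \[0, 1\] giving the variable's weight on the shared latent
#'   severity factor.
#'
#' @return a `variable_spec` object.
#' @export
variable_spec <- function(name, kind = c("categorical", "numeric"), modality,
                          categories = NULL, dim = 1L, gen_params = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind)
  if (!is.character(modality) || length(modality) != 1L ||
      !modality %in% modality_tags())
    stop("unknown modality tag '", modality, "' for variable '", name, "'")

  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("categorical variable '", name, "' needs >= 2 categories")
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("duplicate categories in variable '", name, "'")
    prob <- gen_params$prob
    if (is.null(prob))
      prob <- matrix(1 / length(categories), length(categories), 2L)
    prob <- as.matrix(prob)
    if (nrow(prob) != length(categories) || ncol(prob) != 2L)
      stop("gen_params$prob of '", name, "' must be ",
           length(categories), " x 2")
    if (any(prob < 0))
      stop("negative category probability in variable '", name, "'")
    if (any(abs(colSums(prob) - 1) > 1e-9))
      stop("per-class category probabilities of '", name,
           "' must sum to 1 (tolerance 1e-9)")
    dimnames(prob) <- list(categories, class_names())
    dim <- 1L
    gp <- list(prob = prob)
  } else {
    dim <- as.integer(dim)
    if (is.na(dim) || dim < 1L)
      stop("numeric variable '", name, "' needs dim >= 1")
    categories <- NULL
    expand <- function(x, what) {
      m <- if (is.matrix(x)) x else matrix(x, dim, 2L, byrow = TRUE)
      if (nrow(m) != dim || ncol(m) != 2L)
        stop("gen_params$", what, " of '", name, "' must be ", dim, " x 2")
      dimnames(m) <- list(NULL, class_names())
      m
    }
    mean_m <- expand(if (is.null(gen_params$mean)) 0 else gen_params$mean,
                     "mean")
    sd_m <- expand(if (is.null(gen_params$sd)) 1 else gen_params$sd, "sd")
    if (any(sd_m <= 0))
      stop("numeric SDs of variable '", name, "' must be strictly positive")
    loading <- if (is.null(gen_params$loading)) 0 else gen_params$loading
    if (!is.numeric(loading) || length(loading) != 1L ||
        loading < 0 || loading > 1)
      stop("loading of variable '", name, "' must be a scalar in [0, 1]")
    gp <- list(mean = mean_m, sd = sd_m, loading = loading)
  }

  structure(list(name = name, kind = kind, modality = modality,
                 categories = categories, dim = dim, gen_params = gp),
            class = "variable_spec")
}

#' Assemble a feature schema
#'
#' @param variables list of [variable_spec()] objects, in column order.
#' @param class_labels named integer vector mapping class names to label
#'   codes; fixed to `c(CN = 0, MCI = 1)` for the binary staging task.
#' @return a `feature_schema` object.
#' @export
feature_schema <- function(variables, class_labels = c(CN = 0L, MCI = 1L)) {
  stopifnot(is.list(variables), length(variables) >= 1L)
  ok <- vapply(variables, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all schema entries must be variable_spec objects")
  nm <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("variable names must be unique")
  names(variables) <- nm
  structure(list(variables = variables, class_labels = class_labels),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("feature_schema:", length(x$variables), "variables,",
      n_numeric_columns(x), "numeric columns,",
      n_onehot_columns(x), "one-hot columns\n")
  invisible(x)
}

#' Column accounting helpers
#'
#' `n_numeric_columns()` counts numeric element columns (vector-valued
#' variables counted element-wise); `n_onehot_columns()` counts the total
#' one-hot expansion of the categorical variables; `schema_columns()` lists
#' the raw cohort-table column names, one per categorical variable and one
#' per numeric element (`name` for scalars, `name_k` for vector elements).
#'
#' @param schema a [feature_schema()].
#' @return integer count or character vector of column names.
#' @export
n_numeric_columns <- function(schema) {
  sum(vapply(schema$variables,
             function(v) if (v$kind == "numeric") v$dim else 0L, integer(1)))
}

#' @rdname n_numeric_columns
#' @export
n_onehot_columns <- function(schema) {
  sum(vapply(schema$variables,
             function(v) if (v$kind == "categorical")
               length(v$categories) else 0L, integer(1)))
}

element_names <- function(v) {
  if (v$kind == "categorical" || v$dim == 1L) v$name
  else paste0(v$name, "_", seq_len(v$dim))
}

#' @rdname n_numeric_columns
#' @export
schema_columns <- function(schema) {
  unlist(lapply(schema$variables, element_names), use.names = FALSE)
}

# per raw column: variable name, kind, modality
column_info <- function(schema) {
  do.call(rbind, lapply(schema$variables, function(v) {
    data.frame(column = element_names(v), variable = v$name, kind = v$kind,
               modality = v$modality, stringsAsFactors = FALSE)
  }))
}

numeric_column_names <- function(schema) {
  ci <- column_info(schema)
  ci$column[ci$kind == "numeric"]
}

categorical_variable_names <- function(schema) {
  nm <- vapply(schema$variables, `[[`, character(1), "name")
  nm[vapply(schema$variables, `[[`, character(1), "kind") == "categorical"]
}

# discretized normal over integer category labels, renormalized
discretized_normal_prob <- function(levels, mean, sd) {
  lv <- as.numeric(levels)
  p <- pnorm(lv + 0.5, mean, sd) - pnorm(lv - 0.5, mean, sd)
  p / sum(p)
}

# per-class (mean, sd) for a variable without printed summary statistics:
# the MCI mean is displaced from the CN mean along the latent severity axis
# by direction * loading * severity_weight standard deviations
derived_gp <- function(mean_cn, sd, direction, loading, severity_weight) {
  d <- length(mean_cn)
  direction <- rep_len(direction, d)
  sd <- rep_len(sd, d)
  list(mean = cbind(CN = mean_cn,
                    MCI = mean_cn + direction * loading * severity_weight * sd),
       sd = cbind(CN = sd, MCI = sd),
       loading = loading)
}

#' Default baseline cohort schema
#'
#' Builds the package's reference schema for a two-class (CN vs MCI)
#' baseline cohort: 44 numeric feature columns (everyday-cognition ECog as a
#' 14-vector, ADAS-Cog as a 3-vector, RAVLT as a 4-vector, the rest scalars)
#' and categorical variables whose one-hot expansion totals 29 columns
#' (gender 2, ethnicity 2, race 6, marital status 4, APOE4 allele count 3,
#' education 12), i.e. 73 encoded columns in total. Variables with published
#' baseline summary statistics (age, education, APOE4, CDR sum-of-boxes,
#' MMSE) carry those per-class parameters; the remaining parameters are
#' package defaults chosen to be realistic for an elderly memory-clinic
#' population, with MCI means displaced along a shared latent severity
#' factor (see [generate_cohort()]).
#'
#' @param config_overrides optional named list: for each named variable, a
#'   list of `variable_spec` fields to replace (merged into `gen_params`
#'   etc. then re-validated). Naming an unknown variable is an error.
#' @param severity_weight displacement, in within-class standard deviations
#'   per unit loading, between the CN and MCI means of the unanchored
#'   numeric variables (default 2).
#' @param education_levels number of education-year levels (default 12,
#'   spanning 9-20 completed years).
#' @return a [feature_schema()].
#' @export
build_default_schema <- function(config_overrides = NULL,
                                 severity_weight = 2,
                                 education_levels = 12L) {
  sw <- severity_weight
  edu_lv <- as.character(seq(21L - as.integer(education_levels), 20L))

  vs <- list(
    variable_spec("gender", "categorical", "demographic",
                  categories = c("Female", "Male"),
                  gen_params = list(prob = cbind(CN = c(61, 63) / 124,
                                                 MCI = c(151, 228) / 379))),
    variable_spec("ethnicity", "categorical", "demographic",
                  categories = c("Hisp/Latino", "Not Hisp/Latino"),
                  gen_params = list(prob = cbind(CN = c(0.04, 0.96),
                                                 MCI = c(0.04, 0.96)))),
    variable_spec("race", "categorical", "demographic",
                  categories = c("Am Indian/Alaskan", "Asian", "Black",
                                 "Hawaiian/Other PI", "More than one",
                                 "White"),
                  gen_params = list(prob = cbind(
                    CN = c(0.005, 0.02, 0.045, 0.002, 0.013, 0.915),
                    MCI = c(0.005, 0.02, 0.045, 0.002, 0.013, 0.915)))),
    variable_spec("marital", "categorical", "demographic",
                  categories = c("Divorced", "Married", "Never married",
                                 "Widowed"),
                  gen_params = list(prob = cbind(CN = c(0.10, 0.72, 0.05, 0.13),
                                                 MCI = c(0.10, 0.76, 0.04, 0.10)))),
    variable_spec("education", "categorical", "demographic",
                  categories = edu_lv,
                  gen_params = list(prob = cbind(
                    CN = discretized_normal_prob(edu_lv, 16.28, 2.68),
                    MCI = discretized_normal_prob(edu_lv, 16.08, 2.73)))),
    variable_spec("apoe4", "categorical", "genotype",
                  categories = c("0", "1", "2"),
                  gen_params = list(prob = cbind(CN = c(89, 33, 2) / 124,
                                                 MCI = c(184, 151, 44) / 379))),
    variable_spec("age", "numeric", "demographic",
                  gen_params = list(mean = c(75.45, 71.98),
                                    sd = c(5.46, 7.34), loading = 0.2)),
    variable_spec("cdrsb", "numeric", "clinical",
                  gen_params = list(mean = c(0.04, 1.44),
                                    sd = c(0.14, 0.87), loading = 0.6)),
    variable_spec("faq", "numeric", "clinical",
                  gen_params = derived_gp(0.2, 1.1, +1, 0.5, sw)),
    variable_spec("ecog", "numeric", "clinical", dim = 14L,
                  gen_params = derived_gp(rep(1.35, 14), rep(0.4, 14),
                                          +1, 0.4, sw)),
    variable_spec("mmse", "numeric", "cognitive",
                  gen_params = list(mean = c(29.16, 27.77),
                                    sd = c(1.06, 1.77), loading = 0.5)),
    variable_spec("adas", "numeric", "cognitive", dim = 3L,
                  gen_params = derived_gp(c(8.5, 13.0, 2.8), c(4.0, 6.0, 1.8),
                                          +1, 0.5, sw)),
    variable_spec("moca", "numeric", "cognitive",
                  gen_params = derived_gp(25.8, 2.3, -1, 0.5, sw)),
    variable_spec("ravlt", "numeric", "cognitive", dim = 4L,
                  gen_params = derived_gp(c(45, 5.8, 3.8, 35),
                                          c(10, 2.3, 2.7, 27),
                                          c(-1, -1, +1, +1), 0.5, sw)),
    variable_spec("ldeltotal", "numeric", "cognitive",
                  gen_params = derived_gp(13.5, 3.3, -1, 0.5, sw)),
    variable_spec("trabscor", "numeric", "cognitive",
                  gen_params = derived_gp(85, 40, +1, 0.4, sw)),
    variable_spec("digitscor", "numeric", "cognitive",
                  gen_params = derived_gp(45, 10, -1, 0.4, sw)),
    variable_spec("mpacc_digit", "numeric", "cognitive",
                  gen_params = derived_gp(0.3, 2.6, -1, 0.5, sw)),
    variable_spec("mpacc_trailsb", "numeric", "cognitive",
                  gen_params = derived_gp(0.2, 2.8, -1, 0.5, sw)),
    variable_spec("abeta", "numeric", "CSF",
                  gen_params = derived_gp(1100, 440, -1, 0.4, sw)),
    variable_spec("tau", "numeric", "CSF",
                  gen_params = derived_gp(240, 90, +1, 0.4, sw)),
    variable_spec("ptau", "numeric", "CSF",
                  gen_params = derived_gp(22, 9, +1, 0.4, sw)),
    variable_spec("ventricles", "numeric", "MRI",
                  gen_params = derived_gp(34000, 19000, +1, 0.3, sw)),
    variable_spec("hippocampus", "numeric", "MRI",
                  gen_params = derived_gp(7400, 900, -1, 0.3, sw)),
    variable_spec("wholebrain", "numeric", "MRI",
                  gen_params = derived_gp(1040000, 100000, -1, 0.3, sw)),
    variable_spec("entorhinal", "numeric", "MRI",
                  gen_params = derived_gp(3800, 700, -1, 0.3, sw)),
    variable_spec("fusiform", "numeric", "MRI",
                  gen_params = derived_gp(18000, 2500, -1, 0.3, sw)),
    variable_spec("midtemp", "numeric", "MRI",
                  gen_params = derived_gp(20500, 2800, -1, 0.3, sw)),
    variable_spec("icv", "numeric", "MRI",
                  gen_params = derived_gp(1530000, 160000, +1, 0.0, sw)),
    variable_spec("fdg", "numeric", "FDG",
                  gen_params = derived_gp(1.31, 0.12, -1, 0.4, sw)),
    variable_spec("av45", "numeric", "AV45",
                  gen_params = derived_gp(1.12, 0.19, +1, 0.4, sw)),
    variable_spec("pib", "numeric", "PIB",
                  gen_params = derived_gp(1.45, 0.35, +1, 0.4, sw))
  )
  names(vs) <- vapply(vs, `[[`, character(1), "name")

  if (!is.null(config_overrides)) {
    stopifnot(is.list(config_overrides))
    unknown <- setdiff(names(config_overrides), names(vs))
    if (length(unknown))
      stop("config override names unknown variable(s): ",
           paste(unknown, collapse = ", "))
    for (nm in names(config_overrides)) {
      ov <- config_overrides[[nm]]
      cur <- vs[[nm]]
      fields <- cur[c("name", "kind", "modality", "categories", "dim",
                      "gen_params")]
      if (!is.null(ov$gen_params)) {
        fields$gen_params <- modifyList(fields$gen_params, ov$gen_params)
        ov$gen_params <- NULL
      }
      fields[names(ov)] <- ov
      vs[[nm]] <- do.call(variable_spec, fields)
    }
  }

  feature_schema(vs)
}
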