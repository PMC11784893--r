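#' Rank classifiers within each condition
#'
#' Within every row of the performance matrix (one row per condition, here
#' an imputation method; one column per classifier) rank 1 goes to the
#' best score; ties receive the mean of the spanned ranks, so each row
#' sums to `c(c+1)/2` exactly.
#'
#' @param perf numeric matrix, conditions x classifiers (finite entries,
#'   >= 2 of each).
#' @return a `rank_matrix`: list with `ranks` (same shape as `perf`) and
#'   `avg_ranks` (per-classifier column means).
#' @export
average_ranks <- function(perf) {
  perf <- as.matrix(perf)
  if (nrow(perf) < 2L || ncol(perf) < 2L)
    stop("performance matrix needs >= 2 conditions and >= 2 classifiers")
  if (any(!is.finite(perf))) stop("non-finite performance entry")
  ranks <- t(apply(perf, 1, function(r) rank(-r, ties.method = "average")))
  dimnames(ranks) <- dimnames(perf)
  structure(list(ranks = ranks, avg_ranks = colMeans(ranks)),
            class = "rank_matrix")
}

# upper-tail chi-squared probability used for the Friedman p-value
chi2_upper_tail <- function(stat, df) pchisq(stat, df, lower.tail = FALSE)

#' Friedman rank test
#'
#' `chi2_F = 12 D / (c (c+1)) * (sum_j R_j^2 - c (c+1)^2 / 4)` over the
#' average ranks `R_j` of `c` classifiers across `D` conditions, referred
#' to the chi-squared distribution with `c - 1` degrees of freedom.
#'
#' @param rank_matrix a `rank_matrix` from [average_ranks()].
#' @return list with `chi2_F`, `df`, `p_value`, `D`, `c`.
#' @export
friedman_test <- function(rank_matrix) {
  stopifnot(inherits(rank_matrix, "rank_matrix"))
  D <- nrow(rank_matrix$ranks)
  c_clf <- ncol(rank_matrix$ranks)
  R <- rank_matrix$avg_ranks
  chi2 <- 12 * D / (c_clf * (c_clf + 1)) *
    (sum(R^2) - c_clf * (c_clf + 1)^2 / 4)
  chi2 <- max(chi2, 0)
  structure(list(chi2_F = chi2, df = c_clf - 1L,
                 p_value = chi2_upper_tail(chi2, c_clf - 1L),
                 D = D, c = c_clf),
            class = "friedman_result")
}

#' Nemenyi critical difference
#'
#' `CD = q_alpha * sqrt(c (c+1) / (6 D))`, with `q_alpha` the Studentized
#' range critical value for `c` groups at level `alpha` (infinite degrees
#' of freedom) divided by `sqrt(2)` — the standard convention that
#' reproduces the published two-decimal q tables.
#'
#' @param c_clf number of classifiers compared (>= 2).
#' @param D_cond number of conditions ("datasets", here imputation
#'   methods, >= 1).
#' @param alpha significance level (any level supported through the
#'   Studentized-range quantile; 0.05 and 0.10 are the conventional
#'   choices).
#' @return a `nemenyi_result`: list with `alpha`, `q_alpha`, `cd`.
#' @export
nemenyi_cd <- function(c_clf, D_cond, alpha = 0.05) {
  stopifnot(c_clf >= 2L, D_cond >= 1L, alpha > 0, alpha < 1)
  q_alpha <- qtukey(1 - alpha, nmeans = c_clf, df = Inf) / sqrt(2)
  structure(list(alpha = alpha, q_alpha = q_alpha,
                 cd = q_alpha * sqrt(c_clf * (c_clf + 1) / (6 * D_cond)),
                 c = c_clf, D = D_cond),
            class = "nemenyi_result")
}

#' Classifier pairs whose average ranks differ significantly
#'
#' @param rank_matrix a `rank_matrix`.
#' @param nemenyi a `nemenyi_result`; a pair is flagged when
#'   `|R_i - R_j| > cd`.
#' @return data.frame of unordered pairs with columns `a`, `b`,
#'   `rank_diff`.
#' @export
significant_pairs <- function(rank_matrix, nemenyi) {
  stopifnot(inherits(rank_matrix, "rank_matrix"),
            inherits(nemenyi, "nemenyi_result"))
  R <- rank_matrix$avg_ranks
  nms <- names(R)
  if (is.null(nms)) nms <- paste0("clf", seq_along(R))
  out <- list()
  for (i in seq_along(R)) for (j in seq_along(R)) {
    if (i < j && abs(R[i] - R[j]) > nemenyi$cd)
      out[[length(out) + 1L]] <- data.frame(a = nms[i], b = nms[j],
                                            rank_diff = abs(R[i] - R[j]))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a = character(), b = character(), rank_diff = numeric())
}

# maximal cliques of the non-significance relation |R_i - R_j| <= cd;
# on a line these are maximal windows of the sorted average ranks
rank_cliques <- function(avg_ranks, cd) {
  ord <- order(avg_ranks)
  R <- avg_ranks[ord]
  n <- length(R)
  wins <- lapply(seq_len(n), function(i) {
    j <- i
    while (j < n && R[j + 1] - R[i] <= cd) j <- j + 1
    ord[i:j]
  })
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && keep[i] && all(wins[[i]] %in% wins[[j]]) &&
        length(wins[[i]]) < length(wins[[j]]))
      keep[i] <- FALSE
  }
  unique(wins[keep])
}

#' Critical-difference diagram
#'
#' Renders the classical number-line summary of a Nemenyi comparison:
#' classifiers placed at their average ranks (rank 1 = best, leftmost), a
#' bar showing the critical difference, and connector bars joining maximal
#' groups of classifiers whose ranks differ by at most the CD. Writes an
#' SVG rendering and a plain-text rendering (same path with a `.txt`
#' extension) and returns the text form.
#'
#' @param rank_matrix a `rank_matrix` from [average_ranks()].
#' @param nemenyi a `nemenyi_result` from [nemenyi_cd()].
#' @param path output SVG path (the text twin replaces the extension with
#'   `.txt`).
#' @return the plain-text rendering, invisibly.
#' @export
cd_diagram <- function(rank_matrix, nemenyi, path) {
  stopifnot(inherits(rank_matrix, "rank_matrix"),
            inherits(nemenyi, "nemenyi_result"))
  R <- rank_matrix$avg_ranks
  if (is.null(names(R))) names(R) <- paste0("clf", seq_along(R))
  c_clf <- length(R)
  cliques <- rank_cliques(R, nemenyi$cd)

  txt <- c(sprintf("critical-difference diagram (alpha = %g, CD = %.3f)",
                   nemenyi$alpha, nemenyi$cd),
           "average ranks (1 = best):",
           sprintf("  %6.3f  %s", R[order(R)], names(R)[order(R)]),
           "non-significant groups:",
           vapply(cliques, function(cl)
             paste0("  { ", paste(names(R)[sort(cl)], collapse = ", "),
                    " }"), character(1)))
  txt_path <- sub("\\.svg$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  writeLines(txt, txt_path)

  writeLines(cd_diagram_svg(R, nemenyi, cliques), path)
  invisible(paste(txt, collapse = "\n"))
}

cd_diagram_svg <- function(R, nemenyi, cliques) {
  c_clf <- length(R)
  width <- 640; margin <- 60
  axis_y <- 70
  scale_x <- function(r) margin + (r - 1) / max(c_clf - 1, 1) *
    (width - 2 * margin)
  ord <- order(R)
  # alternate labels left/right column, stacked below the axis
  label_y <- axis_y + 30 + seq_len(c_clf) * 16
  clique_y <- axis_y + 8 + (seq_along(cliques) - 1) * 6
  height <- max(label_y) + 20

  sv <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                         'width="%d" height="%d" font-family="sans-serif" ',
                         'font-size="11">'), width, height),
          sprintf('<line x1="%g" y1="%d" x2="%g" y2="%d" stroke="black"/>',
                  scale_x(1), axis_y, scale_x(c_clf), axis_y),
          unlist(lapply(seq_len(c_clf), function(k) c(
            sprintf(paste0('<line x1="%g" y1="%d" x2="%g" y2="%d" ',
                           'stroke="black"/>'),
                    scale_x(k), axis_y - 4, scale_x(k), axis_y + 4),
            sprintf('<text x="%g" y="%d" text-anchor="middle">%d</text>',
                    scale_x(k), axis_y - 8, k)))),
          # CD ruler
          sprintf(paste0('<line x1="%g" y1="%d" x2="%g" y2="%d" ',
                         'stroke="black"/>'),
                  scale_x(1), axis_y - 40, scale_x(1 + nemenyi$cd),
                  axis_y - 40),
          sprintf('<text x="%g" y="%d">CD = %.3f</text>',
                  scale_x(1), axis_y - 46, nemenyi$cd),
          # clique connector bars
          unlist(lapply(seq_along(cliques), function(i) {
            cl <- cliques[[i]]
            sprintf(paste0('<line x1="%g" y1="%g" x2="%g" y2="%g" ',
                           'stroke="black" stroke-width="3"/>'),
                    scale_x(min(R[cl])), clique_y[i],
                    scale_x(max(R[cl])), clique_y[i])
          })),
          # classifier markers and labels
          unlist(lapply(seq_len(c_clf), function(k) {
            j <- ord[k]
            c(sprintf(paste0('<line x1="%g" y1="%d" x2="%g" y2="%g" ',
                             'stroke="grey"/>'),
                      scale_x(R[j]), axis_y, scale_x(R[j]),
                      label_y[k] - 4),
              sprintf('<text x="%g" y="%g">%s (%.3f)</text>',
                      scale_x(R[j]) + 3, label_y[k], names(R)[j], R[j]))
          })),
          '</svg>')
  sv
}
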