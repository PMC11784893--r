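#!/usr/bin/env Rscript

# Rank-based comparison of the classifiers across imputation methods:
# average ranks of test accuracy, the Friedman test of equal performance,
# and Nemenyi critical-difference diagrams at alpha = 0.10 and 0.05.

suppressPackageStartupMessages({
  library(edrvfl)
  library(jsonlite)
})

cells <- read.csv("results/result_grid.csv")
acc <- cells[cells$metric == "accuracy", ]
perf <- tapply(acc$mean, list(acc$method, acc$model), identity)
cat("performance matrix (mean accuracy):\n")
print(round(perf, 3))

rk <- average_ranks(perf)
cat("\naverage ranks (1 = best):\n")
print(sort(round(rk$avg_ranks, 2)))
write.csv(data.frame(classifier = names(rk$avg_ranks),
                     avg_rank = rk$avg_ranks),
          "results/ranks.csv", row.names = FALSE)

fr <- friedman_test(rk)
cat(sprintf("\nFriedman: chi2_F = %.3f, df = %d, p = %.3g\n",
            fr$chi2_F, fr$df, fr$p_value))
write_json(fr[c("chi2_F", "df", "p_value", "D", "c")],
           "results/friedman.json", auto_unbox = TRUE, digits = NA)

nem <- lapply(c(0.10, 0.05), function(a) {
  n <- nemenyi_cd(ncol(perf), nrow(perf), a)
  cat(sprintf("Nemenyi alpha = %.2f: q = %.3f, CD = %.3f\n",
              a, n$q_alpha, n$cd))
  sp <- significant_pairs(rk, n)
  if (nrow(sp)) {
    cat("  significant pairs:\n")
    print(sp, row.names = FALSE)
  } else cat("  no pair exceeds the critical difference\n")
  out <- sprintf("results/cd_diagram_alpha%02d.svg", round(100 * a))
  cd_diagram(rk, n, out)
  cat("  wrote", out, "\n")
  c(n[c("alpha", "q_alpha", "cd")], list(significant = sp))
})
write_json(nem, "results/nemenyi.json", auto_unbox = TRUE, digits = NA)
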