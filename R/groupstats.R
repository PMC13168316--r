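# Gated univariate group comparisons for process quantities (titers, IVCD,
# rates, indices). Assumption gate: Shapiro-Wilk on ANOVA residuals and
# Levene's test; both pass -> one-way ANOVA with Tukey HSD, otherwise
# Kruskal-Wallis with Dunn's post hoc test (BH-corrected by default).

# Dunn's test: pairwise z from mean ranks with tie correction
.dunn_test <- function(values, groups, p_adjust = "BH") {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  est <- z <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    est[i] <- mean_rank[a] - mean_rank[b]
    z[i] <- est[i] / se
  }
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(
    pair = paste(pairs[1, ], pairs[2, ], sep = " - "),
    estimate = est, statistic = z, p = p,
    adj_p = stats::p.adjust(p, method = p_adjust),
    stringsAsFactors = FALSE
  )
}

#' Gated group comparison: ANOVA/Tukey or Kruskal-Wallis/Dunn
#'
#' Tests a numeric response across groups. Normality of the one-way ANOVA
#' residuals (Shapiro-Wilk) and homogeneity of variances (Levene's test,
#' median-centered) are checked at `alpha_gate`; if both pass, the
#' parametric branch runs one-way ANOVA followed by Tukey's HSD, otherwise
#' the nonparametric branch runs Kruskal-Wallis followed by Dunn's post hoc
#' test with multiple-comparison correction. Pairwise adjusted p-values are
#' labelled with significance stars.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (factor or character), >= 2 groups with >= 2
#'   observations each.
#' @param alpha_gate Significance level of the assumption gate (default
#'   0.05).
#' @param mode `"all_pairs"` for every pairwise comparison or
#'   `"vs_reference"` to keep only comparisons against `reference`.
#' @param reference Reference group label for `mode = "vs_reference"`.
#' @param dunn_adjust Correction method for Dunn's test (`"BH"` default;
#'   `"bonferroni"` or `"holm"` also supported).
#' @return Object of class `group_comparison`: gate p-values, chosen
#'   `branch`, omnibus `statistic` and `p`, and a `pairwise` table with
#'   columns `pair`, `estimate`, `p`, `adj_p`, `stars`.
#' @export
compare_groups <- function(values, groups, alpha_gate = 0.05,
                           mode = c("all_pairs", "vs_reference"),
                           reference = "STD",
                           dunn_adjust = c("BH", "bonferroni", "holm")) {
  mode <- match.arg(mode)
  dunn_adjust <- match.arg(dunn_adjust)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }

  fit <- stats::aov(values ~ groups)
  shapiro_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                        error = function(e) 0)
  levene_p <- car::leveneTest(values ~ groups)[1, "Pr(>F)"]
  parametric <- is.finite(shapiro_p) && is.finite(levene_p) &&
    shapiro_p >= alpha_gate && levene_p >= alpha_gate

  if (parametric) {
    an <- stats::anova(fit)
    statistic <- an[1, "F value"]; omnibus_p <- an[1, "Pr(>F)"]
    tk <- stats::TukeyHSD(fit)$groups
    raw_pairs <- rownames(tk)
    pairwise <- data.frame(
      pair = gsub("-", " - ", raw_pairs, fixed = TRUE),
      estimate = tk[, "diff"], p = tk[, "p adj"], adj_p = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
  } else {
    kw <- stats::kruskal.test(values, groups)
    statistic <- unname(kw$statistic); omnibus_p <- kw$p.value
    dn <- .dunn_test(values, groups, p_adjust = dunn_adjust)
    pairwise <- dn[c("pair", "estimate", "p", "adj_p")]
  }
  pairwise$stars <- assign_stars(pairwise$adj_p)
  rownames(pairwise) <- NULL

  if (mode == "vs_reference") {
    sel <- grepl(paste0("(^|\\s)", .escape_re(reference), "($|\\s)"),
                 pairwise$pair)
    pairwise <- pairwise[sel, , drop = FALSE]
  }

  structure(
    list(shapiro_p = shapiro_p, levene_p = unname(levene_p),
         branch = if (parametric) "parametric" else "nonparametric",
         omnibus = if (parametric) "one-way ANOVA" else "Kruskal-Wallis",
         statistic = statistic, p = omnibus_p, pairwise = pairwise,
         alpha_gate = alpha_gate),
    class = "group_comparison"
  )
}

.escape_re <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' @export
print.group_comparison <- function(x, ...) {
  cat("Gate: Shapiro-Wilk p = ", signif(x$shapiro_p, 3),
      ", Levene p = ", signif(x$levene_p, 3),
      " -> ", x$branch, " branch\n", sep = "")
  cat(x$omnibus, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
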