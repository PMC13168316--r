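# Per-glycoform linear-model contrasts on clr values. Each glycoform is fit
# with an ordinary least-squares cell-means model over the strategy x phase
# cells; contrasts of cell means are tested with either plain OLS t-tests or
# empirical-Bayes moderated t-tests (per-glycoform residual variances shrunk
# toward a pooled inverse-gamma prior fit by matching moments of the log
# variances, with correspondingly augmented degrees of freedom). P-values are
# adjusted across glycoforms within one comparison (Benjamini-Hochberg).

#' Fit per-glycoform cell-means models
#'
#' One OLS fit per glycoform, with one coefficient per (strategy x phase)
#' cell (or any other cell definition given by `cells`).
#'
#' @param clr A `clr_matrix` (samples x glycoforms) or plain matrix.
#' @param metadata Sample metadata; defaults to the `clr_matrix` metadata.
#' @param cells Character vector naming the metadata columns whose
#'   interaction defines the cells (default `c("strategy", "phase")`).
#' @return Object of class `glyco_fit`: `coefficients` (cells x glycoforms
#'   matrix of cell means), `sigma2` (per-glycoform residual variance), `df`
#'   (residual degrees of freedom), `n_per_cell`, `cell_levels`.
#' @export
fit_cell_means <- function(clr, metadata = .clr_metadata(clr),
                           cells = c("strategy", "phase")) {
  x <- .as_clr_values(clr)
  if (is.null(metadata)) stop("metadata required")
  miss <- setdiff(cells, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  cell <- interaction(metadata[cells], sep = ".", drop = TRUE)
  counts <- table(cell)
  if (any(counts < 2)) {
    stop("cell(s) with fewer than 2 replicates: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  design <- stats::model.matrix(~ 0 + cell)
  colnames(design) <- levels(cell)
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) stop("design matrix is rank deficient")
  coefs <- qr.coef(qrx, x)
  resid <- x - design %*% coefs
  df <- nrow(x) - ncol(design)
  sigma2 <- colSums(resid^2) / df
  structure(
    list(coefficients = coefs, sigma2 = sigma2, df = df,
         n_per_cell = as.vector(counts), cell_levels = levels(cell),
         glycoforms = colnames(x)),
    class = "glyco_fit"
  )
}

#' @export
print.glyco_fit <- function(x, ...) {
  cat("glyco_fit: ", length(x$glycoforms), " glycoforms, ",
      length(x$cell_levels), " cells, residual df = ", x$df, "\n", sep = "")
  invisible(x)
}

#' @export
coef.glyco_fit <- function(object, ...) object$coefficients

#' @export
summary.glyco_fit <- function(object, ...) {
  cat("Cell-means fit over cells:\n  ",
      paste(object$cell_levels, collapse = ", "), "\n", sep = "")
  cat("replicates per cell: ",
      paste(object$n_per_cell, collapse = ", "), "\n", sep = "")
  cat("residual variance range: ",
      signif(min(object$sigma2), 3), " - ", signif(max(object$sigma2), 3),
      "\n", sep = "")
  invisible(object)
}

# inverse of trigamma by Newton iteration (monotone, fast convergence)
.trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  x <- 0.5 + 1 / y[ok]
  for (i in 1:50) {
    tg <- trigamma(x)
    delta <- tg * (1 - tg / y[ok]) / psigamma(x, 2)
    x <- x + delta
    if (max(abs(delta / x)) < 1e-10) break
  }
  out[ok] <- x
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled inverse-chi-square prior (prior variance `s0^2`, prior df
#' `d0`) to the per-glycoform residual variances by matching the first two
#' moments of `log(sigma2)`, then returns posterior (shrunken) variances
#' `(d0 s0^2 + df sigma2) / (d0 + df)` and the augmented df `d0 + df`.
#'
#' @param sigma2 Per-glycoform residual variances.
#' @param df Residual degrees of freedom of each fit (scalar).
#' @return List with `s2_post`, `df_total`, `d0`, `s0_2`.
#' @export
moderate_variances <- function(sigma2, df) {
  stopifnot(all(sigma2 >= 0), df > 0)
  z <- log(pmax(sigma2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- mean(e)
  vv <- max(stats::var(e) - trigamma(df / 2), 0)
  if (vv > 0) {
    d0 <- 2 * .trigamma_inverse(vv)
    s0_2 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ev)
  }
  s2_post <- if (is.finite(d0)) {
    (d0 * s0_2 + df * sigma2) / (d0 + df)
  } else {
    rep(s0_2, length(sigma2))
  }
  list(s2_post = s2_post, df_total = d0 + df, d0 = d0, s0_2 = s0_2)
}

#' Test a contrast of cell means across glycoforms
#'
#' Effect sizes are contrasts of cell means on the clr (natural-log-ratio)
#' scale, reported divided by `ln 2` as log2 fold changes. With
#' `moderate = TRUE` the t-statistics use empirical-Bayes shrunken variances
#' and augmented df; otherwise plain OLS t-tests. Two-sided p-values are
#' Benjamini-Hochberg adjusted across glycoforms within this one comparison
#' and labelled with significance stars.
#'
#' @param fit A [fit_cell_means()] object.
#' @param contrast Named numeric vector of cell weights summing to 0 (names
#'   matching `fit$cell_levels`; unnamed cells get weight 0), or a full
#'   weight vector in cell order.
#' @param comparison Label for the comparison (carried into the result).
#' @param moderate Use empirical-Bayes moderated variances (default `TRUE`).
#' @return `data.frame` of class `contrast_result` with columns `comparison`,
#'   `glycoform`, `log2fc`, `t`, `df`, `p`, `adj_p`, `stars`.
#' @export
test_contrast <- function(fit, contrast, comparison = "contrast",
                          moderate = TRUE) {
  stopifnot(inherits(fit, "glyco_fit"))
  k <- length(fit$cell_levels)
  w <- numeric(k)
  names(w) <- fit$cell_levels
  if (!is.null(names(contrast)) && any(nzchar(names(contrast)))) {
    unknown <- setdiff(names(contrast), fit$cell_levels)
    if (length(unknown)) stop("unknown cell(s) in contrast: ",
                              paste(unknown, collapse = ", "))
    w[names(contrast)] <- contrast
  } else {
    stopifnot(length(contrast) == k)
    w[] <- contrast
  }
  if (abs(sum(w)) > 1e-10) stop("contrast weights must sum to 0")

  effect <- as.vector(t(fit$coefficients) %*% w)
  # var of contrast: sum w_c^2 / n_c times sigma2 (cell-means design)
  cfac <- sum(w^2 / fit$n_per_cell)
  if (moderate) {
    mod <- moderate_variances(fit$sigma2, fit$df)
    s2 <- mod$s2_post; dfree <- mod$df_total
  } else {
    s2 <- fit$sigma2; dfree <- fit$df
  }
  tstat <- effect / sqrt(s2 * cfac)
  p <- 2 * stats::pt(abs(tstat), df = dfree, lower.tail = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    comparison = comparison, glycoform = fit$glycoforms,
    log2fc = effect / log(2), t = tstat,
    df = if (length(dfree) == 1) rep(dfree, length(p)) else dfree,
    p = p, adj_p = adj, stars = assign_stars(adj),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Significance star labels for adjusted p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, else `"ns"`.
#' @export
assign_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Standard strategy/phase comparisons of a glycoform study
#'
#' Convenience wrapper running (i) stationary vs exponential within each
#' strategy and (ii) strategy vs strategy within each phase (versus a
#' reference strategy), on a fitted cell-means model with cells
#' `strategy.phase`.
#'
#' @param fit A [fit_cell_means()] with default `strategy`/`phase` cells.
#' @param reference Reference strategy for between-strategy contrasts
#'   (default `"STD"`); `NULL` skips them.
#' @param moderate Passed to [test_contrast()].
#' @return `data.frame` stacking all [test_contrast()] results.
#' @export
standard_contrasts <- function(fit, reference = "STD", moderate = TRUE) {
  lv <- fit$cell_levels
  parts <- strsplit(lv, ".", fixed = TRUE)
  strat <- vapply(parts, `[[`, character(1), 1)
  phase <- vapply(parts, `[[`, character(1), 2)
  out <- list()
  for (s in unique(strat)) {
    a <- lv[strat == s & phase == "sta"]; b <- lv[strat == s & phase == "exp"]
    if (length(a) == 1 && length(b) == 1) {
      out[[length(out) + 1L]] <- test_contrast(
        fit, stats::setNames(c(1, -1), c(a, b)),
        comparison = paste0(s, ": sta_vs_exp"), moderate = moderate
      )
    }
  }
  if (!is.null(reference)) {
    for (ph in unique(phase)) {
      ref <- lv[strat == reference & phase == ph]
      if (length(ref) != 1) next
      for (s in setdiff(unique(strat), reference)) {
        a <- lv[strat == s & phase == ph]
        if (length(a) != 1) next
        out[[length(out) + 1L]] <- test_contrast(
          fit, stats::setNames(c(1, -1), c(a, ref)),
          comparison = paste0(ph, ": ", s, "_vs_", reference),
          moderate = moderate
        )
      }
    }
  }
  do.call(rbind, out)
}
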