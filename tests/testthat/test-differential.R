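# Cell-means fits, empirical-Bayes moderation and contrast tests, with
# limma as an independent implementation where available.

build_clr <- function(shift = 0, n = 4, sigma = 0.1, seed = 1) {
  # two strategies, one phase, n reps each; second strategy shifted on the
  # first two glycoforms by `shift` (clr scale, before re-centering)
  spec <- strategy_presets()
  base <- simulate_glycoforms(spec$STD, "exp",
                              simulation_config(sigma_clr = sigma),
                              seed = seed, n_rep = n)
  cfg2 <- simulation_config(sigma_clr = sigma, delta_gal = shift)
  other <- simulate_glycoforms(spec$`STD+`, "exp", cfg2,
                               seed = seed + 500, n_rep = n)
  ab <- rbind(base$abundance, other$abundance)
  md <- rbind(base$metadata, other$metadata)
  clr_transform(glycoform_table(ab, md))
}

test_that("balanced cell-means coefficients equal cell means", {
  clr <- build_clr(seed = 2)
  fit <- fit_cell_means(clr)
  md <- clr$metadata
  for (s in unique(md$strategy)) {
    sel <- md$strategy == s
    expect_equal(unname(fit$coefficients[paste0(s, ".exp"), ]),
                 unname(colMeans(clr$values[sel, ])), tolerance = 1e-10)
  }
  expect_equal(fit$df, nrow(clr$values) - 2)
})

test_that("hand-solved 2x2 normal equations match the fit and noise-free variance is 0", {
  # 2 strategies x 2 phases, 2 reps per cell, one response column
  md <- data.frame(
    sample_id = paste0("s", 1:8),
    strategy = rep(c("STD", "LoG"), each = 4),
    phase = rep(c("exp", "exp", "sta", "sta"), 2),
    replicate = rep(c("r1", "r2"), 4)
  )
  y <- c(1.0, 1.2, 2.0, 2.2, 0.4, 0.6, 3.0, 3.4)
  x <- cbind(g1 = y, g2 = -y)
  rownames(x) <- md$sample_id
  fit <- fit_cell_means(x, metadata = md)
  # normal equations of a cell-means design reduce to per-cell averages
  cellmeans <- tapply(y, interaction(md[c("strategy", "phase")],
                                     sep = ".", drop = TRUE), mean)
  expect_equal(unname(fit$coefficients[, "g1"]),
               as.vector(cellmeans[fit$cell_levels]))
  # noise-free data: exact fit
  x0 <- cbind(g1 = rep(c(1, 1, 2, 2, 3, 3, 4, 4), 1))
  rownames(x0) <- md$sample_id
  expect_equal(unname(fit_cell_means(x0, metadata = md)$sigma2), 0)
})

test_that("contrasts recover constructed shifts as log2 fold changes", {
  clr <- build_clr(seed = 4, sigma = 0)
  fit <- fit_cell_means(clr)
  expect_error(test_contrast(fit, c(1, 1)), "sum to 0")

  # shift one group of a noise-free fit by exactly ln 2 on all columns:
  # clr re-centering cancels a constant, so apply it on the raw values
  x <- clr$values
  sel <- clr$metadata$strategy == "STD+"
  x[sel, 1] <- x[sel, 1] + log(2) * 1   # +ln2 on one glycoform
  x[sel, -1] <- x[sel, -1]              # others unchanged
  fit2 <- fit_cell_means(x, metadata = clr$metadata)
  res <- test_contrast(fit2, stats::setNames(c(1, -1),
                                             c("STD+.exp", "STD.exp")),
                       moderate = FALSE)
  expect_equal(res$log2fc[1], 1, tolerance = 1e-10)
  expect_equal(res$log2fc[-1], rep(0, nrow(res) - 1), tolerance = 1e-10)
})

test_that("unmoderated contrast t equals the classical two-sample pooled t", {
  clr <- build_clr(seed = 6, sigma = 0.15)
  fit <- fit_cell_means(clr)
  res <- test_contrast(fit, stats::setNames(c(1, -1),
                                            c("STD+.exp", "STD.exp")),
                       moderate = FALSE)
  md <- clr$metadata
  for (j in c(1, 4)) {
    tt <- stats::t.test(clr$values[md$strategy == "STD+", j],
                        clr$values[md$strategy == "STD", j],
                        var.equal = TRUE)
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated statistics agree with limma on the same design", {
  skip_if_not_installed("limma")
  clr <- build_clr(seed = 9, sigma = 0.12)
  md <- clr$metadata
  grp <- factor(md$strategy, levels = c("STD", "STD+"))
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- c("A", "B")
  lfit <- limma::lmFit(t(clr$values), design)
  lfit <- limma::contrasts.fit(lfit, contrasts = matrix(c(-1, 1), 2, 1))
  lfit <- limma::eBayes(lfit)

  fit <- fit_cell_means(clr, cells = "strategy")
  mod <- moderate_variances(fit$sigma2, fit$df)
  expect_equal(mod$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_2, lfit$s2.prior, tolerance = 1e-6)
  res <- test_contrast(fit, stats::setNames(c(1, -1), c("STD+", "STD")))
  expect_equal(res$t, unname(lfit$t[, 1]), tolerance = 1e-6)
  expect_equal(res$p, unname(lfit$p.value[, 1]), tolerance = 1e-6)
})

test_that("moderated and plain t converge as replication grows", {
  gaps <- vapply(c(3, 8, 20), function(n) {
    clr <- build_clr(seed = 20 + n, sigma = 0.1, n = n)
    fit <- fit_cell_means(clr)
    con <- stats::setNames(c(1, -1), c("STD+.exp", "STD.exp"))
    tm <- test_contrast(fit, con, moderate = TRUE)$t
    to <- test_contrast(fit, con, moderate = FALSE)$t
    mean(abs(tm - to))
  }, numeric(1))
  expect_lt(gaps[3], gaps[1])
})

test_that("BH adjustment is monotone and stars follow the thresholds", {
  clr <- build_clr(seed = 31, sigma = 0.1, shift = 0.6)
  fit <- fit_cell_means(clr)
  res <- test_contrast(fit, stats::setNames(c(1, -1),
                                            c("STD+.exp", "STD.exp")))
  expect_true(all(res$adj_p >= res$p - 1e-15))
  ord <- order(res$p)
  expect_true(all(diff(res$adj_p[ord]) >= -1e-15))
  expect_identical(assign_stars(c(0.0005, 0.005, 0.03, 0.5, 0.05)),
                   c("***", "**", "*", "ns", "ns"))
  expect_error(assign_stars(1.2), "\\[0, 1\\]")
})

test_that("positive planted shifts give positive log2FC with high probability", {
  hits <- vapply(1:20, function(s) {
    clr <- build_clr(seed = 100 + s, sigma = 0.1, shift = 0.3)
    fit <- fit_cell_means(clr)
    res <- test_contrast(fit, stats::setNames(c(1, -1),
                                              c("STD+.exp", "STD.exp")))
    gal <- vapply(lapply(res$glycoform, parse_glycoform), `[[`,
                  integer(1), "g_j") > 0
    mean(res$log2fc[gal]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
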