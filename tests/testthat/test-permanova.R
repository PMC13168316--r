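# PERMANOVA engine: sequential SS partition, permutation p-values, and the
# dispersion homogeneity test, checked against brute-force enumeration,
# the classical ANOVA limit, and vegan as an independent implementation.

sim_clr_study <- function(seed = 3) {
  spec <- strategy_presets()
  tab_e <- simulate_glycoforms(spec$STD, "exp", seed = seed)
  tab_s <- simulate_glycoforms(spec$STD, "sta", seed = seed + 1)
  tab_e2 <- simulate_glycoforms(spec$`STD+`, "exp", seed = seed + 2)
  tab_s2 <- simulate_glycoforms(spec$`STD+`, "sta", seed = seed + 3)
  ab <- rbind(tab_e$abundance, tab_s$abundance,
              tab_e2$abundance, tab_s2$abundance)
  md <- rbind(tab_e$metadata, tab_s$metadata,
              tab_e2$metadata, tab_s2$metadata)
  clr_transform(glycoform_table(ab, md))
}

test_that("two distinct tight groups give R2 = 1 and the exhaustive-minimum p", {
  x <- rbind(matrix(rep(c(0, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(5, 5), 3), 3, byrow = TRUE))
  rownames(x) <- paste0("s", 1:6)
  md <- two_group_meta(rownames(x), rep(c("STD", "LoG"), each = 3))
  perms <- two_group_assignments(3)
  res <- permanova(x, "strategy", metadata = md,
                   permutations = perms[-1, , drop = FALSE])
  expect_equal(res$table$r2[1], 1, tolerance = 1e-10)
  # only the identity and the wholesale group swap reproduce the perfect
  # separation: the exhaustive minimum achievable p is 2/20
  expect_equal(res$table$p[1], 2 / 20)
})

test_that("exhaustive 20-relabeling enumeration matches the engine exactly", {
  withr::with_seed(5, {
    x <- matrix(rnorm(6 * 3), 6, 3)
  })
  x[4:6, ] <- x[4:6, ] + 1.5
  rownames(x) <- paste0("s", 1:6)
  groups <- rep(c("A", "B"), each = 3)
  md <- data.frame(sample_id = rownames(x), g = groups)

  # brute-force oracle: pseudo-F for each of the 20 distinct assignments,
  # computed purely from pairwise distances
  perms <- two_group_assignments(3)
  f_all <- apply(perms, 1, function(p) bruteforce_permanova_f(x, groups[order(p)]))
  f_obs <- bruteforce_permanova_f(x, groups)
  p_exhaustive <- mean(f_all >= f_obs - 1e-12)

  # engine fed the 19 non-identity assignments; add-one convention then
  # reproduces the exhaustive count (identity contributes the +1)
  nonid <- perms[-1, , drop = FALSE]
  res <- permanova(x, "g", metadata = md, permutations = nonid)
  expect_equal(res$table$f[1], f_obs, tolerance = 1e-10)
  expect_equal(res$table$p[1], p_exhaustive, tolerance = 1e-12)
})

test_that("1-D Euclidean PERMANOVA pseudo-F equals classical ANOVA F", {
  withr::with_seed(8, {
    y <- c(rnorm(5, 0), rnorm(6, 1), rnorm(4, 2))
  })
  g <- rep(c("a", "b", "c"), c(5, 6, 4))
  md <- data.frame(sample_id = seq_along(y), g = g)
  x <- matrix(y, ncol = 1, dimnames = list(md$sample_id, "y"))
  res <- permanova(x, "g", metadata = md, n_perm = 19, seed = 1)
  f_classic <- summary(stats::aov(y ~ g))[[1]]["g", "F value"]
  expect_equal(res$table$f[1], f_classic, tolerance = 1e-10)
})

test_that("sequential two-term partition matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  clr <- sim_clr_study()
  md <- clr$metadata
  res <- permanova(clr, c("phase", "strategy"), n_perm = 99, seed = 1)
  resi <- permanova(clr, c("phase", "strategy", "phase:strategy"),
                    n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::dist(clr$values) ~ phase + strategy,
                        data = md, permutations = 99, by = "terms")
  expect_equal(res$table$ss[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$table$f[1:2], ref$F[1:2], tolerance = 1e-8)
  refi <- vegan::adonis2(stats::dist(clr$values) ~ phase * strategy,
                         data = md, permutations = 99, by = "terms")
  expect_equal(resi$table$ss[1:3], refi$SumOfSqs[1:3], tolerance = 1e-8)
  # R2 additivity
  expect_equal(sum(res$table$r2[1:3]), 1, tolerance = 1e-10)
  expect_equal(sum(resi$table$r2[1:4]), 1, tolerance = 1e-10)
})

test_that("seeded permutations are reproducible and errors are raised", {
  clr <- sim_clr_study()
  a <- permanova(clr, "phase", n_perm = 49, seed = 7)
  b <- permanova(clr, "phase", n_perm = 49, seed = 7)
  expect_identical(a$table$p, b$table$p)
  md1 <- clr$metadata; md1$phase <- "exp"
  expect_error(permanova(clr, "phase", metadata = md1), "fewer than 2")
  expect_error(permanova(clr, "phase", n_perm = 0), "n_perm")
})

test_that("congruent translated groups show homogeneous dispersion", {
  base <- matrix(c(0, 0, 2, 0, 0, 1, 1, 3), 4, 2, byrow = TRUE)
  x <- rbind(base, base + 10)
  rownames(x) <- paste0("s", 1:8)
  g <- rep(c("A", "B"), each = 4)
  res <- dispersion_test(x, g, n_perm = 199, seed = 2)
  expect_true(all(res$distances >= 0))
  expect_equal(unname(res$group_means[1]), unname(res$group_means[2]))
  expect_gte(res$p, 0.1)
})

test_that("zero-dispersion group vs spread group is extreme in the exhaustive null", {
  x <- rbind(matrix(0, 3, 2),
             matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE))
  rownames(x) <- paste0("s", 1:6)
  g <- rep(c("A", "B"), each = 3)
  perms <- two_group_assignments(3)
  res <- dispersion_test(x, g, permutations = perms[-1, , drop = FALSE])
  # only the identity and the wholesale label swap reach the observed F
  expect_equal(res$p, 2 / 20)
  expect_equal(unname(res$group_means["A"]), 0)
})

test_that("dispersion distances match vegan::betadisper centroids", {
  skip_if_not_installed("vegan")
  clr <- sim_clr_study()
  res <- dispersion_test(clr, "phase", n_perm = 99, seed = 1)
  bd <- vegan::betadisper(stats::dist(clr$values),
                          clr$metadata$phase, type = "centroid")
  expect_equal(unname(res$distances), unname(bd$distances),
               tolerance = 1e-8)
  expect_error(dispersion_test(clr$values[1:3, ], c("a", "a", "b")),
               "fewer than 2")
})
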