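# Distance-based multivariate ANOVA (PERMANOVA) with sequential (Type-I)
# sums of squares, and a homogeneity-of-dispersion test. Both operate on
# Euclidean distances between clr rows. The SS partition follows the
# standard distance-matrix formulation: with A = -D^2/2 and G the
# double-centered (Gower) form of A, the SS explained by a model matrix X is
# tr(H G H) for the hat matrix H of X; sequential term SS are differences of
# nested-model traces. Permutation p-values use the add-one convention
# p = (#{F* >= F} + 1) / (n_perm + 1).

# run fn with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

.gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

.hat <- function(x) {
  qx <- qr(x)
  q1 <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(q1)
}

# sequential SS of the terms for one ordering of sample indices
.permanova_ss <- function(g, hats, df_terms, df_res, perm = NULL) {
  if (!is.null(perm)) g <- g[perm, perm, drop = FALSE]
  ss_total <- sum(diag(g))
  trs <- vapply(hats, function(h) sum(h * g), numeric(1))  # tr(HGH) = sum(H*G)
  ss_seq <- diff(c(0, trs))
  ss_res <- ss_total - trs[length(trs)]
  f <- (ss_seq / df_terms) / (ss_res / df_res)
  list(ss = ss_seq, ss_res = ss_res, ss_total = ss_total, f = f)
}

#' PERMANOVA on clr-transformed glycan abundances
#'
#' Permutational multivariate ANOVA on Euclidean distances with sequential
#' (Type-I) sums of squares. Terms are entered in the order given; an
#' interaction of two terms is written `"a:b"` and must come after its main
#' effects. Samples (rows/columns of the distance matrix) are permuted
#' freely; each term's pseudo-F is compared against its permutation
#' distribution.
#'
#' @param clr A `clr_matrix` or plain samples x variables matrix.
#' @param terms Character vector of metadata column names, e.g.
#'   `c("phase", "strategy")` or `c("phase", "strategy", "phase:strategy")`.
#' @param metadata Sample metadata `data.frame` (defaults to the
#'   `clr_matrix` metadata).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation engine.
#' @param permutations Optional matrix of permutations (rows = permuted index
#'   vectors) overriding random generation, e.g. an exhaustive enumeration.
#' @return Object of class `permanova_result`: `data.frame` `table` with one
#'   row per term plus residual and total (columns `term`, `df`, `ss`, `f`,
#'   `r2`, `p`), and fields `n_perm`, `seed`.
#' @export
permanova <- function(clr, terms, metadata = .clr_metadata(clr),
                      n_perm = 999, seed = 1L, permutations = NULL) {
  x <- .as_clr_values(clr)
  if (is.null(metadata)) stop("metadata required")
  if (is.null(permutations) && n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(x)

  # build nested model matrices intercept -> +term1 -> +term2 ...
  mm <- list()
  form <- "~ 1"
  for (tm in terms) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    for (v in vars) {
      if (!v %in% names(metadata)) stop("unknown metadata column: ", v)
      if (length(unique(metadata[[v]])) < 2) {
        stop("term '", v, "' has fewer than 2 levels")
      }
    }
    form <- paste(form, "+", tm)
    mm[[tm]] <- stats::model.matrix(stats::as.formula(form), data = metadata)
  }
  hats <- lapply(mm, .hat)
  ranks <- vapply(mm, function(m) qr(m)$rank, integer(1))
  df_terms <- diff(c(1L, ranks))
  if (any(df_terms < 1)) stop("term adds no degrees of freedom")
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("no residual degrees of freedom")

  g <- .gower_center(stats::dist(x))
  obs <- .permanova_ss(g, hats, df_terms, df_res)

  perms <- if (!is.null(permutations)) {
    stopifnot(ncol(permutations) == n)
    permutations
  } else {
    with_seed(seed, function() {
      t(replicate(n_perm, sample.int(n)))
    })
  }
  np <- nrow(perms)
  count <- numeric(length(terms))
  for (i in seq_len(np)) {
    fp <- .permanova_ss(g, hats, df_terms, df_res, perm = perms[i, ])$f
    count <- count + (fp >= obs$f - 1e-12)
  }
  p <- (count + 1) / (np + 1)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    ss = c(obs$ss, obs$ss_res, obs$ss_total),
    f = c(obs$f, NA, NA),
    r2 = c(obs$ss, obs$ss_res, obs$ss_total) / obs$ss_total,
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_perm = np, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (Euclidean, sequential SS, ", x$n_perm,
      " permutations)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Computes each sample's Euclidean distance to its group centroid in the
#' full coordinate space and tests homogeneity of the group mean dispersions
#' by permuting group labels of the distances, comparing the one-way ANOVA F
#' ratio on the distances (add-one p-value).
#'
#' @param clr A `clr_matrix` or plain matrix.
#' @param grouping Factor/character vector of group labels, or a metadata
#'   column name.
#' @param metadata Metadata used when `grouping` is a column name.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param permutations Optional explicit permutation matrix (rows = permuted
#'   index vectors applied to the distances' group labels).
#' @return Object of class `dispersion_result`: `distances` (per sample),
#'   `group_means`, observed `f`, permutation `p`, `n_perm`, `seed`.
#' @export
dispersion_test <- function(clr, grouping, metadata = .clr_metadata(clr),
                            n_perm = 999, seed = 1L, permutations = NULL) {
  x <- .as_clr_values(clr)
  if (is.character(grouping) && length(grouping) == 1L) {
    if (is.null(metadata) || !grouping %in% names(metadata)) {
      stop("grouping column not found in metadata: ", grouping)
    }
    grouping <- metadata[[grouping]]
  }
  grouping <- factor(grouping)
  if (length(grouping) != nrow(x)) stop("grouping length mismatch")
  sizes <- table(grouping)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  centroids <- apply(x, 2, function(col) tapply(col, grouping, mean))
  dist_to_centroid <- sqrt(rowSums((x - centroids[as.integer(grouping), ,
                                                  drop = FALSE])^2))
  f_stat <- function(d, grp) {
    m <- tapply(d, grp, mean); n_g <- tapply(d, grp, length)
    ss_b <- sum(n_g * (m - mean(d))^2)
    ss_w <- sum((d - m[as.integer(grp)])^2)
    dfb <- nlevels(grp) - 1; dfw <- length(d) - nlevels(grp)
    (ss_b / dfb) / (ss_w / dfw)
  }
  f_obs <- f_stat(dist_to_centroid, grouping)
  perms <- if (!is.null(permutations)) permutations else {
    with_seed(seed, function() {
      t(replicate(n_perm, sample.int(length(grouping))))
    })
  }
  np <- nrow(perms)
  count <- 0
  for (i in seq_len(np)) {
    count <- count +
      (f_stat(dist_to_centroid[perms[i, ]], grouping) >= f_obs - 1e-12)
  }
  structure(
    list(
      distances = stats::setNames(dist_to_centroid, rownames(x)),
      group_means = tapply(dist_to_centroid, grouping, mean),
      f = f_obs, p = (count + 1) / (np + 1), n_perm = np, seed = seed
    ),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion homogeneity (", x$n_perm,
      " permutations)\n", sep = "")
  cat("group mean distances to centroid:\n")
  print(round(x$group_means, 4))
  cat("F =", signif(x$f, 4), " p =", signif(x$p, 4), "\n")
  invisible(x)
}
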