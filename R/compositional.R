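# Compositional analysis of glycoform abundances. Fractional abundances live
# on the simplex (constant sum 100), so ordinary Euclidean statistics are
# applied only after the centered log-ratio (clr) transform
# clr(x)_k = ln(x_k / g(x)), g(x) the row geometric mean, which maps each
# sample to a zero-sum vector in an unconstrained space.

#' Centered log-ratio transform of a glycoform table
#'
#' @param table A [glycoform_table()] (all abundances strictly positive under
#'   the default policy).
#' @param zero_policy `"strict"` (zeros are an error naming the sample and
#'   glycoform) or `"replace"` (zeros replaced by `delta` percent, then the
#'   row renormalized, with a warning).
#' @param delta Replacement value in percent for `zero_policy = "replace"`.
#' @return Object of class `clr_matrix`: list with `values` (samples x
#'   glycoforms, rows sum to 0) and `metadata`.
#' @examples
#' m <- matrix(c(50, 25, 25), 1,
#'             dimnames = list("s1", c("G0F . G0F", "G1F . G1F", "G0 . G0")))
#' clr_transform(glycoform_table(m))$values
#' @export
clr_transform <- function(table, zero_policy = c("strict", "replace"),
                          delta = 0.01) {
  stopifnot(inherits(table, "glycoform_table"))
  zero_policy <- match.arg(zero_policy)
  x <- table$abundance
  if (any(x == 0)) {
    zero <- which(x == 0, arr.ind = TRUE)
    what <- paste0(rownames(x)[zero[, 1]], ":", colnames(x)[zero[, 2]])
    if (zero_policy == "strict") {
      stop("zero abundance(s) under strict policy: ",
           paste(utils::head(what, 5), collapse = ", "))
    }
    warning("replacing ", nrow(zero), " zero abundance(s) with delta = ",
            delta, " percent")
    x[x == 0] <- delta
    x <- x / rowSums(x) * 100
  }
  lx <- log(x)
  values <- lx - rowMeans(lx)
  structure(list(values = values, metadata = table$metadata),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat("clr_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " glycoforms (rows sum to 0)\n", sep = "")
  invisible(x)
}

.as_clr_values <- function(clr) {
  if (inherits(clr, "clr_matrix")) clr$values else as.matrix(clr)
}

.clr_metadata <- function(clr) {
  if (inherits(clr, "clr_matrix")) clr$metadata else NULL
}

#' Principal component analysis of clr values
#'
#' Covariance PCA of the (column-centered) clr matrix via singular value
#' decomposition. Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param clr A `clr_matrix` (or plain matrix), >= 2 samples.
#' @return List with `scores`, `loadings`, `explained` (variance fractions
#'   summing to 1), `sdev` and `metadata`.
#' @export
glyco_pca <- function(clr) {
  x <- .as_clr_values(clr)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  ev <- pc$sdev^2
  list(scores = scores, loadings = loadings,
       explained = ev / sum(ev), sdev = pc$sdev,
       metadata = .clr_metadata(clr))
}

#' Sample-by-sample Spearman correlation of glycan profiles
#'
#' Correlates each pair of samples across glycoforms (profiles as columns,
#' as is common for omics data). A constant profile has no rank variance;
#' its correlations are returned as `NA`.
#'
#' @param clr A `clr_matrix` (or plain samples x glycoforms matrix).
#' @return Symmetric samples x samples matrix with unit diagonal.
#' @export
spearman_sample_correlation <- function(clr) {
  x <- .as_clr_values(clr)
  if (ncol(x) < 2) stop("need at least 2 glycoforms per sample")
  suppressWarnings(
    rho <- stats::cor(t(x), method = "spearman",
                      use = "pairwise.complete.obs")
  )
  const <- apply(x, 1, function(r) stats::sd(r) == 0)
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  rho
}
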