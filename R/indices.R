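# Summary indices of antibody glycosylation state. Galactosylation: the
# abundance-weighted fraction of available galactosylation sites occupied
# across a sample's glycoform pool. Glycation: the occupancy of backbone
# hexose (glucose adduct) sites measured on deglycosylated antibody, out of a
# fixed maximum of 3 sites.

#' Galactosylation index per sample
#'
#' For each sample, computes
#' \deqn{100 \cdot \frac{\sum_j A_j g_j}{\sum_j A_j d_j}}
#' where \eqn{A_j} is the fractional abundance of glycoform \eqn{j},
#' \eqn{g_j} its number of galactose residues and \eqn{d_j} its number of
#' possible galactosylation sites (two per present glycan).
#'
#' @param table A [glycoform_table()].
#' @return Named numeric vector of percentages in `[0, 100]`, one per sample.
#' @examples
#' m <- matrix(c(50, 50), 1,
#'             dimnames = list("s1", c("G0F . G0F", "G1F . G1F")))
#' galactosylation_index(glycoform_table(m))  # 25
#' @export
galactosylation_index <- function(table) {
  stopifnot(inherits(table, "glycoform_table"))
  g <- vapply(table$species, `[[`, integer(1), "g_j")
  d <- vapply(table$species, `[[`, integer(1), "d_j")
  num <- as.vector(table$abundance %*% g)
  den <- as.vector(table$abundance %*% d)
  if (any(den <= 0)) {
    stop("galactosylation index undefined: no galactosylation sites in ",
         "sample(s) ",
         paste(rownames(table$abundance)[den <= 0], collapse = ", "))
  }
  stats::setNames(100 * num / den, rownames(table$abundance))
}

#' Construct a glycation hexose-count profile
#'
#' Distribution of backbone hexose adduct counts (0-3) measured on
#' deglycosylated antibody, in percent per sample.
#'
#' @param f Numeric matrix (samples x 4, columns hexose counts 0..3) or a
#'   length-4 vector for a single sample; percentages summing to 100 per row.
#' @param sample_ids Optional sample ids (default from rownames).
#' @param max_sites Maximum glycation sites per antibody (fixed default 3).
#' @return Object of class `glycation_profile` with fields `f` (matrix,
#'   rows sum to 100) and `max_sites`.
#' @export
glycation_profile <- function(f, sample_ids = NULL, max_sites = 3L) {
  if (is.vector(f)) f <- matrix(f, nrow = 1, dimnames = list("s1", NULL))
  stopifnot(is.matrix(f), ncol(f) == max_sites + 1L)
  if (any(f < 0)) stop("negative glycation fractions are not allowed")
  rs <- rowSums(f)
  if (any(rs == 0)) stop("all-zero glycation profile row(s)")
  if (any(abs(rs - 100) > 1e-9)) f <- f / rs * 100
  if (!is.null(sample_ids)) rownames(f) <- sample_ids
  if (is.null(rownames(f))) rownames(f) <- paste0("S", seq_len(nrow(f)))
  colnames(f) <- paste0("hexoses_", 0:max_sites)
  structure(list(f = f, max_sites = as.integer(max_sites)),
            class = "glycation_profile")
}

#' Glycation index per sample
#'
#' Computes \deqn{100 \cdot \frac{\sum_i g_i f_i}{\sum_i s_i f_i}} where
#' \eqn{g_i \in \{0,1,2,3\}} is the hexose count of class \eqn{i}, \eqn{f_i}
#' its fractional abundance (percent, summing to 100) and \eqn{s_i} the fixed
#' maximum of 3 glycation sites.
#'
#' @param profile A [glycation_profile()].
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @examples
#' glycation_index(glycation_profile(c(50, 50, 0, 0)))  # 16.667
#' @export
glycation_index <- function(profile) {
  stopifnot(inherits(profile, "glycation_profile"))
  g <- 0:profile$max_sites
  num <- as.vector(profile$f %*% g)
  den <- profile$max_sites * rowSums(profile$f)
  stats::setNames(100 * num / den, rownames(profile$f))
}

#' Read glycation profiles from CSV
#'
#' Expected columns: `sample_id`, `hexoses_0` .. `hexoses_3` (percent).
#' @param path CSV path.
#' @return A `glycation_profile`.
#' @export
read_glycation_profile <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", paste0("hexoses_", 0:3))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("glycation profile file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  f <- as.matrix(df[paste0("hexoses_", 0:3)])
  glycation_profile(f, sample_ids = df$sample_id)
}

#' Write glycation profiles to CSV
#' @param profile A `glycation_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_glycation_profile <- function(profile, path) {
  df <- data.frame(sample_id = rownames(profile$f), profile$f,
                   check.names = FALSE)
  write_result_csv(df, path)
}
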