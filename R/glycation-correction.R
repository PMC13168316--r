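# Hexosylation bias: on an intact antibody, a backbone glucose adduct
# (glycation) and a terminal galactose both add 162 Da, so the intact-level
# hexose ladder mixes the two. Under the model
#
#   observed hexose distribution = true galactosylation distribution
#                                   (*) glycation hexose distribution
#
# (independence of glycation and galactosylation), the true distribution is
# recovered per sample by deconvolving each backbone-class ladder with the
# glycation distribution measured on deglycosylated antibody, via
# non-negative least squares, then clipping at zero and renormalizing.

# build species grouping: for each species index, backbone class and apparent
# hexose offset (galactoses + adducts)
.ladder_index <- function(species) {
  data.frame(
    col = seq_along(species),
    class = vapply(species, .backbone_class, character(1)),
    g = vapply(species, `[[`, integer(1), "g_j"),
    hex = vapply(species, `[[`, integer(1), "hexose_adducts"),
    d = vapply(species, `[[`, integer(1), "d_j"),
    stringsAsFactors = FALSE
  )
}

# canonical adduct-free species label for a backbone class at galactose count g
.synth_label <- function(class_key, g) {
  toks <- strsplit(class_key, paste0(" ", GLYCAN_SEP, " "), fixed = TRUE)[[1]]
  out <- character(2)
  remaining <- g
  for (i in 2:1) {  # load galactoses onto the later-sorted arm first
    if (toks[i] == "none") {
      out[i] <- "none"
    } else {
      take <- min(remaining, 2L)
      remaining <- remaining - take
      out[i] <- paste0("G", take, if (endsWith(toks[i], "F")) "F" else "")
    }
  }
  if (remaining > 0L) stop("galactose count exceeds sites in class ", class_key)
  parse_glycoform(paste(out[1], GLYCAN_SEP, out[2]))$label
}

# convolution matrix: Q[h+1, g+1] = q[h-g+1] for 0 <= h-g <= max adducts
.conv_matrix <- function(q, n_true, n_obs) {
  Q <- matrix(0, n_obs, n_true)
  for (g in 0:(n_true - 1L)) {
    for (k in 0:(length(q) - 1L)) {
      h <- g + k
      if (h < n_obs) Q[h + 1L, g + 1L] <- q[k + 1L]
    }
  }
  Q
}

#' Forward-convolve a glycoform table with a glycation distribution
#'
#' Simulates the intact-level hexosylation bias: each sample's adduct-free
#' glycoform abundances are spread over backbone hexose adduct counts 0..3
#' according to that sample's glycation distribution, yielding the apparent
#' intact-level table (species labels gain `"+kHex"` suffixes). This is the
#' forward model that [correct_hexosylation_bias()] inverts.
#'
#' @param table A [glycoform_table()] with adduct-free species.
#' @param profile A [glycation_profile()] covering the same sample ids.
#' @return A `glycoform_table` with hexose-adduct species.
#' @export
apply_glycation_bias <- function(table, profile) {
  stopifnot(inherits(table, "glycoform_table"),
            inherits(profile, "glycation_profile"))
  .match_profile_samples(table, profile)
  if (any(vapply(table$species, `[[`, integer(1), "hexose_adducts") > 0)) {
    stop("input table must be adduct-free")
  }
  labels0 <- colnames(table$abundance)
  n_adduct <- profile$max_sites
  out_labels <- c(labels0, unlist(lapply(1:n_adduct, function(k)
    paste0(labels0, " + ", k, "Hex"))))
  out <- matrix(0, nrow(table$abundance), length(out_labels),
                dimnames = list(rownames(table$abundance), out_labels))
  q <- profile$f[rownames(table$abundance), , drop = FALSE] / 100
  for (k in 0:n_adduct) {
    block <- table$abundance * q[, k + 1L]
    cols <- if (k == 0) labels0 else paste0(labels0, " + ", k, "Hex")
    out[, cols] <- block
  }
  keep <- colSums(out) > 0 | colnames(out) %in% labels0
  glycoform_table(out[, keep, drop = FALSE], table$metadata,
                  normalize = FALSE)
}

.match_profile_samples <- function(table, profile) {
  tids <- rownames(table$abundance)
  pids <- rownames(profile$f)
  miss <- setdiff(tids, pids)
  if (length(miss)) {
    stop("glycation profile lacks sample(s): ", paste(miss, collapse = ", "))
  }
  invisible(NULL)
}

#' Correct the intact-level hexosylation bias
#'
#' Recovers true N-glycan galactosylation abundances from intact-level
#' hexose-resolved abundances, using an independently measured glycation
#' distribution (deglycosylated antibody). Within each backbone class
#' (presence/fucosylation pattern), the observed total-hexose ladder is
#' deconvolved by the sample's glycation distribution via non-negative least
#' squares; corrected masses are redistributed over the class's adduct-free
#' species (proportionally to their observed abundances at each galactose
#' count), clipped at zero, and the sample renormalized to 100. With a
#' zero-glycation profile the table is returned unchanged.
#'
#' This is a simplified linear-deconvolution correction; it assumes glycation
#' acts independently of the glycan composition.
#'
#' @param intact_table A [glycoform_table()] of intact-level abundances;
#'   species labels may carry `"+kHex"` adduct suffixes.
#' @param profile A [glycation_profile()] covering the same sample ids.
#' @return An adduct-free `glycoform_table` of corrected abundances.
#' @export
correct_hexosylation_bias <- function(intact_table, profile) {
  stopifnot(inherits(intact_table, "glycoform_table"),
            inherits(profile, "glycation_profile"))
  .match_profile_samples(intact_table, profile)

  idx <- .ladder_index(intact_table$species)
  idx$h <- idx$g + idx$hex
  classes <- split(idx, idx$class)

  # output species: adduct-free galactose ladder of every class (canonical
  # labels plus any adduct-free species already present in the input)
  out_cols <- list()
  for (cls in names(classes)) {
    ci <- classes[[cls]]
    d_cls <- ci$d[1]
    for (g in 0:d_cls) out_cols[[paste(cls, g)]] <- .synth_label(cls, g)
  }
  input_free <- colnames(intact_table$abundance)[idx$hex == 0L]
  out_labels <- unique(c(unlist(out_cols), input_free))
  A <- intact_table$abundance
  out <- matrix(0, nrow(A), length(out_labels),
                dimnames = list(rownames(A), out_labels))

  for (s in rownames(A)) {
    q <- profile$f[s, ] / 100
    for (cls in names(classes)) {
      ci <- classes[[cls]]
      d_cls <- ci$d[1]
      n_true <- d_cls + 1L
      n_obs <- max(max(ci$h) + 1L, n_true)
      obs <- numeric(n_obs)
      for (r in seq_len(nrow(ci))) {
        obs[ci$h[r] + 1L] <- obs[ci$h[r] + 1L] + A[s, ci$col[r]]
      }
      if (all(q[-1] == 0)) {
        truth <- obs[seq_len(n_true)]
      } else {
        Q <- .conv_matrix(q, n_true, n_obs)
        truth <- pracma::lsqnonneg(Q, obs)$x
      }
      truth[truth < 0] <- 0
      # redistribute each galactose-count mass over that count's adduct-free
      # species, weighted by their observed abundances
      for (g in 0:d_cls) {
        carriers <- ci$col[ci$g == g & ci$hex == 0L]
        if (length(carriers) == 0L) {
          out[s, .synth_label(cls, g)] <-
            out[s, .synth_label(cls, g)] + truth[g + 1L]
        } else {
          w <- A[s, carriers]
          w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
          labs <- colnames(A)[carriers]
          out[s, labs] <- out[s, labs] + truth[g + 1L] * w
        }
      }
    }
  }
  keep <- colSums(out) > 0
  if (!any(keep)) stop("correction removed all abundance mass")
  glycoform_table(out[, keep, drop = FALSE], intact_table$metadata,
                  normalize = TRUE)
}
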