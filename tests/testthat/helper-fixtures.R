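# Shared fixture builders; all data is generated in code.

# small glycoform table with known structure
make_table <- function(abund, labels = NULL, metadata = NULL) {
  if (is.null(labels)) labels <- colnames(abund)
  m <- as.matrix(abund)
  colnames(m) <- labels
  glycoform_table(m, metadata)
}

# random positive composition table (percent rows), seeded
random_table <- function(n_samples, labels, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(n_samples * length(labels), shape = 2),
                n_samples, length(labels))
  })
  colnames(m) <- labels
  rownames(m) <- paste0("s", seq_len(n_samples))
  glycoform_table(m)
}

default_labels <- c("G0 . G0", "G0F . G0F", "G0F . G1F", "G1F . G1F",
                    "G1F . G2F", "G2F . G2F")

# two-group metadata for multivariate tests
two_group_meta <- function(ids, groups) {
  data.frame(sample_id = ids, strategy = groups,
             phase = "exp", replicate = ids, stringsAsFactors = FALSE)
}

# brute-force PERMANOVA pseudo-F for a one-factor design, computed from
# pairwise distances only (independent of the hat-matrix engine)
bruteforce_permanova_f <- function(x, groups) {
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dg <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# all distinct assignments of 2n samples into two labelled groups of n,
# expressed as index permutations usable by permanova(permutations=)
two_group_assignments <- function(n_per_group) {
  n <- 2 * n_per_group
  combos <- utils::combn(n, n_per_group)
  t(apply(combos, 2, function(g1) c(g1, setdiff(seq_len(n), g1))))
}
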