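# Report assembly: fixed-precision CSV writers, a run manifest, and a
# one-call collation of rate summaries, indices, multivariate tables and
# contrast tables into an output directory.

#' Write a data frame as CSV with fixed numeric precision
#'
#' Numeric columns are formatted to 6 significant digits so repeated runs
#' produce byte-identical, diffable files.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(signif(out[[j]], 6), format = "g",
                                 digits = 6))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, seed, package version, input/output paths and a
#' timestamp as JSON in the output directory.
#'
#' @param out_dir Output directory.
#' @param command Command or function name that produced the outputs.
#' @param seed Seed used.
#' @param inputs,outputs Character vectors of paths.
#' @return Manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, seed = NA,
                               inputs = character(0),
                               outputs = character(0)) {
  manifest <- list(
    command = command, seed = seed,
    inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "glycofeed",
    version = as.character(utils::packageVersion("glycofeed"))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assemble the full analysis report for a study
#'
#' Runs the pipeline stages on a (simulated or loaded) study and writes
#' tidy CSV tables: per-replicate rate series, per-sample indices, PERMANOVA
#' and dispersion tables, PCA scores/loadings, the sample correlation
#' matrix, and the standard contrast table, plus a manifest.
#'
#' @param study A `glyco_study` (see [generate_study()]) or a list with
#'   elements `courses`, `glycoforms`, `glycation`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the permutation tests.
#' @param n_perm Permutations for PERMANOVA/dispersion.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_report <- function(study, out_dir, seed = 1L, n_perm = 999) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_result_csv(df, p)
    paths[[name]] <<- p
  }

  rates <- do.call(rbind, lapply(study$courses, compute_rates))
  rownames(rates) <- NULL
  put(rates, "rates.csv")

  gal <- galactosylation_index(study$glycoforms)
  gly <- glycation_index(study$glycation)
  idx <- merge(
    data.frame(sample_id = names(gal), galactosylation_index = unname(gal)),
    data.frame(sample_id = names(gly), glycation_index = unname(gly)),
    by = "sample_id", all = TRUE
  )
  idx <- merge(study$glycoforms$metadata, idx, by = "sample_id", all.y = TRUE)
  put(idx, "indices.csv")

  clr <- clr_transform(study$glycoforms)
  pv <- permanova(clr, c("phase", "strategy"), n_perm = n_perm, seed = seed)
  pvi <- permanova(clr, c("phase", "strategy", "phase:strategy"),
                   n_perm = n_perm, seed = seed)
  put(rbind(cbind(model = "phase+strategy", pv$table),
            cbind(model = "phase*strategy", pvi$table)),
      "permanova.csv")

  disp <- dispersion_test(clr, "phase", n_perm = n_perm, seed = seed)
  disp_s <- dispersion_test(clr, "strategy", n_perm = n_perm, seed = seed)
  put(data.frame(
    grouping = c("phase", "strategy"),
    f = c(disp$f, disp_s$f), p = c(disp$p, disp_s$p)
  ), "dispersion.csv")

  pca <- glyco_pca(clr)
  put(data.frame(sample_id = rownames(pca$scores), pca$scores,
                 check.names = FALSE), "pca_scores.csv")
  put(data.frame(glycoform = rownames(pca$loadings), pca$loadings,
                 check.names = FALSE), "pca_loadings.csv")
  rho <- spearman_sample_correlation(clr)
  put(data.frame(sample_id = rownames(rho), rho, check.names = FALSE),
      "sample_correlation.csv")

  fit <- fit_cell_means(clr)
  put(standard_contrasts(fit), "contrasts.csv")

  write_run_manifest(out_dir, command = "write_report", seed = seed,
                     outputs = names(paths))
  invisible(unlist(paths))
}
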