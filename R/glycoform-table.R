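# Fractional-abundance tables: samples x glycoform species, in percent, each
# sample summing to 100. Carried as a long data.frame plus per-sample metadata
# (feeding strategy, culture phase, biological replicate).

STRATEGY_LEVELS <- c("STD", "STD+", "LoG", "LoG+", "HiF", "HIP", "HIP+")
PHASE_LEVELS <- c("exp", "sta")

#' Construct a glycoform fractional-abundance table
#'
#' @param abundance Numeric matrix, samples in rows (rownames = sample ids),
#'   glycoform labels in columns. Values are nonnegative; each row is
#'   normalized to sum to 100.
#' @param metadata `data.frame` with columns `sample_id`, `strategy`, `phase`,
#'   `replicate`, one row per sample (matched by `sample_id`). Optional; if
#'   omitted a skeleton with `NA` metadata is created.
#' @param normalize Logical; rescale each row to sum to 100 (default `TRUE`).
#'   When `FALSE`, rows deviating from 100 by more than 0.5 percentage points
#'   are an error; smaller deviations are renormalized with a warning.
#' @return An object of class `glycoform_table`: list with `abundance`
#'   (matrix, rows sum to 100), `species` (list of parsed
#'   [parse_glycoform()] objects, one per column) and `metadata`.
#' @export
glycoform_table <- function(abundance, metadata = NULL, normalize = TRUE) {
  stopifnot(is.matrix(abundance), !is.null(colnames(abundance)))
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- paste0("S", seq_len(nrow(abundance)))
  }
  if (any(abundance < 0)) stop("negative abundances are not allowed")
  if (anyNA(abundance)) stop("missing abundances are not allowed")

  species <- lapply(colnames(abundance), parse_glycoform)
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    stop("duplicate glycoform species after canonicalization: ",
         paste(dup, collapse = ", "))
  }
  colnames(abundance) <- labels

  rs <- rowSums(abundance)
  if (any(rs == 0)) {
    stop("all-zero abundance row(s): ",
         paste(rownames(abundance)[rs == 0], collapse = ", "))
  }
  if (normalize) {
    abundance <- abundance / rs * 100
  } else {
    off <- abs(rs - 100)
    if (any(off > 0.5)) {
      stop("abundance rows deviate from 100% by more than 0.5 points: ",
           paste(rownames(abundance)[off > 0.5], collapse = ", "))
    }
    if (any(off > 1e-9)) {
      warning("renormalizing rows deviating from 100% by up to 0.5 points")
      abundance <- abundance / rs * 100
    }
  }

  md <- .check_metadata(metadata, rownames(abundance))
  structure(
    list(abundance = abundance, species = species, metadata = md),
    class = "glycoform_table"
  )
}

.check_metadata <- function(metadata, sample_ids) {
  if (is.null(metadata)) {
    metadata <- data.frame(
      sample_id = sample_ids, strategy = NA_character_,
      phase = NA_character_, replicate = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  need <- c("sample_id", "strategy", "phase", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(metadata$sample_id, sample_ids) ||
      anyDuplicated(metadata$sample_id)) {
    stop("metadata sample_id must match table samples exactly")
  }
  metadata <- metadata[match(sample_ids, metadata$sample_id), need, drop = FALSE]
  bad <- !is.na(metadata$strategy) & !metadata$strategy %in% STRATEGY_LEVELS
  if (any(bad)) {
    stop("unknown strategy value(s): ",
         paste(unique(metadata$strategy[bad]), collapse = ", "))
  }
  badp <- !is.na(metadata$phase) & !metadata$phase %in% PHASE_LEVELS
  if (any(badp)) {
    stop("unknown phase value(s): ",
         paste(unique(metadata$phase[badp]), collapse = ", "))
  }
  rownames(metadata) <- NULL
  metadata
}

#' Normalize raw abundances to fractional abundances summing to 100
#'
#' @param raw Numeric matrix of nonnegative raw abundances (samples x species,
#'   column names are glycoform labels), or a `glycoform_table`.
#' @param metadata Optional sample metadata (see [glycoform_table()]).
#' @return A `glycoform_table` whose rows sum to 100; relative ratios within
#'   each sample are preserved.
#' @examples
#' m <- matrix(c(3, 1), 1, dimnames = list("s1", c("G0F . G0F", "G1F . G1F")))
#' normalize_abundances(m)$abundance  # 75 / 25
#' @export
normalize_abundances <- function(raw, metadata = NULL) {
  if (inherits(raw, "glycoform_table")) {
    return(glycoform_table(raw$abundance, raw$metadata, normalize = TRUE))
  }
  glycoform_table(raw, metadata, normalize = TRUE)
}

#' @export
print.glycoform_table <- function(x, ...) {
  cat("glycoform_table: ", nrow(x$abundance), " samples x ",
      ncol(x$abundance), " glycoforms\n", sep = "")
  strat <- unique(stats::na.omit(x$metadata$strategy))
  if (length(strat)) cat("strategies:", paste(strat, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.glycoform_table <- function(x, ...) {
  long <- data.frame(
    sample_id = rep(rownames(x$abundance), times = ncol(x$abundance)),
    glycoform = rep(colnames(x$abundance), each = nrow(x$abundance)),
    abundance_percent = as.vector(x$abundance),
    stringsAsFactors = FALSE
  )
  merge(x$metadata, long, by = "sample_id", sort = FALSE)
}

#' Read a glycoform table from delimited text
#'
#' Accepts the long format (columns `sample_id`, `strategy`, `phase`,
#' `replicate`, `glycoform`, `abundance_percent`) or a wide format (one
#' `sample_id` column, optional metadata columns, remaining columns one per
#' glycoform label).
#'
#' @param path File path (CSV; TSV detected from the `.tsv` extension).
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @return A `glycoform_table`.
#' @export
read_glycoform_table <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (all(c("glycoform", "abundance_percent") %in% names(df)))
      "long" else "wide"
  }
  if (format == "long") {
    need <- c("sample_id", "glycoform", "abundance_percent")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("long glycoform file '", path, "' lacks column(s): ",
           paste(miss, collapse = ", "))
    }
    df$glycoform <- canonical_glycoform(df$glycoform)
    wide <- stats::xtabs(abundance_percent ~ sample_id + glycoform, data = df)
    m <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
                dimnames = unname(dimnames(wide)))
    mdcols <- intersect(c("sample_id", "strategy", "phase", "replicate"),
                        names(df))
    md <- unique(df[mdcols])
    if (!all(c("strategy", "phase", "replicate") %in% names(md))) md <- NULL
    glycoform_table(m, md)
  } else {
    if (!"sample_id" %in% names(df)) {
      stop("wide glycoform file '", path, "' lacks a sample_id column")
    }
    mdcols <- intersect(c("strategy", "phase", "replicate"), names(df))
    gcols <- setdiff(names(df), c("sample_id", mdcols))
    m <- as.matrix(df[gcols])
    rownames(m) <- df$sample_id
    md <- if (length(mdcols) == 3) df[c("sample_id", mdcols)] else NULL
    glycoform_table(m, md)
  }
}

#' Write a glycoform table as long-format CSV
#' @param x A `glycoform_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_glycoform_table <- function(x, path) {
  stopifnot(inherits(x, "glycoform_table"))
  write_result_csv(as.data.frame(x), path)
}
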