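# Paired Fc N-glycan nomenclature: an intact IgG carries one N-glycan per heavy
# chain, written "X <dot> Y" (e.g. "G1F <dot> G0F"). Tokens G0/G1/G2 carry 0/1/2
# terminal galactoses, a trailing F marks core fucosylation, and "none" marks an
# unoccupied site. Glycated variants (extracellular hexose adducts on the
# protein backbone, +162 Da each, indistinguishable from galactose by intact
# mass) are written with a "+kHex" suffix.

GLYCAN_SEP <- "\u22c5"  # the dot operator; "." accepted on input as fallback

.arm_vocab <- c("none", "G0", "G1", "G2", "G0F", "G1F", "G2F")

#' Parse a single glycan arm token
#'
#' @param token Character scalar, one of `none`, `G0`, `G1`, `G2`, `G0F`,
#'   `G1F`, `G2F`.
#' @return A list with fields `token`, `present`, `gal_count`, `fucosylated`
#'   and `gal_sites` (2 for a present glycan, 0 for an absent one).
#' @keywords internal
parse_glycan_arm <- function(token) {
  token <- trimws(token)
  if (!token %in% .arm_vocab) {
    stop("unknown glycan arm token: '", token, "'", call. = FALSE)
  }
  present <- token != "none"
  list(
    token       = token,
    present     = present,
    gal_count   = if (present) as.integer(substr(token, 2L, 2L)) else 0L,
    fucosylated = present && endsWith(token, "F"),
    gal_sites   = if (present) 2L else 0L
  )
}

.arm_sort_key <- function(arm) {
  # canonical order: present arms first, then ascending galactose, then
  # afucosylated before fucosylated, then token text
  sprintf(
    "%d|%d|%d|%s",
    if (arm$present) 0L else 1L, arm$gal_count,
    if (arm$fucosylated) 1L else 0L, arm$token
  )
}

#' Parse a glycoform-pair label
#'
#' Splits a label such as `"G1F ⋅ G0F"` into its two glycan arms, stores
#' them in a deterministic canonical order, and derives the quantities used by
#' the galactosylation index: `g_j`, the total number of galactose residues,
#' and `d_j`, the total number of possible galactosylation sites (two per
#' present glycan, zero for an absent arm). An optional `"+kHex"` suffix
#' (k in 0..3) records backbone hexose (glycation) adducts on the intact mass.
#'
#' The ASCII `"."` separator is accepted as an input alias; rendered labels
#' always use `"⋅"` with single surrounding spaces, so
#' `render_glycoform(parse_glycoform(x))` is a fixed point.
#'
#' @param label Character scalar with exactly two arm tokens separated by
#'   `"⋅"` or `"."`.
#' @return An object of class `glycoform_species`: a list with `arm_a`,
#'   `arm_b` (canonical order), `label`, `g_j`, `d_j`, `hexose_adducts`.
#' @examples
#' sp <- parse_glycoform("G1F . G0F")
#' sp$g_j  # 1 galactose
#' sp$d_j  # 4 sites
#' @export
parse_glycoform <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  work <- trimws(label)

  hex <- 0L
  m <- regmatches(work, regexec("\\+\\s*([0-9]+)\\s*Hex\\s*$", work))[[1]]
  if (length(m)) {
    hex <- as.integer(m[2])
    if (hex < 0L || hex > 3L) {
      stop("hexose adduct count out of range 0-3 in label: '", label, "'",
           call. = FALSE)
    }
    work <- trimws(sub("\\+\\s*[0-9]+\\s*Hex\\s*$", "", work))
  }

  parts <- strsplit(work, paste0("\\s*(", GLYCAN_SEP, "|\\.)\\s*"),
                    perl = FALSE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2L) {
    stop("glycoform label must contain exactly two arm tokens: '", label, "'",
         call. = FALSE)
  }
  arms <- lapply(parts, parse_glycan_arm)
  arms <- arms[order(vapply(arms, .arm_sort_key, character(1)))]

  sp <- list(
    arm_a = arms[[1L]],
    arm_b = arms[[2L]],
    g_j = arms[[1L]]$gal_count + arms[[2L]]$gal_count,
    d_j = arms[[1L]]$gal_sites + arms[[2L]]$gal_sites,
    hexose_adducts = hex
  )
  sp$label <- .render_species(sp)
  class(sp) <- "glycoform_species"
  sp
}

.render_species <- function(sp) {
  base <- paste(sp$arm_a$token, GLYCAN_SEP, sp$arm_b$token)
  if (sp$hexose_adducts > 0L) {
    base <- paste0(base, " + ", sp$hexose_adducts, "Hex")
  }
  base
}

#' Render a glycoform species to its canonical label
#' @param species A `glycoform_species` object.
#' @return Character scalar label using the "⋅" separator.
#' @export
render_glycoform <- function(species) {
  stopifnot(inherits(species, "glycoform_species"))
  .render_species(species)
}

#' @export
print.glycoform_species <- function(x, ...) {
  cat(x$label, " (g_j = ", x$g_j, ", d_j = ", x$d_j, ")\n", sep = "")
  invisible(x)
}

#' Canonicalize a vector of glycoform labels
#' @param labels Character vector of glycoform-pair labels.
#' @return Character vector of canonical labels.
#' @export
canonical_glycoform <- function(labels) {
  vapply(labels, function(l) parse_glycoform(l)$label, character(1),
         USE.NAMES = FALSE)
}

# total apparent hexose offset of a species relative to its fully
# non-galactosylated backbone: galactoses plus glycation adducts
.apparent_hexoses <- function(sp) sp$g_j + sp$hexose_adducts

# backbone class key: presence/fucosylation pattern with galactose digits and
# adducts stripped; species in one class differ only by hexose count
.backbone_class <- function(sp) {
  tok <- function(arm) {
    if (!arm$present) "none" else if (arm$fucosylated) "GxF" else "Gx"
  }
  paste(tok(sp$arm_a), GLYCAN_SEP, tok(sp$arm_b))
}
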