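#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices (positive = hydrophobic). Named numeric
#' vector over the 20 standard one-letter codes.
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' Summed hydropathy of a sequence segment
#'
#' Returns the *sum* (not the length-normalised GRAVY mean) of per-residue
#' hydropathy values. The sum is the convention used when comparing loop
#' segments of different length, e.g. a 7-residue ancestral loop L5
#' (`"LNSMVNS"`, score 1.3) against its 9-residue descendant counterpart
#' (`"MNSTLKGDN"`, score -10.6): the longer, more hydrophilic loop scores far
#' lower even per the raw sum.
#'
#' @param segment Character string (or vector of single residues) of standard
#'   one-letter codes; gaps are not allowed. The empty string scores 0.
#' @param scale Named numeric hydropathy scale covering all residues present;
#'   defaults to [kyte_doolittle].
#' @return Single numeric score (dimensionless).
#' @export
#' @examples
#' hydropathy_sum("LNSMVNS")    # 1.3
#' hydropathy_sum("MNSTLKGDN")  # -10.6
hydropathy_sum <- function(segment, scale = kyte_doolittle) {
  if (length(segment) == 1L) segment <- strsplit(segment, "")[[1]]
  if (!length(segment)) return(0)
  segment <- toupper(segment)
  unknown <- setdiff(unique(segment), names(scale))
  if (length(unknown))
    stop("residue code(s) missing from the hydropathy scale: ",
         paste(unknown, collapse = ", "))
  sum(scale[segment])
}

#' Read a hydropathy scale from CSV
#'
#' Two columns: `residue` (one-letter code) and `value`. All 20 standard
#' residues must be present.
#'
#' @param path CSV file.
#' @return Named numeric vector usable as the `scale` of [hydropathy_sum()].
#' @export
read_hydropathy_scale <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  scale <- stats::setNames(as.numeric(tab$value), toupper(tab$residue))
  missing <- setdiff(names(kyte_doolittle), names(scale))
  if (length(missing))
    stop("hydropathy scale missing residue(s): ", paste(missing, collapse = ", "))
  scale
}
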