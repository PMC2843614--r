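#' Aligned sequence in a shared reference numbering
#'
#' An `aligned_sequence` stores a protein sequence as one-letter residues
#' together with the reference position (column) each residue occupies.
#' Sequences that have been aligned to a common reference (here, descendant
#' numbering) share columns, so grafting and residue-level diffs are simple
#' column operations. Gap columns carry `"-"`.
#'
#' @param id Non-empty character label.
#' @param residues Character vector of one-letter amino-acid codes, `"-"`
#'   allowed for gap columns.
#' @param ref_positions Integer vector of 1-based reference positions, one per
#'   element of `residues`. Defaults to `seq_along(residues)` (the usual case
#'   for sequences taken from a fixed-column alignment).
#' @return An object of class `aligned_sequence`.
#' @export
aligned_sequence <- function(id, residues, ref_positions = seq_along(residues)) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), c(AA_ALPHABET, "-"))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  ref_positions <- as.integer(ref_positions)
  if (length(ref_positions) != length(residues))
    stop("'ref_positions' must have one entry per residue")
  nong <- ref_positions[residues != "-"]
  if (is.unsorted(nong, strictly = TRUE))
    stop("'ref_positions' must be strictly increasing over non-gap residues")
  structure(list(id = id, residues = residues, ref_positions = ref_positions),
            class = "aligned_sequence")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @export
print.aligned_sequence <- function(x, ...) {
  n <- sum(x$residues != "-")
  cat(sprintf("<aligned_sequence> %s: %d residues over reference positions %d-%d\n",
              x$id, n, min(x$ref_positions), max(x$ref_positions)))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
as.character.aligned_sequence <- function(x, ...) {
  paste(x$residues[x$residues != "-"], collapse = "")
}

#' Extract the residues covering a reference interval
#'
#' @param x An [aligned_sequence()].
#' @param start,end Inclusive reference positions.
#' @param keep_gaps Keep gap columns in the result (default drops them).
#' @return Character string of residues whose reference position lies in
#'   `[start, end]`.
#' @export
segment <- function(x, start, end, keep_gaps = FALSE) {
  stopifnot(inherits(x, "aligned_sequence"), start <= end)
  keep <- x$ref_positions >= start & x$ref_positions <= end
  res <- x$residues[keep]
  if (!keep_gaps) res <- res[res != "-"]
  paste(res, collapse = "")
}

#' Read an aligned FASTA file into a list of aligned sequences
#'
#' All records must have equal width (a fixed-column alignment); column index
#' is taken as the reference position.
#'
#' @param path FASTA file, gaps as `-`.
#' @return Named list of [aligned_sequence()] objects. Names are the first
#'   whitespace-delimited token of each header.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L)
    stop("alignment columns differ in width; input must be a fixed-column alignment")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out <- lapply(seq_along(set), function(i)
    aligned_sequence(ids[i], as.character(set[[i]])))
  names(out) <- ids
  out
}

#' Write aligned sequences to FASTA
#'
#' @param seqs List of [aligned_sequence()].
#' @param path Output file.
#' @param keep_gaps Write gap columns (default `TRUE`, preserving the
#'   alignment); set `FALSE` for plain ungapped sequences.
#' @export
write_aligned_fasta <- function(seqs, path, keep_gaps = TRUE) {
  if (inherits(seqs, "aligned_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    res <- s$residues
    if (!keep_gaps) res <- res[res != "-"]
    c(paste0(">", s$id), paste(res, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference-numbered region map
#'
#' The region map names sequence regions (terminal segments `NT`/`CT`, loops
#' `L2`..`L6`) as inclusive `[start, end]` intervals in the shared reference
#' numbering. It is deliberately a config file: published boundary coordinates
#' are typically read off a structure figure, so they must stay editable.
#'
#' @param path JSON file with a top-level `regions` object mapping
#'   `name -> [start, end]`.
#' @return Named list of length-2 integer vectors.
#' @export
read_region_map <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  regions <- lapply(cfg$regions, function(iv) as.integer(iv))
  validate_region_map(regions)
  regions
}

validate_region_map <- function(regions) {
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("region names must be unique and non-empty")
  for (nm in names(regions)) {
    iv <- regions[[nm]]
    if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2])
      stop("region '", nm, "' must be an interval [start, end] with start <= end")
  }
  invisible(regions)
}

#' Bundled example data paths
#'
#' Convenience accessor for the plain-text fixtures shipped with the package
#' (synthetic stand-in alignment, dissociation-constant table, region map,
#' glycan motif annotations).
#'
#' @param file File name under the package `extdata/` directory; `NULL` lists
#'   the available files.
#' @return Full path (or a character vector of file names).
#' @export
galtrace_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "galtrace")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no such example file: ", file)
  path
}
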