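#' Graft reference-numbered regions from a donor onto a base sequence
#'
#' Builds a chimeric sequence: inside every listed region the product carries
#' the donor's residues (including donor insertions or deletions relative to
#' the base, honoured through alignment gaps); everywhere else it carries the
#' base's. Because regions are addressed in the shared reference numbering,
#' a graft may change the product's length (a 7-residue loop can be replaced
#' by a 9-residue one) while all positions keep their reference numbers.
#'
#' @param base,donor [aligned_sequence()] objects sharing reference numbering.
#' @param regions Character vector of region names to graft (may be empty, in
#'   which case the base is returned unchanged apart from its name).
#' @param region_map Named list of inclusive `[start, end]` intervals, e.g.
#'   from [read_region_map()].
#' @param id Label for the product; default is derived with [mutant_name()].
#' @return An [aligned_sequence()] chimera.
#' @export
graft_regions <- function(base, donor, regions, region_map,
                          id = mutant_name(base$id, regions)) {
  stopifnot(inherits(base, "aligned_sequence"), inherits(donor, "aligned_sequence"))
  validate_region_map(region_map)
  unknown <- setdiff(regions, names(region_map))
  if (length(unknown))
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  cols <- align_columns(base, donor)
  in_region <- rep(FALSE, length(cols$positions))
  for (nm in regions) {
    iv <- region_map[[nm]]
    hit <- cols$positions >= iv[1] & cols$positions <= iv[2]
    if (!any(cols$base[hit] != "-") && !any(cols$donor[hit] != "-"))
      stop("region '", nm, "' lies outside the coverage of both sequences")
    in_region <- in_region | hit
  }
  res <- ifelse(in_region, cols$donor, cols$base)
  aligned_sequence(id, res, cols$positions)
}

# Reconcile two aligned sequences onto one column vector keyed by reference
# position. Both inputs normally come from the same fixed-column alignment;
# positions present in only one sequence are padded with gaps in the other.
align_columns <- function(a, b) {
  positions <- sort(unique(c(a$ref_positions, b$ref_positions)))
  pick <- function(s) {
    out <- rep("-", length(positions))
    out[match(s$ref_positions, positions)] <- s$residues
    out
  }
  list(positions = positions, base = pick(a), donor = pick(b))
}

#' Derive the conventional chimera name from the grafted regions
#'
#' Region labels are joined with `/` in the fixed order N/C, L5, L6, L3
#' (the order the mutants were built in); grafting both terminal segments
#' `NT` and `CT` is written `N/C`.
#'
#' @param base_id Name of the base sequence.
#' @param regions Character vector of grafted region names.
#' @return A single string, e.g. `"Con-anc-N/C/L5/L6"`.
#' @export
mutant_name <- function(base_id, regions) {
  if (!length(regions)) return(base_id)
  labels <- character(0)
  if (all(c("NT", "CT") %in% regions)) {
    labels <- "N/C"
  } else if (any(c("NT", "CT") %in% regions)) {
    labels <- intersect(c("NT", "CT"), regions)
  }
  rest <- setdiff(regions, c("NT", "CT"))
  order <- c("L5", "L6", "L3")
  labels <- c(labels, intersect(order, rest), sort(setdiff(rest, order)))
  paste0(base_id, "-", paste(labels, collapse = "/"))
}

#' Residue-level differences between two aligned sequences
#'
#' Reports one record per reference position at which the two sequences
#' disagree: substitutions where both carry a residue, and insertion/deletion
#' records where exactly one of them has a gap. Substitution labels follow
#' the `E5Q` convention (residue of `a`, reference position, residue of `b`).
#'
#' @param a,b [aligned_sequence()] objects sharing reference numbering.
#' @return A data.frame with columns `position`, `from`, `to`, `type`
#'   (`"substitution"`, `"insertion"` = present only in `b`, `"deletion"` =
#'   present only in `a`) and `label`, sorted by position. Zero rows when the
#'   sequences are identical.
#' @export
diff_substitutions <- function(a, b) {
  stopifnot(inherits(a, "aligned_sequence"), inherits(b, "aligned_sequence"))
  cols <- align_columns(a, b)
  keep <- cols$base != cols$donor
  pos <- cols$positions[keep]
  from <- cols$base[keep]
  to <- cols$donor[keep]
  type <- ifelse(from == "-", "insertion",
                 ifelse(to == "-", "deletion", "substitution"))
  data.frame(position = pos, from = from, to = to, type = type,
             label = paste0(from, pos, to),
             stringsAsFactors = FALSE)
}

#' Write / read a substitution list as TSV
#'
#' @param diff Data.frame from [diff_substitutions()].
#' @param path Output file.
#' @export
write_substitutions <- function(diff, path) {
  utils::write.table(diff[, c("position", "from", "to", "type", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_substitutions
#' @export
read_substitutions <- function(path) {
  utils::read.delim(path, colClasses = c(position = "integer"))
}
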