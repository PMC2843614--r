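#' Dissociation-constant table (lectin x glycan)
#'
#' Container for frontal-affinity-chromatography (FAC) dissociation constants.
#' Rows are glycan ids, columns are lectins, values are K_d in micromolar.
#' "No detectable binding" (printed `-` in source tables) is a distinct state,
#' stored as `NA` -- never 0 or infinity -- and is skipped (with coverage
#' reported) by every summary. Printed strings, when a table is read from a
#' publication-style CSV, are retained so that rounding-consistency checks can
#' honour the precision each cell was printed at.
#'
#' @param kd Numeric matrix (glycans x lectins), `NA` = no detectable binding,
#'   all finite values > 0. Dimnames required.
#' @param printed Optional character matrix of the K_d cells as printed.
#' @param printed_ratios Optional named list (by reference lectin) of printed
#'   ratio-column character matrices.
#' @param method Optional method tag (e.g. `"FAC"`, `"SPR"`).
#' @return Object of class `kd_table`.
#' @export
kd_table <- function(kd, printed = NULL, printed_ratios = NULL, method = "FAC") {
  if (!is.matrix(kd) || is.null(rownames(kd)) || is.null(colnames(kd)))
    stop("'kd' must be a matrix with glycan rownames and lectin colnames")
  if (anyDuplicated(rownames(kd)) || anyDuplicated(colnames(kd)))
    stop("glycan and lectin labels must be unique")
  if (any(kd <= 0, na.rm = TRUE)) stop("K_d values must be positive")
  structure(list(kd = kd, printed = printed, printed_ratios = printed_ratios,
                 method = method),
            class = "kd_table")
}

#' @export
print.kd_table <- function(x, ...) {
  cat(sprintf("<kd_table> %d glycans x %d lectins (%s), %d no-binding cells\n",
              nrow(x$kd), ncol(x$kd), x$method, sum(is.na(x$kd))))
  invisible(x)
}

#' @export
dim.kd_table <- function(x) dim(x$kd)

lectins <- function(tab) colnames(tab$kd)
glycans <- function(tab) rownames(tab$kd)

check_lectin <- function(tab, lectin) {
  missing <- setdiff(lectin, lectins(tab))
  if (length(missing))
    stop("unknown lectin(s): ", paste(missing, collapse = ", "))
  invisible(lectin)
}

#' Read a K_d table from CSV
#'
#' Accepts either a long table with columns `glycan`, `lectin`, `kd` (plus any
#' number of printed `ratio_to_<reference>` columns, as in the packaged
#' fixture) or a wide table with glycan ids in the first column and one column
#' per lectin. `-` (or empty) cells mean no detectable binding.
#'
#' @param path CSV file.
#' @param method Method tag stored on the table.
#' @return A [kd_table()].
#' @export
read_kd_table <- function(path, method = "FAC") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (all(c("glycan", "lectin", "kd") %in% names(tab))) {
    gl <- unique(tab$glycan); le <- unique(tab$lectin)
    shape <- function(col) {
      m <- matrix(NA_character_, length(gl), length(le), dimnames = list(gl, le))
      m[cbind(match(tab$glycan, gl), match(tab$lectin, le))] <- col
      m
    }
    printed <- shape(tab$kd)
    ratio_cols <- grep("^ratio_to_", names(tab), value = TRUE)
    printed_ratios <- lapply(ratio_cols, function(cn) shape(tab[[cn]]))
    names(printed_ratios) <- sub("^ratio_to_", "", ratio_cols)
    kd_table(parse_kd_cells(printed), printed = printed,
             printed_ratios = if (length(printed_ratios)) printed_ratios,
             method = method)
  } else {
    gl <- tab[[1]]
    printed <- as.matrix(tab[, -1, drop = FALSE])
    rownames(printed) <- gl
    kd_table(parse_kd_cells(printed), printed = printed, method = method)
  }
}

parse_kd_cells <- function(m) {
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  num[m %in% c("-", "", NA)] <- NA
  num
}

#' Write a K_d table as wide CSV
#'
#' @param tab A [kd_table()].
#' @param path Output file; no-binding cells are written as `-`.
#' @export
write_kd_table <- function(tab, path) {
  m <- tab$kd
  chr <- ifelse(is.na(m), "-", format(m, trim = TRUE, scientific = FALSE))
  out <- data.frame(glycan = rownames(m), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dissociation constant from a frontal elution measurement
#'
#' In frontal affinity chromatography with the analyte far below the column
#' capacity, the retardation of the elution front past the void front measures
#' affinity through `K_d = Bt / (V - V0)`, with `Bt` the immobilised ligand
#' content (nmol) and `V`, `V0` the front volumes with and without retardation
#' (mL); nmol/mL gives K_d directly in micromolar. Zero retardation
#' (`V == V0`) means no detectable binding and is returned as `NA`, the
#' explicit no-binding marker of [kd_table()].
#'
#' @param Bt Immobilised ligand content, nmol (> 0).
#' @param V Front elution volume, mL.
#' @param V0 Front volume without retardation, mL. All three are recycled.
#' @return Numeric K_d in micromolar; `NA` where `V == V0`.
#' @export
fac_kd <- function(Bt, V, V0) {
  n <- max(length(Bt), length(V), length(V0))
  Bt <- rep_len(Bt, n); V <- rep_len(V, n); V0 <- rep_len(V0, n)
  if (any(Bt <= 0)) stop("'Bt' must be positive")
  if (any(V0 < 0) || any(V < V0)) stop("need V >= V0 >= 0")
  out <- ifelse(V > V0, Bt / (V - V0), NA_real_)
  out
}
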