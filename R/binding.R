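#' Relative binding activity of one lectin against a reference
#'
#' For each glycan, the relative activity is `K_d(reference) / K_d(lectin)`
#' (values > 1 mean the lectin binds more strongly than the reference).
#' Cells where either lectin shows no detectable binding are undefined; the
#' result records which side was missing so summaries can report coverage.
#'
#' @param tab A [kd_table()].
#' @param lectin,reference Lectin column names.
#' @return Data.frame with columns `glycan`, `ratio` (NA when undefined) and
#'   `missing` (`""`, `"lectin"`, `"reference"` or `"both"`).
#' @export
relative_activity <- function(tab, lectin, reference) {
  check_lectin(tab, c(lectin, reference))
  kl <- tab$kd[, lectin]
  kr <- tab$kd[, reference]
  missing <- ifelse(is.na(kl) & is.na(kr), "both",
                    ifelse(is.na(kl), "lectin",
                           ifelse(is.na(kr), "reference", "")))
  data.frame(glycan = glycans(tab), ratio = kr / kl, missing = missing,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Publication-style ratio columns
#'
#' Reproduces the layout of a comparative K_d table: per lectin, the K_d plus
#' one relative-activity column per reference lectin, rounded to 2 significant
#' figures (rounding is applied here, at the presentation layer only).
#'
#' @param tab A [kd_table()].
#' @param references Character vector of reference lectins.
#' @param lectins_used Lectins to tabulate; default all columns.
#' @param sigfigs Significant figures for the ratio columns (default 2).
#' @return Long data.frame: `lectin`, `glycan`, `kd`, then one
#'   `ratio_to_<reference>` column per reference.
#' @export
ratio_columns <- function(tab, references, lectins_used = lectins(tab),
                          sigfigs = 2) {
  check_lectin(tab, c(references, lectins_used))
  out <- do.call(rbind, lapply(lectins_used, function(l) {
    d <- data.frame(lectin = l, glycan = glycans(tab), kd = tab$kd[, l],
                    row.names = NULL, stringsAsFactors = FALSE)
    for (ref in references)
      d[[paste0("ratio_to_", ref)]] <-
        signif(relative_activity(tab, l, ref)$ratio, sigfigs)
    d
  }))
  out
}

#' Specificity ratio between two glycans
#'
#' The ratio of relative binding activities of `glycan_a` over `glycan_b`:
#' `[K_d(ref, a)/K_d(lectin, a)] / [K_d(ref, b)/K_d(lectin, b)]`. A value far
#' from 1 means the lectin's preference between the two glycans differs from
#' the reference's -- a pure specificity measure, invariant to rescaling all
#' K_d of either lectin. Always computed from the K_d cells themselves, never
#' from pre-rounded ratio columns.
#'
#' @param tab A [kd_table()].
#' @param lectin,reference Lectin column names.
#' @param glycan_a,glycan_b Glycan row ids.
#' @return Unrounded numeric ratio; `NA` (with a `missing` attribute) when any
#'   of the four K_d cells is a no-binding cell. Present with
#'   `signif(x, 3)` to match publication formatting.
#' @export
sugar_pair_ratio <- function(tab, lectin, reference, glycan_a, glycan_b) {
  check_lectin(tab, c(lectin, reference))
  gmiss <- setdiff(c(glycan_a, glycan_b), glycans(tab))
  if (length(gmiss)) stop("unknown glycan(s): ", paste(gmiss, collapse = ", "))
  cells <- c(a_ref = tab$kd[glycan_a, reference],
             a_lec = tab$kd[glycan_a, lectin],
             b_ref = tab$kd[glycan_b, reference],
             b_lec = tab$kd[glycan_b, lectin])
  if (anyNA(cells)) {
    out <- NA_real_
    attr(out, "missing") <- names(cells)[is.na(cells)]
    return(out)
  }
  unname((cells["a_ref"] / cells["a_lec"]) / (cells["b_ref"] / cells["b_lec"]))
}

#' Table of specificity ratios for several lectins and glycan pairs
#'
#' @param tab A [kd_table()].
#' @param lectins_used Lectins to compare (columns of the result).
#' @param reference Shared reference lectin.
#' @param pairs Two-column matrix or data.frame of glycan ids (a, b).
#' @param annotations Optional glycan motif annotations (see
#'   [read_glycan_annotations()]); adds a `different_structures` column from
#'   [differential_features()].
#' @param sigfigs Significant figures applied at presentation (default 3).
#' @return Data.frame, one row per pair.
#' @export
sugar_pair_table <- function(tab, lectins_used, reference, pairs,
                             annotations = NULL, sigfigs = 3) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- data.frame(glycan_a = pairs[[1]], glycan_b = pairs[[2]],
                    stringsAsFactors = FALSE)
  for (l in lectins_used)
    out[[l]] <- vapply(seq_len(nrow(pairs)), function(i)
      signif(sugar_pair_ratio(tab, l, reference, pairs[[1]][i], pairs[[2]][i]),
             sigfigs), numeric(1))
  if (!is.null(annotations))
    out$different_structures <- vapply(seq_len(nrow(pairs)), function(i) {
      d <- differential_features(annotations, pairs[[1]][i], pairs[[2]][i])
      paste(c(d$only_a, d$only_b), collapse = "/")
    }, character(1))
  out
}

#' Glycan motif annotations
#'
#' Reads a JSON config mapping glycan ids to sets of structural motif labels
#' (e.g. `"alpha1,4-fucosyl(GlcNAc)"`). Used to attribute specificity shifts
#' between two glycans to the structural features that differ between them.
#'
#' @param path JSON file with a top-level `glycans` object.
#' @return Named list of character vectors, class `glycan_annotations`.
#' @export
read_glycan_annotations <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  ann <- lapply(cfg$glycans, as.character)
  structure(ann, class = "glycan_annotations")
}

#' Structural features differing between two glycans
#'
#' Symmetric difference of the two motif sets, reported with direction.
#'
#' @param annotations A `glycan_annotations` object (named list of motif sets).
#' @param glycan_a,glycan_b Glycan ids present in the annotations.
#' @return List with elements `only_a` (motifs present in a, absent in b) and
#'   `only_b`.
#' @export
differential_features <- function(annotations, glycan_a, glycan_b) {
  miss <- setdiff(c(glycan_a, glycan_b), names(annotations))
  if (length(miss)) stop("unannotated glycan(s): ", paste(miss, collapse = ", "))
  a <- annotations[[glycan_a]]
  b <- annotations[[glycan_b]]
  list(only_a = setdiff(a, b), only_b = setdiff(b, a))
}

#' Gain/loss/retained calls between a lectin and a reference
#'
#' Per glycan: `"lost"` where the reference has a K_d but the lectin shows no
#' detectable binding, `"gained"` for the converse, `"retained"` otherwise
#' (including glycans with no binding on either side).
#'
#' @param tab A [kd_table()].
#' @param lectin,reference Lectin column names.
#' @return Data.frame with columns `glycan` and `call`.
#' @export
binding_loss_calls <- function(tab, lectin, reference) {
  check_lectin(tab, c(lectin, reference))
  kl <- tab$kd[, lectin]
  kr <- tab$kd[, reference]
  call <- ifelse(!is.na(kr) & is.na(kl), "lost",
                 ifelse(is.na(kr) & !is.na(kl), "gained", "retained"))
  data.frame(glycan = glycans(tab), call = call, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Consistency report between printed ratio columns and the K_d cells
#'
#' Publication ratio columns are rounded, and they are often computed from
#' unrounded K_d values that were themselves printed at 1-2 significant
#' figures. This report recomputes every printed ratio cell from the printed
#' K_d cells and classifies it:
#'
#' * `match` -- recomputed ratio rounds to the printed value (within half a
#'   unit of the printed cell's last digit);
#' * `input_rounding` -- not an exact match, but the printed ratio is
#'   achievable from some K_d pair within half a unit of each printed K_d
#'   (i.e. the discrepancy is explained by input rounding alone);
#' * `inconsistent` -- not explainable by rounding;
#' * `not_printed` -- both K_d present but the ratio cell is `-`;
#' * `no_kd` -- ratio cell `-` with at least one K_d missing (consistent).
#'
#' @param tab A [kd_table()] read from a CSV that carried printed
#'   `ratio_to_*` columns (see [read_kd_table()]).
#' @return Data.frame with one row per (lectin, reference, glycan) printed
#'   cell: printed and recomputed values, achievable interval, class.
#' @export
ratio_diff_report <- function(tab) {
  if (is.null(tab$printed_ratios))
    stop("this kd_table carries no printed ratio columns")
  rows <- list()
  for (ref in names(tab$printed_ratios)) {
    pr <- tab$printed_ratios[[ref]]
    for (l in lectins(tab)) for (g in glycans(tab)) {
      printed <- pr[g, l]
      if (is.na(printed)) next
      kl <- tab$kd[g, l]; kr <- tab$kd[g, ref]
      if (printed %in% c("-", "")) {
        cls <- if (!is.na(kl) && !is.na(kr)) "not_printed" else "no_kd"
        rows[[length(rows) + 1L]] <- data.frame(
          lectin = l, reference = ref, glycan = g, printed = printed,
          recomputed = if (cls == "not_printed") kr / kl else NA_real_,
          lo = NA_real_, hi = NA_real_, class = cls, stringsAsFactors = FALSE)
        next
      }
      pv <- as.numeric(printed)
      up <- printed_ulp(printed)
      if (is.na(kl) || is.na(kr)) { cls <- "spurious"; rec <- NA_real_; lo <- hi <- NA_real_ }
      else {
        rec <- kr / kl
        ul <- printed_ulp(tab$printed[g, l])
        ur <- printed_ulp(tab$printed[g, ref])
        lo <- (kr - ur / 2) / (kl + ul / 2)
        hi <- (kr + ur / 2) / (kl - ul / 2)
        eps <- 1e-9
        cls <- if (abs(rec - pv) <= up / 2 + eps) "match"
               else if (pv + up / 2 >= lo - eps && pv - up / 2 <= hi + eps) "input_rounding"
               else "inconsistent"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lectin = l, reference = ref, glycan = g, printed = printed,
        recomputed = rec, lo = lo, hi = hi, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Unit in the last printed digit of a decimal string. Decimals use their
# decimal places; integers are read as exact to the unit except that trailing
# zeros of values >= 100 are treated as non-significant (e.g. "550" ~ 2 s.f.).
printed_ulp <- function(s) {
  s <- sub("^\\s+|\\s+$", "", s)
  if (grepl("\\.", s)) {
    dec <- nchar(sub("^[^.]*\\.", "", s))
    return(10^(-dec))
  }
  v <- as.numeric(s)
  tz <- nchar(s) - nchar(sub("0+$", "", s))
  if (!is.na(v) && v >= 100 && tz > 0) 10^tz else 1
}
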