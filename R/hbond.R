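#' Hydrogen-bond occupancy matrix
#'
#' Binary bonds x snapshots matrix: entry 1 when the bond is present in the
#' snapshot. Row names are bond labels; the snapshot interval (ps) rides along
#' as an attribute.
#'
#' @param mat Matrix of 0/1 with bond-label rownames.
#' @param interval_ps Snapshot interval in ps.
#' @param bonds Optional bond metadata data.frame (one row per matrix row),
#'   as built by [detect_hbonds()].
#' @return Object of class `occupancy_matrix` (a matrix with attributes).
#' @export
occupancy_matrix <- function(mat, interval_ps, bonds = NULL) {
  mat <- as.matrix(mat)
  if (length(mat) && !all(mat %in% c(0, 1))) stop("occupancy entries must be 0/1")
  if (is.null(rownames(mat))) {
    if (nrow(mat) > 0L) stop("bond-label rownames required")
    rownames(mat) <- character(0)
  }
  storage.mode(mat) <- "integer"
  structure(mat, interval_ps = interval_ps, bonds = bonds,
            class = c("occupancy_matrix", "matrix", "array"))
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("<occupancy_matrix> %d bonds x %d snapshots @ %g ps\n",
              nrow(x), ncol(x), attr(x, "interval_ps")))
  invisible(x)
}

#' Detect hydrogen bonds geometrically in a toy trajectory
#'
#' A donor-acceptor pair is hydrogen bonded in a frame iff the heavy-atom
#' distance is `<= d_cut` and (when hydrogens are available) the
#' donor-H...acceptor angle at the hydrogen is `>= angle_cut` for at least one
#' hydrogen covalently attached to the donor (within 1.2 A). Donors are N/O
#' atoms carrying at least one hydrogen; acceptors are N/O atoms. When the
#' structure carries no hydrogens at all, detection falls back to a
#' distance-only criterion over all inter-residue N/O pairs. The published
#' analyses this reproduces do not state their geometric criteria; these
#' defaults are the conventional trajectory-analysis ones and both thresholds
#' are arguments.
#'
#' @param traj A [trajectory_frames()] object.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut Donor-H...acceptor angle cutoff, degrees (default 120).
#' @return List with `bonds` (data.frame of donor/acceptor atom descriptors
#'   and `label`) and `occupancy` (an [occupancy_matrix()]), keeping only
#'   pairs bonded in at least one frame.
#' @export
detect_hbonds <- function(traj, d_cut = 3.5, angle_cut = 120) {
  at <- traj$atoms
  heavy <- which(at$element %in% c("N", "O"))
  hyd <- which(at$element == "H")
  if (!length(heavy)) stop("no donor/acceptor (N/O) atoms in trajectory")
  use_angle <- length(hyd) > 0L
  # hydrogens attached to each heavy atom (first frame geometry)
  attached <- if (use_angle) {
    xyz1 <- traj$coords[, , 1]
    lapply(heavy, function(i) {
      d <- sqrt(colSums((t(xyz1[hyd, , drop = FALSE]) - xyz1[i, ])^2))
      hyd[d <= 1.2]
    })
  }
  reskey <- paste(at$chain, at$resid)
  pairs <- list()
  for (ii in seq_along(heavy)) for (jj in seq_along(heavy)) {
    i <- heavy[ii]; j <- heavy[jj]
    if (i == j || reskey[i] == reskey[j]) next
    if (use_angle && !length(attached[[ii]])) next  # donors need a hydrogen
    if (!use_angle && j < i) next                   # undirected in distance-only mode
    pairs[[length(pairs) + 1L]] <- c(ii, jj)
  }
  if (!length(pairs)) stop("no candidate donor/acceptor pairs")
  nf <- n_frames(traj)
  occ <- matrix(0L, length(pairs), nf)
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k]
    for (p in seq_along(pairs)) {
      i <- heavy[pairs[[p]][1]]; j <- heavy[pairs[[p]][2]]
      dv <- xyz[j, ] - xyz[i, ]
      if (sqrt(sum(dv^2)) > d_cut) next
      ok <- TRUE
      if (use_angle) {
        hs <- attached[[pairs[[p]][1]]]
        ang <- vapply(hs, function(h) {
          v1 <- xyz[i, ] - xyz[h, ]; v2 <- xyz[j, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        }, numeric(1))
        ok <- any(ang >= angle_cut)
      }
      if (ok) occ[p, k] <- 1L
    }
  }
  desc <- function(i) sprintf("%s/%s%d/%s", at$chain[i], at$resname[i], at$resid[i], at$name[i])
  idx <- do.call(rbind, pairs)
  di <- heavy[idx[, 1]]; ai <- heavy[idx[, 2]]
  bonds <- data.frame(
    label = paste(vapply(di, desc, ""), vapply(ai, desc, ""), sep = "--"),
    donor_chain = at$chain[di], donor_resname = at$resname[di],
    donor_resid = at$resid[di], donor_atom = at$name[di],
    acceptor_chain = at$chain[ai], acceptor_resname = at$resname[ai],
    acceptor_resid = at$resid[ai], acceptor_atom = at$name[ai],
    stringsAsFactors = FALSE)
  seen <- rowSums(occ) > 0L
  bonds <- bonds[seen, , drop = FALSE]
  occ <- occ[seen, , drop = FALSE]
  rownames(occ) <- bonds$label
  list(bonds = bonds,
       occupancy = occupancy_matrix(occ, traj$interval_ps, bonds = bonds))
}

#' Overall hydrogen-bond formation rate
#'
#' Fraction of all analysed snapshots in which a bond is present.
#'
#' @param occ An [occupancy_matrix()].
#' @param bond Optional bond label(s); default all bonds.
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
overall_formation_rate <- function(occ, bond = NULL) {
  if (ncol(occ) == 0L) stop("empty occupancy matrix")
  r <- rowMeans(occ)
  if (!is.null(bond)) {
    miss <- setdiff(bond, rownames(occ))
    if (length(miss)) stop("unknown bond(s): ", paste(miss, collapse = ", "))
    r <- r[bond]
  }
  r
}

#' Keep only informative (intermittently formed) bonds
#'
#' Bonds that are almost never or almost always formed carry no usable
#' fluctuation signal; the conventional filter keeps bonds with overall
#' formation rate in `[low, high]` (bounds inclusive), default 10-90%.
#'
#' @param occ An [occupancy_matrix()].
#' @param low,high Inclusive rate bounds, `0 <= low < high <= 1`.
#' @return Filtered [occupancy_matrix()], bond order preserved.
#' @export
filter_informative_bonds <- function(occ, low = 0.10, high = 0.90) {
  stopifnot(low >= 0, high <= 1, low < high)
  if (nrow(occ) == 0L) return(occ)
  r <- rowMeans(occ)
  keep <- r >= low & r <= high
  occupancy_matrix(occ[keep, , drop = FALSE], attr(occ, "interval_ps"),
                   bonds = attr(occ, "bonds")[keep, , drop = FALSE])
}

#' Formation rates in consecutive time bins
#'
#' Truncates the occupancy series to the first `analysis_span_ps`, partitions
#' it into consecutive equal bins of `bin_width_ps`, and returns the mean
#' occupancy of each bond within each bin. A trailing partial bin is dropped.
#' With 10-ps snapshots and the defaults (200-ps bins over the first 3 ns)
#' this gives 15 bins of 20 snapshots.
#'
#' @param occ An [occupancy_matrix()].
#' @param bin_width_ps Bin width in ps; must be a multiple of the snapshot
#'   interval.
#' @param analysis_span_ps Span analysed from the start of the trajectory, ps.
#' @return Matrix bonds x bins of rates in `[0, 1]` (class `binned_rates`),
#'   with attributes `bin_width_ps` and `snapshots_per_bin`.
#' @export
bin_formation_rates <- function(occ, bin_width_ps = 200, analysis_span_ps = 3000) {
  iv <- attr(occ, "interval_ps")
  if (bin_width_ps %% iv != 0)
    stop("'bin_width_ps' must be a multiple of the snapshot interval (", iv, " ps)")
  per_bin <- bin_width_ps / iv
  n_avail <- min(ncol(occ), floor(analysis_span_ps / iv))
  n_bins <- floor(n_avail / per_bin)
  if (n_bins < 1L) stop("analysis span shorter than one bin")
  use <- occ[, seq_len(n_bins * per_bin), drop = FALSE]
  bin_of <- rep(seq_len(n_bins), each = per_bin)
  rates <- t(apply(use, 1, function(row) tapply(row, bin_of, mean)))
  if (nrow(use) == 1L) rates <- matrix(rates, 1, n_bins, dimnames = list(rownames(use), NULL))
  colnames(rates) <- paste0("bin", seq_len(n_bins))
  structure(rates, bin_width_ps = bin_width_ps, snapshots_per_bin = per_bin,
            class = c("binned_rates", "matrix", "array"))
}

#' Pairwise correlation of binned formation rates
#'
#' Product-moment (Pearson) correlation between the bin-rate vectors of every
#' bond pair, `sum((x_i - xbar)*(y_i - ybar)) / sqrt(sum((x_i - xbar)^2) *
#' sum((y_i - ybar)^2))` over time bins `i`. Pairs where either vector has
#' zero variance are undefined (`NA`) and are excluded from all downstream
#' averaging.
#'
#' @param rates A `binned_rates` matrix from [bin_formation_rates()] (>= 3
#'   bins).
#' @return Symmetric correlation matrix with unit diagonal where defined;
#'   attribute `n_undefined` counts the NA off-diagonal pairs.
#' @export
pairwise_correlation <- function(rates) {
  if (ncol(rates) < 3L) stop("need at least 3 time bins")
  cm <- suppressWarnings(stats::cor(t(rates)))
  dimnames(cm) <- list(rownames(rates), rownames(rates))
  structure(cm, n_undefined = sum(is.na(cm[upper.tri(cm)])))
}

#' Assign bonds to structural-element groups
#'
#' Group kinds: intra-loop (both protein residues inside one loop interval),
#' inter-loop pair (residues in two different loops, labelled e.g. `"L2-L6"`),
#' and ligand-residue (a bond between the ligand and one of the sugar-binding
#' residues, labelled e.g. `"Lac-R28"`). Bonds matching no group are returned
#' with `NA` and excluded from network averaging. Loop intervals must not
#' overlap.
#'
#' @param bonds Bond data.frame from [detect_hbonds()] (or with the same
#'   residue/resname columns).
#' @param loop_ranges Named list of inclusive `[start, end]` loop intervals in
#'   reference numbering (e.g. the `L2`..`L6` entries of [read_region_map()]).
#' @param ligand_residues Integer vector of sugar-binding residue numbers
#'   (default 28 and 47, the two arginines).
#' @param ligand_resnames Residue names treated as the ligand (default
#'   `"LAC"`, plus common sugar residue codes).
#' @return Data.frame `label`, `group` (NA = unassigned), class
#'   `group_assignment`.
#' @export
assign_groups <- function(bonds, loop_ranges, ligand_residues = c(28, 47),
                          ligand_resnames = c("LAC", "BGC", "GAL", "GLC")) {
  validate_region_map(loop_ranges)
  nm <- names(loop_ranges)
  for (i in seq_along(loop_ranges)) for (j in seq_len(i - 1L)) {
    a <- loop_ranges[[i]]; b <- loop_ranges[[j]]
    if (a[1] <= b[2] && b[1] <= a[2])
      stop("overlapping loop ranges: ", nm[i], " and ", nm[j])
  }
  loop_of <- function(resid) {
    hit <- which(vapply(loop_ranges, function(iv)
      resid >= iv[1] && resid <= iv[2], logical(1)))
    if (length(hit)) nm[hit[1]] else NA_character_
  }
  group <- vapply(seq_len(nrow(bonds)), function(k) {
    d_lig <- bonds$donor_resname[k] %in% ligand_resnames
    a_lig <- bonds$acceptor_resname[k] %in% ligand_resnames
    if (d_lig && a_lig) return(NA_character_)
    if (d_lig || a_lig) {
      prot <- if (d_lig) bonds$acceptor_resid[k] else bonds$donor_resid[k]
      if (prot %in% ligand_residues) return(paste0("Lac-R", prot))
      return(NA_character_)
    }
    la <- loop_of(bonds$donor_resid[k]); lb <- loop_of(bonds$acceptor_resid[k])
    if (is.na(la) || is.na(lb)) return(NA_character_)
    if (la == lb) return(la)
    paste(sort(c(la, lb)), collapse = "-")
  }, character(1))
  structure(data.frame(label = bonds$label, group = group,
                       stringsAsFactors = FALSE),
            class = c("group_assignment", "data.frame"))
}

#' Average bond-pair correlations within and between groups
#'
#' Edges of the cooperativity network: for groups A and B, the mean of all
#' defined pairwise correlations over bond pairs (a in A, b in B, a != b);
#' the self-edge of a group averages its internal pairs. Undefined
#' (zero-variance) pairs are excluded and counted.
#'
#' @param corr Correlation matrix from [pairwise_correlation()].
#' @param assignment A `group_assignment` (bonds with `NA` group are
#'   dropped). Every group must keep at least one bond present in `corr`.
#' @return Data.frame of class `cooperativity_network`: `group_a`, `group_b`,
#'   `r_mean`, `sign`, `n_pairs`, `n_undefined`; self-edges have
#'   `group_a == group_b`. Edges with no defined pair are omitted.
#' @export
group_average_correlation <- function(corr, assignment) {
  asg <- assignment[!is.na(assignment$group), , drop = FALSE]
  asg <- asg[asg$label %in% rownames(corr), , drop = FALSE]
  if (!nrow(asg)) stop("no assigned bonds present in the correlation matrix")
  groups <- unique(asg$group)
  members <- split(asg$label, asg$group)
  rows <- list()
  for (i in seq_along(groups)) for (j in seq_len(i)) {
    ga <- groups[i]; gb <- groups[j]
    ma <- members[[ga]]; mb <- members[[gb]]
    sub <- corr[ma, mb, drop = FALSE]
    if (ga == gb) {
      if (length(ma) < 2L) next
      vals <- sub[upper.tri(sub)]
    } else {
      vals <- as.vector(sub)
    }
    ok <- !is.na(vals)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = gb, group_b = ga, r_mean = mean(vals[ok]),
      sign = ifelse(mean(vals[ok]) >= 0, "positive", "negative"),
      n_pairs = sum(ok), n_undefined = sum(!ok), stringsAsFactors = FALSE)
  }
  net <- do.call(rbind, rows)
  structure(net, class = c("cooperativity_network", "data.frame"))
}

#' Look up an edge of a cooperativity network
#'
#' @param net A `cooperativity_network`.
#' @param a,b Group labels (order-free).
#' @return The mean correlation of that edge, or `NA` if absent.
#' @export
network_edge <- function(net, a, b) {
  hit <- (net$group_a == a & net$group_b == b) |
         (net$group_a == b & net$group_b == a)
  if (!any(hit)) return(NA_real_)
  net$r_mean[hit][1]
}

#' Convert a cooperativity network to an igraph object
#'
#' @param net A `cooperativity_network`.
#' @return An undirected igraph graph with `weight` (= mean r), `sign` and
#'   `n_pairs` edge attributes; self-edges become loop edges.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$group_a, to = net$group_b, weight = net$r_mean,
               sign = net$sign, n_pairs = net$n_pairs),
    directed = FALSE)
}

#' Export a cooperativity network
#'
#' `write_network_edges()` writes a headers-included TSV edge list;
#' `write_network_graphml()` writes GraphML via igraph.
#'
#' @param net A `cooperativity_network`.
#' @param path Output file.
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Occupancy matrix TSV input/output
#'
#' Format: a `# interval_ps: <x>` header line, then one row per bond (bond
#' label, then one 0/1 column per snapshot, tab-separated, with a header row).
#'
#' @param occ An [occupancy_matrix()].
#' @param path File path.
#' @export
write_occupancy <- function(occ, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# interval_ps: %g", attr(occ, "interval_ps")), con)
  df <- data.frame(bond = rownames(occ), unclass(occ), check.names = FALSE)
  colnames(df) <- c("bond", paste0("s", seq_len(ncol(occ))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  first <- readLines(path, n = 1L)
  interval <- if (grepl("^#\\s*interval_ps:", first))
    as.numeric(sub("^#\\s*interval_ps:\\s*", "", first)) else 10
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  occupancy_matrix(m, interval)
}

#' Write binned rates or a correlation matrix as TSV
#'
#' @param m Matrix with bond-label rownames.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(bond = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
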