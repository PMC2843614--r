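#' Read and validate a pipeline configuration
#'
#' The config is a JSON file selecting pipeline stages and their inputs.
#' Recognised top-level fields: `seed` (integer, single source of
#' randomness), `output_dir`, `region_map` (path), and one object per stage
#' to run: `graft` (`fasta`, `base`, `donor`, `grafts` = list of region-name
#' vectors), `hydropathy` (`fasta`, `ids`, `region`), `tm` (`activity_csv`,
#' `smooth`), `bindcompare` (`kd_csv`, `references`, `annotations`, `pairs`),
#' `hbnet` (`occupancy_tsv` or `pdb`, `d_cut`, `angle_cut`, `bin_width_ps`,
#' `span_ps`, `filter` = `[low, high]`, `ligand_residues`).
#'
#' @param path JSON config file.
#' @return Validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  validate_pipeline_config(cfg, dir = dirname(normalizePath(path)))
}

validate_pipeline_config <- function(cfg, dir = ".") {
  known <- c("seed", "output_dir", "region_map", "graft", "hydropathy",
             "tm", "bindcompare", "hbnet")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "galtrace-out"
  # resolve relative input paths against the config file's directory
  fix <- function(p) if (!is.null(p) && !file.exists(p) &&
                         file.exists(file.path(dir, p))) file.path(dir, p) else p
  cfg$region_map <- fix(cfg$region_map)
  for (st in c("graft", "hydropathy", "tm", "bindcompare", "hbnet"))
    for (f in c("fasta", "activity_csv", "kd_csv", "annotations",
                "occupancy_tsv", "pdb"))
      cfg[[st]][[f]] <- fix(cfg[[st]][[f]])
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline described by a config
#'
#' Executes the requested stages in dependency order (graft -> hydropathy ->
#' tm -> bindcompare -> hbnet), writes all tabular outputs with column
#' headers under `output_dir`, and emits exactly one run report (plain text +
#' JSON) recording per-stage parameters, warnings and output paths. The same
#' config and inputs always produce identical outputs; all randomness flows
#' from the single config seed.
#'
#' @param config A `pipeline_config` (or path to one).
#' @return The run report, invisibly (list of class `run_report`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  report <- list(seed = config$seed, stages = list(), warnings = character(0))
  note <- function(stage, params, outputs) {
    report$stages[[stage]] <<- list(parameters = params, outputs = outputs)
  }
  regions <- if (!is.null(config$region_map)) read_region_map(config$region_map)

  if (!is.null(config$graft)) {
    st <- config$graft
    if (is.null(regions)) stop("stage graft: a region_map is required")
    seqs <- read_aligned_fasta(st$fasta)
    if (!all(c(st$base, st$donor) %in% names(seqs)))
      stop("stage graft: base/donor id not found in ", st$fasta)
    outs <- character(0)
    graft_sets <- if (is.matrix(st$grafts)) asplit(st$grafts, 1) else st$grafts
    for (grafted in graft_sets) {
      grafted <- unlist(grafted)
      mut <- graft_regions(seqs[[st$base]], seqs[[st$donor]], grafted, regions)
      d <- diff_substitutions(seqs[[st$base]], mut)
      stem <- gsub("[^A-Za-z0-9._-]+", "_", mut$id)
      fa <- file.path(out_dir, paste0(stem, ".fasta"))
      tsv <- file.path(out_dir, paste0(stem, "_substitutions.tsv"))
      write_aligned_fasta(mut, fa)
      write_substitutions(d, tsv)
      outs <- c(outs, fa, tsv)
    }
    note("graft", st[c("base", "donor", "grafts")], outs)
  }

  if (!is.null(config$hydropathy)) {
    st <- config$hydropathy
    if (is.null(regions)) stop("stage hydropathy: a region_map is required")
    if (!st$region %in% names(regions))
      stop("stage hydropathy: unknown region name: ", st$region)
    seqs <- read_aligned_fasta(st$fasta)
    ids <- if (is.null(st$ids)) names(seqs) else unlist(st$ids)
    iv <- regions[[st$region]]
    tab <- data.frame(
      id = ids, region = st$region,
      segment = vapply(ids, function(i) segment(seqs[[i]], iv[1], iv[2]), ""),
      stringsAsFactors = FALSE)
    tab$hydropathy_sum <- vapply(tab$segment, hydropathy_sum, numeric(1))
    path <- file.path(out_dir, "hydropathy.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note("hydropathy", st["region"], path)
  }

  if (!is.null(config$tm)) {
    st <- config$tm
    curves <- read_activity_csv(st$activity_csv)
    tab <- tm_table(curves, smooth = isTRUE(st$smooth))
    path <- file.path(out_dir, "tm.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    note("tm", list(smooth = isTRUE(st$smooth)), path)
  }

  if (!is.null(config$bindcompare)) {
    st <- config$bindcompare
    tab <- read_kd_table(st$kd_csv)
    refs <- unlist(st$references)
    rc <- ratio_columns(tab, refs)
    p1 <- file.path(out_dir, "ratio_columns.tsv")
    utils::write.table(rc, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- p1
    if (!is.null(tab$printed_ratios)) {
      rep_tab <- ratio_diff_report(tab)
      p2 <- file.path(out_dir, "ratio_diff_report.tsv")
      utils::write.table(rep_tab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(outs, p2)
      n_bad <- sum(rep_tab$class == "inconsistent")
      if (n_bad) report$warnings <- c(report$warnings,
        sprintf("bindcompare: %d ratio cell(s) not explainable by rounding", n_bad))
    }
    if (!is.null(st$pairs)) {
      ann <- if (!is.null(st$annotations)) read_glycan_annotations(st$annotations)
      pairs <- if (is.matrix(st$pairs)) st$pairs
               else do.call(rbind, lapply(st$pairs, unlist))
      sp <- sugar_pair_table(tab, st$lectins, refs[1], pairs, annotations = ann)
      p3 <- file.path(out_dir, "sugar_pair_ratios.tsv")
      utils::write.table(sp, p3, sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(outs, p3)
    }
    note("bindcompare", st[c("references")], outs)
  }

  if (!is.null(config$hbnet)) {
    st <- config$hbnet
    d_cut <- if (is.null(st$d_cut)) 3.5 else st$d_cut
    angle_cut <- if (is.null(st$angle_cut)) 120 else st$angle_cut
    bw <- if (is.null(st$bin_width_ps)) 200 else st$bin_width_ps
    span <- if (is.null(st$span_ps)) 3000 else st$span_ps
    fl <- if (is.null(st$filter)) c(0.10, 0.90) else unlist(st$filter)
    if (!is.null(st$occupancy_tsv)) {
      occ <- read_occupancy(st$occupancy_tsv)
      bonds <- bonds_from_labels(rownames(occ))
    } else if (!is.null(st$pdb)) {
      traj <- read_multimodel_pdb(st$pdb,
        interval_ps = if (is.null(st$interval_ps)) 10 else st$interval_ps)
      det <- detect_hbonds(traj, d_cut = d_cut, angle_cut = angle_cut)
      occ <- det$occupancy
      bonds <- det$bonds
    } else stop("stage hbnet: need 'occupancy_tsv' or 'pdb'")
    kept <- filter_informative_bonds(occ, fl[1], fl[2])
    rates <- bin_formation_rates(kept, bin_width_ps = bw, analysis_span_ps = span)
    corr <- pairwise_correlation(rates)
    lig <- if (is.null(st$ligand_residues)) c(28, 47) else unlist(st$ligand_residues)
    loops <- regions[grep("^L[0-9]+$", names(regions))]
    asg <- assign_groups(bonds[bonds$label %in% rownames(kept), , drop = FALSE],
                         loops, ligand_residues = lig)
    net <- group_average_correlation(corr, asg)
    paths <- file.path(out_dir, c("binned_rates.tsv", "correlations.tsv",
                                  "network_edges.tsv", "network.graphml"))
    write_matrix_tsv(rates, paths[1])
    write_matrix_tsv(round(corr, 10), paths[2])
    write_network_edges(net, paths[3])
    write_network_graphml(net, paths[4])
    nd <- attr(corr, "n_undefined")
    if (nd) report$warnings <- c(report$warnings,
      sprintf("hbnet: %d bond pair(s) had zero-variance rates (undefined r)", nd))
    note("hbnet", list(d_cut = d_cut, angle_cut = angle_cut, bin_width_ps = bw,
                       span_ps = span, filter = fl), paths)
  }

  report_paths <- file.path(out_dir, c("run_report.txt", "run_report.json"))
  writeLines(format_run_report(report), report_paths[1])
  jsonlite::write_json(report, report_paths[2], auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(report, class = "run_report"))
}

# Recover bond metadata from "chain/RES<id>/atom--chain/RES<id>/atom" labels
# (the format written by detect_hbonds), for occupancy files produced outside
# a trajectory run.
bonds_from_labels <- function(labels) {
  part <- function(side, field) vapply(strsplit(labels, "--"), function(x) {
    bits <- strsplit(x[side], "/")[[1]]
    if (length(bits) != 3L) return(NA_character_)
    switch(field, chain = bits[1],
           resname = gsub("[0-9]+$", "", bits[2]),
           resid = gsub("[^0-9]", "", bits[2]),
           atom = bits[3])
  }, character(1))
  data.frame(label = labels,
             donor_chain = part(1, "chain"), donor_resname = part(1, "resname"),
             donor_resid = as.integer(part(1, "resid")), donor_atom = part(1, "atom"),
             acceptor_chain = part(2, "chain"), acceptor_resname = part(2, "resname"),
             acceptor_resid = as.integer(part(2, "resid")), acceptor_atom = part(2, "atom"),
             stringsAsFactors = FALSE)
}

format_run_report <- function(report) {
  lines <- c("galtrace run report",
             sprintf("seed: %d", report$seed), "")
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    lines <- c(lines, sprintf("stage %s", nm),
               sprintf("  parameters: %s",
                       jsonlite::toJSON(st$parameters, auto_unbox = TRUE)),
               sprintf("  outputs: %s", paste(st$outputs, collapse = ", ")), "")
  }
  if (length(report$warnings))
    lines <- c(lines, "warnings:", paste0("  - ", report$warnings))
  else lines <- c(lines, "warnings: none")
  lines
}
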