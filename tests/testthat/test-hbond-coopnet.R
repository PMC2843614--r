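test_that("geometric detection follows distance and angle cutoffs", {
  # single pair at 2.8 A with a collinear hydrogen: present at defaults
  sim <- gen_toy_trajectory(matrix(c(2.8, 5.0), 1, 2))
  det <- detect_hbonds(sim$trajectory)
  expect_equal(nrow(det$bonds), 1)
  expect_equal(as.vector(det$occupancy), c(1L, 0L))
  # distance-only mode when the structure carries no hydrogens
  sim2 <- gen_toy_trajectory(matrix(c(3.4, 3.6), 1, 2), hydrogens = FALSE)
  det2 <- detect_hbonds(sim2$trajectory)
  expect_equal(as.vector(det2$occupancy), c(1L, 0L))
  # tighter cutoff removes the bond entirely (never formed)
  expect_equal(nrow(detect_hbonds(sim2$trajectory, d_cut = 3.0)$occupancy), 0)
})

test_that("detection reproduces the generator schedule exactly", {
  set.seed(42)
  sched <- matrix(runif(10 * 40, 2.2, 5.2), 10, 40)
  sim <- gen_toy_trajectory(sched)
  det <- detect_hbonds(sim$trajectory)
  truth <- sim$truth(3.5)
  truth <- truth[rowSums(truth) > 0, , drop = FALSE]
  expect_equal(unclass(det$occupancy)[rownames(truth), ], truth,
               ignore_attr = TRUE)
})

test_that("overall formation rate is the snapshot mean", {
  occ <- occupancy_matrix(rbind(on = rep(1L, 10), alt = rep(c(1L, 0L), 5)), 10)
  r <- overall_formation_rate(occ)
  expect_equal(unname(r), c(1, 0.5))
  expect_error(overall_formation_rate(occ, "nope"), "unknown bond")
  set.seed(1)
  bern <- occupancy_matrix(matrix(rbinom(3000, 1, 0.3), 1,
                                  dimnames = list("b", NULL)), 10)
  expect_equal(unname(overall_formation_rate(bern)), 0.3, tolerance = 0.02 / 0.3)
})

test_that("the 10-90% filter keeps exactly the intermittent bonds", {
  m <- rbind(rare = c(rep(1L, 1), rep(0L, 19)),
             mid = rep(c(1L, 0L), 10),
             always = c(rep(1L, 19), 0L))
  occ <- occupancy_matrix(m, 10)
  kept <- filter_informative_bonds(occ)
  expect_equal(rownames(kept), "mid")
  # bounds are inclusive
  edge <- occupancy_matrix(rbind(lo = c(rep(1L, 2), rep(0L, 18))), 10)
  expect_equal(nrow(filter_informative_bonds(edge)), 1)
  expect_equal(nrow(filter_informative_bonds(occ[0, , drop = FALSE] |>
                                               occupancy_matrix(10))), 0)
  all_in <- filter_informative_bonds(occupancy_matrix(m[2, , drop = FALSE], 10))
  expect_equal(nrow(all_in), 1)
})

test_that("binning truncates, partitions and averages like the brute-force oracle", {
  set.seed(3)
  occ <- occupancy_matrix(matrix(rbinom(5 * 60, 1, 0.5), 5, 60,
                                 dimnames = list(paste0("b", 1:5), NULL)), 10)
  rates <- bin_formation_rates(occ, bin_width_ps = 200, analysis_span_ps = 600)
  expect_equal(dim(rates), c(5, 3))
  expect_equal(attr(rates, "snapshots_per_bin"), 20)
  oracle <- sapply(1:3, function(k) rowMeans(occ[, (k - 1) * 20 + 1:20]))
  expect_equal(unclass(rates), oracle, ignore_attr = TRUE)
  const <- occupancy_matrix(matrix(1L, 1, 60, dimnames = list("c", NULL)), 10)
  expect_true(all(bin_formation_rates(const, 200, 600) == 1))
  expect_error(bin_formation_rates(occ, 200, 100), "shorter than one bin")
  expect_error(bin_formation_rates(occ, 15), "multiple of the snapshot interval")
})

test_that("pairwise correlation matches the independent formula oracle", {
  set.seed(11)
  rates <- matrix(runif(8 * 15), 8, 15, dimnames = list(paste0("b", 1:8), NULL))
  rates <- structure(rates, bin_width_ps = 200, snapshots_per_bin = 20,
                     class = c("binned_rates", "matrix", "array"))
  cm <- pairwise_correlation(rates)
  for (i in 1:8) for (j in 1:8)
    expect_equal(cm[i, j], pearson_oracle(rates[i, ], rates[j, ]),
                 tolerance = 1e-12)
  expect_equal(diag(cm), rep(1, 8), ignore_attr = TRUE)
  expect_true(all(abs(cm) <= 1 + 1e-12))
  expect_equal(unclass(cm), t(cm), ignore_attr = TRUE)
})

test_that("anti-phase bonds correlate at -1 and zero variance is undefined", {
  x <- c(0.2, 0.8, 0.5, 0.9, 0.1)
  rates <- structure(rbind(x = x, y = 1 - x, flat = rep(0.5, 5)),
                     class = c("binned_rates", "matrix", "array"))
  cm <- pairwise_correlation(rates)
  expect_equal(cm["x", "y"], -1)
  expect_true(is.na(cm["x", "flat"]))
  expect_equal(attr(cm, "n_undefined"), 2)
  expect_error(pairwise_correlation(rates[, 1:2]), "at least 3")
})

test_that("bonds map onto loop, inter-loop and ligand groups", {
  regions <- load_regions()
  loops <- regions[grep("^L[0-9]+$", names(regions))]
  bonds <- data.frame(
    label = c("intra", "inter", "lig28", "lig99", "out"),
    donor_chain = "A", donor_resname = c("ALA", "ALA", "LAC", "LAC", "ALA"),
    donor_resid = c(37, 28, 200, 200, 37),
    donor_atom = "N",
    acceptor_chain = "A", acceptor_resname = "ALA",
    acceptor_resid = c(40, 90, 28, 99, 110), acceptor_atom = "O",
    stringsAsFactors = FALSE)
  asg <- assign_groups(bonds, loops)
  expect_equal(asg$group, c("L3", "L2-L6", "Lac-R28", NA, NA))
  expect_error(assign_groups(bonds, list(L1 = c(1, 10), L2 = c(5, 15))),
               "overlapping loop ranges")
})

test_that("group averaging reduces to the pair correlation for singleton groups", {
  x <- c(0.2, 0.8, 0.5, 0.9, 0.1)
  rates <- structure(rbind(a = x, b = rev(x)),
                     class = c("binned_rates", "matrix", "array"))
  cm <- pairwise_correlation(rates)
  net <- group_average_correlation(cm, data.frame(label = c("a", "b"),
                                                  group = c("G1", "G2")))
  expect_equal(nrow(net), 1)
  expect_equal(network_edge(net, "G1", "G2"), cm["a", "b"])
  expect_true(is.na(network_edge(net, "G1", "G1")))  # singleton: no self pairs
})

test_that("the pipeline is equivariant under bond permutation and early filtering", {
  sim <- planted_occupancy(seed = 5, n_snapshots = 600)
  occ <- sim$occupancy
  set.seed(99)
  perm <- sample(nrow(occ))
  occ_p <- occupancy_matrix(unclass(occ)[perm, ], attr(occ, "interval_ps"))
  r1 <- bin_formation_rates(occ, analysis_span_ps = 600)
  r2 <- bin_formation_rates(occ_p, analysis_span_ps = 600)
  expect_equal(unclass(r2), unclass(r1)[perm, ], ignore_attr = TRUE)
  # filter-then-correlate equals correlate-then-restrict
  kept <- filter_informative_bonds(occ)
  c1 <- pairwise_correlation(bin_formation_rates(kept, analysis_span_ps = 600))
  c2 <- pairwise_correlation(r1)[rownames(kept), rownames(kept)]
  expect_equal(unclass(c1), unclass(c2), ignore_attr = TRUE)
})

test_that("planted two-factor structure is recovered and shuffling destroys it", {
  sim <- planted_occupancy(seed = 2)
  net <- coopnet_chain(sim)
  expect_true(md_sign_pattern_ok(net))
  expect_true(all(abs(net$r_mean) <= 1))
  # per-bond snapshot shuffling: the synchronous structure is gone and the
  # network collapses (a single shared permutation would provably preserve
  # contemporaneous correlations; see the vignette)
  means <- sapply(1:5, function(s) {
    sim <- planted_occupancy(seed = s, n_snapshots = 3000)
    set.seed(1000 + s)
    m <- unclass(sim$occupancy)
    shuf <- occupancy_matrix(t(apply(m, 1, sample)), 10)
    occ <- filter_informative_bonds(shuf)
    net <- group_average_correlation(
      pairwise_correlation(bin_formation_rates(occ)),
      truth_assignment(sim))
    mean(abs(net$r_mean))
  })
  expect_lt(mean(means), 0.3)
})

test_that("cooperativity networks export to edge list, GraphML and igraph", {
  sim <- planted_occupancy(seed = 3, n_snapshots = 600)
  occ <- filter_informative_bonds(sim$occupancy)
  net <- group_average_correlation(
    pairwise_correlation(bin_formation_rates(occ, analysis_span_ps = 600)),
    truth_assignment(sim))
  g <- as_igraph(net)
  expect_s3_class(g, "igraph")
  expect_equal(igraph::ecount(g), nrow(net))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_edges(net, p1)
  back <- utils::read.delim(p1)
  expect_equal(nrow(back), nrow(net))
  write_network_graphml(net, p2)
  expect_true(file.size(p2) > 0)
})

test_that("occupancy matrices round trip through TSV with their interval", {
  sim <- planted_occupancy(seed = 4, n_snapshots = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy(sim$occupancy, path)
  back <- read_occupancy(path)
  expect_equal(unclass(back), unclass(sim$occupancy), ignore_attr = TRUE)
  expect_equal(attr(back, "interval_ps"), 10)
  expect_equal(rownames(back), rownames(sim$occupancy))
})
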