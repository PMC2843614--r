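# Shared builders for the test suite. Fixtures are constructed in code or
# loaded from the plain-text files under inst/extdata.

fixture <- function(file) galtrace_example(file)

aseq <- function(id, s, pos = NULL) {
  res <- strsplit(s, "")[[1]]
  if (is.null(pos)) pos <- seq_along(res)
  aligned_sequence(id, res, pos)
}

load_congerins <- function() read_aligned_fasta(fixture("congerin_alignment_synthetic.fasta"))

load_regions <- function() read_region_map(fixture("region_map.json"))

load_table1 <- function() read_kd_table(fixture("table1_kd.csv"))

# small kd table built in code: 2 lectins x 3 glycans with one planted
# no-binding cell for the "lectin" column
tiny_kd <- function() {
  kd <- matrix(c(2, 4, 8,
                 1, NA, 2), ncol = 2,
               dimnames = list(c("g1", "g2", "g3"), c("ref", "lec")))
  kd_table(kd)
}

# group assignment straight from a gen_occupancy ground-truth record
truth_assignment <- function(sim) {
  data.frame(label = sim$truth$bonds$label, group = sim$truth$bonds$group,
             stringsAsFactors = FALSE)
}

# default planted two-factor occupancy (the stated world of the MD property
# tests): loop groups L2..L6 plus two lactose-arginine groups
planted_occupancy <- function(seed, n_snapshots = 3000) {
  f <- default_md_factors()
  gen_occupancy(default_md_groups(), f$factor_of, f$loadings, f$factor_cor,
                n_snapshots = n_snapshots, rates = 0.5, seed = seed)
}

# full analysis chain: filter -> 200-ps bins -> Pearson -> group averages
coopnet_chain <- function(sim) {
  occ <- filter_informative_bonds(sim$occupancy)
  rates <- bin_formation_rates(occ)
  corr <- pairwise_correlation(rates)
  asg <- truth_assignment(sim)
  asg <- asg[asg$label %in% rownames(occ), ]
  group_average_correlation(corr, asg)
}

# the published qualitative sign pattern: cooperation within {L3,L5} and the
# L2-mediated {L2,L4,L6} block, the latter anti-correlated with each
# lactose-arginine bond group
md_sign_pattern_ok <- function(net) {
  e <- function(a, b) network_edge(net, a, b)
  block <- function(lac) mean(c(e("L2", lac), e("L4", lac), e("L6", lac)))
  isTRUE(e("L3", "L5") > 0 && e("L2", "L4") > 0 && e("L2", "L6") > 0 &&
         block("Lac-R28") < 0 && block("Lac-R47") < 0)
}

# independent textbook formula for the product-moment coefficient, kept free
# of stats::cor on purpose
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
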