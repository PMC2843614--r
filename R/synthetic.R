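#' Synthetic hydrogen-bond occupancy with planted correlation structure
#'
#' Generates binary bond-presence series by thresholding latent Gaussian
#' propensities driven by shared factors (probit construction): bond `b` in
#' group `g` has latent `z_b(t) = lambda_g * F_{f(g)}(t) +
#' sqrt(1 - lambda_g^2) * eps_b(t)` and is present when `z_b(t) <=
#' qnorm(p_b)`, so each bond's marginal formation rate matches its target and
#' the sign structure of group correlations maps analytically onto the factor
#' loadings and the inter-factor correlation. An optional AR(1) coefficient
#' adds temporal persistence to all latent series; a two-state Markov mode
#' (`process = "markov"`, independent bonds) is available when only
#' autocorrelation realism is needed.
#'
#' @param groups Named integer vector: bonds per group.
#' @param factor_of Named character vector mapping each group to a latent
#'   factor name.
#' @param loadings Named numeric vector in `[-1, 1]`: loading of each group on
#'   its factor.
#' @param factor_cor Correlation matrix between the factors (dimnames = factor
#'   names); default identity.
#' @param n_snapshots Number of snapshots (default 3000).
#' @param interval_ps Snapshot interval, ps (default 10).
#' @param rates Marginal formation-rate targets in (0, 1): single value,
#'   per-group named vector, or per-bond vector; default 0.5.
#' @param ar AR(1) coefficient in `[0, 1)` for latent series (default 0).
#' @param process `"probit"` (default) or `"markov"`.
#' @param seed Integer seed; the generator is bit-reproducible given a seed.
#' @return List with `occupancy` (an [occupancy_matrix()]) and `truth`
#'   (factor series, per-bond group/factor/loading/target-rate table).
#' @export
gen_occupancy <- function(groups, factor_of = NULL, loadings = NULL,
                          factor_cor = NULL, n_snapshots = 3000,
                          interval_ps = 10, rates = 0.5, ar = 0,
                          process = c("probit", "markov"), seed = 1) {
  process <- match.arg(process)
  stopifnot(!is.null(names(groups)), all(groups >= 1))
  if (is.null(factor_of))
    factor_of <- stats::setNames(rep("F1", length(groups)), names(groups))
  if (is.null(loadings))
    loadings <- stats::setNames(rep(0, length(groups)), names(groups))
  if (any(abs(loadings) > 1)) stop("loadings must lie in [-1, 1]")
  fnames <- unique(unname(factor_of))
  if (is.null(factor_cor)) {
    factor_cor <- diag(length(fnames))
    dimnames(factor_cor) <- list(fnames, fnames)
  }
  bond_group <- rep(names(groups), groups)
  n_b <- length(bond_group)
  labels <- paste0(bond_group, ".b", unlist(lapply(groups, seq_len)))
  p <- if (length(rates) == 1L) rep(rates, n_b)
       else if (!is.null(names(rates))) unname(rates[bond_group])
       else rep_len(rates, n_b)
  if (any(is.na(p) | p <= 0 | p >= 1)) stop("rate targets must lie in (0, 1)")
  set.seed(seed)
  ar_series <- function(innov) {
    if (ar == 0) return(innov)
    stats::filter(innov * sqrt(1 - ar^2), ar, method = "recursive")
  }
  if (process == "markov") {
    occ <- matrix(0L, n_b, n_snapshots)
    f <- 0.1  # flip-rate scale; stationary occupancy equals the target rate
    for (b in seq_len(n_b)) {
      x <- as.integer(stats::runif(1) < p[b])
      for (t in seq_len(n_snapshots)) {
        flip <- if (x == 1L) f * (1 - p[b]) else f * p[b]
        if (stats::runif(1) < flip) x <- 1L - x
        occ[b, t] <- x
      }
    }
    truth <- list(factors = NULL,
                  bonds = data.frame(label = labels, group = bond_group,
                                     target_rate = p, stringsAsFactors = FALSE))
  } else {
    L <- chol(factor_cor[fnames, fnames, drop = FALSE])
    innov <- matrix(stats::rnorm(n_snapshots * length(fnames)), n_snapshots)
    fac <- innov %*% L
    fac <- apply(fac, 2, ar_series)
    colnames(fac) <- fnames
    occ <- matrix(0L, n_b, n_snapshots)
    for (b in seq_len(n_b)) {
      lam <- loadings[[bond_group[b]]]
      eps <- ar_series(stats::rnorm(n_snapshots))
      z <- lam * fac[, factor_of[[bond_group[b]]]] + sqrt(1 - lam^2) * eps
      occ[b, ] <- as.integer(z <= stats::qnorm(p[b]))
    }
    truth <- list(factors = fac,
                  bonds = data.frame(label = labels, group = bond_group,
                                     factor = unname(factor_of[bond_group]),
                                     loading = unname(loadings[bond_group]),
                                     target_rate = p, stringsAsFactors = FALSE))
  }
  rownames(occ) <- labels
  list(occupancy = occupancy_matrix(occ, interval_ps), truth = truth)
}

#' Synthetic thermal-inactivation curve
#'
#' Logistic decay of residual activity with temperature:
#' `a(T) = 1 / (1 + exp((T - midpoint)/steepness))`, plus optional Gaussian
#' noise, clipped to `[0, 1]`. At zero noise the value at the midpoint is
#' exactly 0.5.
#'
#' @param midpoint Half-activity temperature planted in the curve, degrees C.
#' @param steepness Transition width parameter, degrees C (default 1.5,
#'   giving the few-degree transition typical of lectin inactivation assays).
#' @param temperatures Sampling grid, degrees C (default 38-62 in 1-degree
#'   steps, the assay's measured range).
#' @param noise_sd Gaussian noise standard deviation on the activity scale.
#' @param seed Integer seed (only consumed when `noise_sd > 0`).
#' @return An [inactivation_curve()]; the planted midpoint is attached as
#'   attribute `midpoint`.
#' @export
gen_inactivation_curve <- function(midpoint, steepness = 1.5,
                                   temperatures = seq(38, 62, by = 1),
                                   noise_sd = 0, seed = 1) {
  a <- 1 / (1 + exp((temperatures - midpoint) / steepness))
  if (noise_sd > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(length(a), sd = noise_sd)
  }
  a <- pmin(1, pmax(0, a))
  curve <- inactivation_curve(temperatures, a)
  attr(curve, "midpoint") <- midpoint
  curve
}

#' Synthetic dissociation-constant table with planted region effects
#'
#' Builds `K_d(lectin, glycan) = baseline(glycan) / prod(effects of the
#' lectin's grafted regions on the glycan's class) * lognormal noise`, so a
#' planted region-specific affinity gain (e.g. a 20-fold L5 effect on the
#' fucosylated class) propagates exactly into relative activities and
#' sugar-pair specificity ratios. Missing cells (no detectable binding) can be
#' planted per (lectin, glycan).
#'
#' @param baseline Named numeric vector: baseline K_d per glycan (uM).
#' @param classes Named character vector: structural class per glycan.
#' @param lectin_regions Named list: grafted region names per lectin (the
#'   baseline lectin has `character(0)`).
#' @param effects Named list (by region) of named numeric vectors (by class):
#'   multiplicative affinity gain (> 0) of that region graft on that class.
#'   Classes absent from a region's vector get effect 1.
#' @param noise_sdlog Lognormal noise sd on the log scale (default 0).
#' @param missing Optional data.frame with columns `lectin`, `glycan` marking
#'   no-binding cells.
#' @param seed Integer seed.
#' @return List with `table` (a [kd_table()]) and `truth` (the planted
#'   effects per cell).
#' @export
gen_kd_table <- function(baseline, classes, lectin_regions, effects,
                         noise_sdlog = 0, missing = NULL, seed = 1) {
  stopifnot(!is.null(names(baseline)), all(baseline > 0),
            identical(sort(names(baseline)), sort(names(classes))))
  gl <- names(baseline)
  le <- names(lectin_regions)
  set.seed(seed)
  kd <- matrix(NA_real_, length(gl), length(le), dimnames = list(gl, le))
  eff <- kd
  for (l in le) for (g in gl) {
    e <- 1
    for (reg in lectin_regions[[l]]) {
      ev <- effects[[reg]]
      if (!is.null(ev) && classes[[g]] %in% names(ev)) e <- e * ev[[classes[[g]]]]
    }
    if (any(unlist(effects) <= 0)) stop("effects must be positive")
    noise <- if (noise_sdlog > 0) exp(stats::rnorm(1, sd = noise_sdlog)) else 1
    kd[g, l] <- baseline[[g]] / e * noise
    eff[g, l] <- e
  }
  if (!is.null(missing))
    for (i in seq_len(nrow(missing)))
      kd[missing$glycan[i], missing$lectin[i]] <- NA
  list(table = kd_table(kd, method = "synthetic"),
       truth = list(effects = eff, classes = classes))
}

#' Synthetic frontal-elution measurement for a known K_d
#'
#' Inverse of [fac_kd()]: given a target K_d (uM) and column parameters,
#' returns the front volume `V = V0 + Bt / K_d`. Used for round-trip checks
#' of the frontal-chromatography relation.
#'
#' @param kd Target dissociation constant, uM.
#' @param Bt Immobilised ligand content, nmol (default 0.5).
#' @param V0 Unretarded front volume, mL (default 5).
#' @return Data.frame with columns `Bt`, `V`, `V0`, `kd`.
#' @export
gen_frontal_elution <- function(kd, Bt = 0.5, V0 = 5) {
  data.frame(Bt = Bt, V = V0 + Bt / kd, V0 = V0, kd = kd)
}

#' Toy multi-model trajectory with scheduled donor-acceptor distances
#'
#' Builds coordinate frames in which each donor-acceptor pair follows its
#' distance schedule exactly: pair `i` sits on its own line (offset 50 A from
#' the others, so pairs never interact), with the donor nitrogen at the
#' origin, its hydrogen 1.0 A towards the acceptor (collinear, so the
#' donor-H...acceptor angle is exactly 180 degrees), and the acceptor oxygen
#' at the scheduled distance. Geometric detection therefore has closed-form
#' ground truth: bond `i` is present in frame `k` iff `schedule[i, k] <=
#' d_cut`.
#'
#' @param schedules Numeric matrix pairs x frames of donor-acceptor distances
#'   (Angstrom, > 0).
#' @param interval_ps Snapshot interval, ps (default 10).
#' @param hydrogens Place donor hydrogens (default TRUE); `FALSE` exercises
#'   distance-only detection.
#' @return List with `trajectory` (a [trajectory_frames()]) and `truth`
#'   (function of `d_cut` returning the expected occupancy matrix).
#' @export
gen_toy_trajectory <- function(schedules, interval_ps = 10, hydrogens = TRUE) {
  if (!is.matrix(schedules)) schedules <- matrix(schedules, nrow = 1)
  if (any(schedules <= 0)) stop("distances must be positive")
  n_p <- nrow(schedules); n_f <- ncol(schedules)
  per <- if (hydrogens) 3L else 2L
  atoms <- do.call(rbind, lapply(seq_len(n_p), function(i) {
    rows <- data.frame(
      name = c("N", if (hydrogens) "H", "O"),
      resname = c("DON", if (hydrogens) "DON", "ACC"),
      chain = "A",
      resid = c(2L * i - 1L, if (hydrogens) 2L * i - 1L, 2L * i),
      element = c("N", if (hydrogens) "H", "O"),
      stringsAsFactors = FALSE)
    rows
  }))
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, c("serial", "name", "resname", "chain", "resid", "element")]
  coords <- array(0, c(nrow(atoms), 3, n_f))
  for (i in seq_len(n_p)) {
    base <- (i - 1L) * per
    y <- 50 * (i - 1)
    coords[base + 1L, 2, ] <- y
    if (hydrogens) {
      coords[base + 2L, 1, ] <- 1.0
      coords[base + 2L, 2, ] <- y
    }
    coords[base + per, 1, ] <- schedules[i, ]
    coords[base + per, 2, ] <- y
  }
  traj <- trajectory_frames(atoms, coords, interval_ps)
  truth <- function(d_cut = 3.5) {
    m <- matrix(as.integer(schedules <= d_cut), n_p, n_f)
    rownames(m) <- sprintf("A/DON%d/N--A/ACC%d/O", 2L * seq_len(n_p) - 1L,
                           2L * seq_len(n_p))
    m
  }
  list(trajectory = traj, truth = truth)
}
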