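#' Specify a synthetic rs-fMRI cohort
#'
#' Describes a three-group cohort (healthy controls `HC`, subclinical
#' depression `SD`, major depressive disorder `MDD`) of ROI time series,
#' head-motion traces and phenotypes, with optional planted connectivity
#' effects whose ground truth is returned alongside the generated data.
#'
#' Defaults mirror the acquisition the pipeline targets: 200 volumes at
#' TR = 2.5 s on a 246-node parcellation, with enrolled group sizes
#' HC = 40, SD = 34, MDD = 40 and covariate distributions matching the
#' study population (young adults, BDI-II elevated in SD, HAMD elevated
#' in MDD).
#'
#' @param n_per_group named integer vector of enrolled subjects per group;
#'   names must be `HC`, `SD`, `MDD`, each at least 2.
#' @param g number of parcellation nodes (default 246).
#' @param n_volumes number of acquired volumes T (default 200).
#' @param tr_seconds repetition time in seconds (default 2.5).
#' @param effects list of [effect_spec()] objects planting group-specific
#'   hub connectivity changes.
#' @param ar_coefficient lag-1 temporal autocorrelation of the ROI series,
#'   in \[0, 1).
#' @param motion_model list with `spike_rate` (expected motion spikes per
#'   volume), `spike_amplitude` (spike size in mm), `drift_scale`
#'   (per-volume random-walk step SD in mm).
#' @param covariate_model per-group covariate distributions; see
#'   [default_covariate_model()].
#' @param n_factors number of latent factors in the base connectivity
#'   model (default 10).
#' @param seed master integer seed; per-subject streams are derived from
#'   it so cohorts are reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 40L, SD = 34L, MDD = 40L),
                        g = 246L,
                        n_volumes = 200L,
                        tr_seconds = 2.5,
                        effects = list(),
                        ar_coefficient = 0.3,
                        motion_model = list(spike_rate = 0.01,
                                            spike_amplitude = 0.5,
                                            drift_scale = 0.02),
                        covariate_model = default_covariate_model(),
                        n_factors = 10L,
                        seed = 1L) {
  groups <- c("HC", "SD", "MDD")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must be named with HC, SD and MDD")
  n_per_group <- as.integer(n_per_group[groups])
  if (any(n_per_group < 2L))
    stop("each group needs at least 2 subjects")
  if (g < 3L) stop("g must be at least 3")
  if (n_volumes <= 20L) stop("n_volumes must exceed 20")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
    if (e$hub_node > g) stop("effect hub_node exceeds node count g")
    if (e$partner_count >= g) stop("effect partner_count must be < g")
  }
  structure(list(n_per_group = n_per_group, g = as.integer(g),
                 n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
                 effects = effects, ar_coefficient = ar_coefficient,
                 motion_model = motion_model,
                 covariate_model = covariate_model,
                 n_factors = as.integer(n_factors),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Plant a hub connectivity effect in one group
#'
#' Adds `delta_r` to the correlation between `hub_node` and its
#' `partner_count` partner nodes in the designated group's connectivity
#' matrix. Partners are chosen deterministically as the nodes following
#' the hub in index order (wrapping around), so the ground truth is fully
#' determined by the spec.
#'
#' @param group one of "HC", "SD", "MDD".
#' @param hub_node node index (1-based).
#' @param partner_count number of partner nodes receiving the increment.
#' @param delta_r signed correlation increment, |delta_r| < 1.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(group, hub_node, partner_count, delta_r) {
  group <- match.arg(group, c("HC", "SD", "MDD"))
  if (abs(delta_r) >= 1) stop("|delta_r| must be < 1")
  if (hub_node < 1L) stop("hub_node must be a positive index")
  if (partner_count < 1L) stop("partner_count must be positive")
  structure(list(group = group, hub_node = as.integer(hub_node),
                 partner_count = as.integer(partner_count),
                 delta_r = delta_r),
            class = "effect_spec")
}

#' Default per-group covariate distributions
#'
#' Means and SDs for age and education (years), the proportion of female
#' subjects, and the clinical scores (BDI-II for HC/SD, HAMD for MDD)
#' follow the demographics of the target study population: university-age
#' subjects with comparable education across groups.
#'
#' @return a named list of per-group parameter lists.
#' @export
default_covariate_model <- function() {
  list(
    HC  = list(age_mean = 19.24, age_sd = 0.94, edu_mean = 13.18,
               edu_sd = 0.87, female_prop = 16 / 33,
               bdi_mean = 1.55, bdi_sd = 1.44,
               hamd_mean = NA_real_, hamd_sd = NA_real_),
    SD  = list(age_mean = 19.65, age_sd = 1.77, edu_mean = 13.36,
               edu_sd = 0.92, female_prop = 16 / 26,
               bdi_mean = 22.46, bdi_sd = 7.73,
               hamd_mean = NA_real_, hamd_sd = NA_real_),
    MDD = list(age_mean = 21.13, age_sd = 6.17, edu_mean = 12.94,
               edu_sd = 2.60, female_prop = 27 / 38,
               bdi_mean = NA_real_, bdi_sd = NA_real_,
               hamd_mean = 21.51, hamd_sd = 4.58)
  )
}

# Shared base correlation structure: one positive global factor plus
# n_factors - 1 zero-mean factors and unit idiosyncratic noise, rescaled
# to a correlation matrix. Gives the positive-dominant, low-rank-ish
# structure typical of empirical FC matrices.
base_correlation <- function(spec) {
  g <- spec$g
  k <- max(1L, spec$n_factors)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  load <- matrix(stats::rnorm(g * k, 0, 0.3), g, k)
  load[, 1] <- stats::rnorm(g, 0.5, 0.15)
  sigma <- tcrossprod(load) + diag(g)
  stats::cov2cor(sigma)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Nearest correlation matrix by Higham's (2002) alternating projections
# with Dykstra correction: PSD projection alternating with unit-diagonal
# restoration. Unlike naive eigenvalue clipping plus re-standardisation,
# this changes the planted entries minimally and does not deflate the
# hub's remaining correlations through variance inflation.
nearest_correlation <- function(a, tol = 1e-7, max_iter = 200L) {
  y <- a
  ds <- matrix(0, nrow(a), ncol(a))
  for (it in seq_len(max_iter)) {
    r <- y - ds
    ed <- eigen(r, symmetric = TRUE)
    x <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
    x <- (x + t(x)) / 2
    ds <- x - r
    y_old <- y
    y <- x
    diag(y) <- 1
    if (max(abs(y - y_old)) < tol) break
  }
  # final tiny ridge so chol() succeeds despite roundoff
  ed <- eigen(y, symmetric = TRUE)
  if (min(ed$values) < 1e-8) {
    y <- ed$vectors %*% (pmax(ed$values, 1e-8) * t(ed$vectors))
    y <- stats::cov2cor((y + t(y)) / 2)
  }
  y
}

effect_partners <- function(effect, g) {
  partners <- ((effect$hub_node - 1L + seq_len(effect$partner_count)) %% g) + 1L
  partners[partners != effect$hub_node]
}

#' Build the group connectivity (correlation) matrix
#'
#' Starts from the base correlation matrix shared by all groups, adds
#' `delta_r` to the hub-partner correlations of every effect planted in
#' `group`, and projects the result to the nearest positive-definite
#' correlation matrix by eigenvalue clipping and re-standardisation.
#'
#' @param spec a [cohort_spec()].
#' @param group group label ("HC", "SD" or "MDD").
#' @return a list with `cor` (the positive-definite group correlation
#'   matrix), `raw` (the perturbed matrix before the PD projection),
#'   `base` (the unperturbed base matrix) and `affected_nodes` (the hub
#'   node indices of the group's effects).
#' @export
build_group_covariance <- function(spec, group) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group, c("HC", "SD", "MDD"))
  base <- base_correlation(spec)
  r <- base
  affected <- integer(0)
  for (e in spec$effects) {
    if (e$group != group) next
    partners <- effect_partners(e, spec$g)
    newvals <- r[e$hub_node, partners] + e$delta_r
    if (any(abs(newvals) >= 1))
      stop(sprintf(
        "effect on group %s hub %d (delta_r = %g) drives |r| >= 1",
        e$group, e$hub_node, e$delta_r))
    r[e$hub_node, partners] <- newvals
    r[partners, e$hub_node] <- newvals
    affected <- c(affected, e$hub_node)
  }
  raw <- r
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    r <- nearest_correlation(r)
  list(cor = r, raw = raw, base = base, affected_nodes = unique(affected))
}

# Stationary AR(1) series with cross-sectional covariance sigma_chol'X:
# innovations are scaled by sqrt(1 - phi^2) so the marginal covariance
# equals the target at any lag-0.
simulate_series <- function(n_volumes, chol_sigma, phi, burn = 50L) {
  g <- ncol(chol_sigma)
  total <- n_volumes + burn
  eps <- matrix(stats::rnorm(total * g), total, g) %*% chol_sigma
  if (phi > 0) {
    eps <- eps * sqrt(1 - phi^2)
    x <- apply(eps, 2, function(e)
      as.numeric(stats::filter(e, phi, method = "recursive")))
  } else {
    x <- eps
  }
  x[(burn + 1):total, , drop = FALSE]
}

# Realignment trace: smooth random walk plus Poisson-placed single-volume
# spikes. Translations in mm; rotations in radians, scaled so that a spike
# contributes a comparable FD (arc length on a 50 mm sphere).
simulate_realignment <- function(n_volumes, motion) {
  rp <- matrix(0, n_volumes, 6)
  for (p in 1:3)
    rp[, p] <- cumsum(stats::rnorm(n_volumes, 0, motion$drift_scale))
  for (p in 4:6)
    rp[, p] <- cumsum(stats::rnorm(n_volumes, 0, motion$drift_scale / 50))
  n_spikes <- stats::rpois(1, motion$spike_rate * n_volumes)
  if (n_spikes > 0) {
    at <- sample(2:n_volumes, min(n_spikes, n_volumes - 1))
    for (t in at) {
      p <- sample(1:6, 1)
      amp <- motion$spike_amplitude * stats::runif(1, 0.8, 1.2) *
        sample(c(-1, 1), 1)
      if (p >= 4) amp <- amp / 50
      rp[t, p] <- rp[t, p] + amp
    }
  }
  rp
}

subject_seed <- function(master, group_index, within_index) {
  as.integer((as.double(master) * 7919 + group_index * 104729 +
                within_index * 97) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws, for every subject, a T x g ROI time-series matrix (stationary
#' AR(1) process with the group's planted correlation structure), a T x 6
#' realignment trace (random-walk drift plus motion spikes), and
#' phenotype covariates. Fully reproducible given `spec$seed`; per-subject
#' random streams are derived from the master seed with fixed offsets so
#' a subject's data do not depend on the other groups' sizes.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort` with `subjects` (list of
#'   `subject_record`: subject_id, group, age, sex, education, bdi, hamd,
#'   series, realignment), `truth` (per-group affected nodes and the
#'   effect list) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("HC", "SD", "MDD")
  covs <- list()
  for (grp in groups) covs[[grp]] <- build_group_covariance(spec, grp)
  chols <- lapply(covs, function(x) chol(x$cor))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  subjects <- list()
  idx <- 0L
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    cm <- spec$covariate_model[[grp]]
    for (si in seq_len(spec$n_per_group[gi])) {
      idx <- idx + 1L
      set.seed(subject_seed(spec$seed, gi, si))
      series <- simulate_series(spec$n_volumes, chols[[grp]],
                                spec$ar_coefficient)
      rp <- simulate_realignment(spec$n_volumes, spec$motion_model)
      age <- round(max(17, stats::rnorm(1, cm$age_mean, cm$age_sd)), 1)
      edu <- round(max(6, stats::rnorm(1, cm$edu_mean, cm$edu_sd)), 1)
      sex <- if (stats::runif(1) < cm$female_prop) "female" else "male"
      bdi <- if (is.na(cm$bdi_mean)) NA_real_ else
        round(max(0, stats::rnorm(1, cm$bdi_mean, cm$bdi_sd)), 1)
      hamd <- if (is.na(cm$hamd_mean)) NA_real_ else
        round(max(0, stats::rnorm(1, cm$hamd_mean, cm$hamd_sd)), 1)
      subjects[[idx]] <- structure(
        list(subject_id = sprintf("sub-%s%03d", grp, si), group = grp,
             age = age, sex = sex, education = edu, bdi = bdi, hamd = hamd,
             series = series, realignment = rp),
        class = "subject_record")
    }
  }
  truth <- list(
    affected_nodes = lapply(covs, function(x) x$affected_nodes),
    effects = spec$effects)
  structure(list(subjects = subjects, truth = truth, spec = spec),
            class = "cohort")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      sprintf("HC=%d SD=%d MDD=%d subjects,", x$n_per_group[1],
              x$n_per_group[2], x$n_per_group[3]),
      sprintf("g=%d nodes, T=%d volumes, TR=%gs,", x$g, x$n_volumes,
              x$tr_seconds),
      sprintf("%d planted effect(s), seed=%d\n", length(x$effects), x$seed))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), g=%d, T=%d\n",
              length(x$subjects),
              paste(sprintf("%s=%d", c("HC", "SD", "MDD"),
                            x$spec$n_per_group), collapse = " "),
              x$spec$g, x$spec$n_volumes))
  invisible(x)
}

#' Phenotype table of a cohort
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @return a data.frame with one row per subject: subject_id, group, age,
#'   sex, education, bdi, hamd.
#' @export
cohort_phenotype <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, education = s$education,
               bdi = s$bdi, hamd = s$hamd,
               stringsAsFactors = FALSE)))
}
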