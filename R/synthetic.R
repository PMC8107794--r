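#' Configuration of a synthetic connectome cohort
#'
#' The generator plants the statistical structure that the downstream analysis
#' assumes: sex differences in within-network connectivity whose sign flips
#' with age (male > female before a crossing age, female > male after), an
#' optional common age trend of all edges, motion/quality/volume confounds
#' with configurable sex and age loadings, HCP-like family blocks, and an
#' internalizing score generated as a U-shaped (quadratic) function of the
#' true male-posterior score.
#'
#' The planted male-minus-female Cohen's d on the intra-network edges of
#' network k at age a is
#' \deqn{d_k(a) = baseline_k - slope_k (a - age_{min}),}
#' with `slope_k = baseline_k / (crossing_age - age_min)` by default, so every
#' affected network crosses zero exactly at `crossing_age`. Supplying `slope`
#' fixes a single shared decay rate instead (the crossing then differs across
#' networks).
#'
#' @param n_subjects cohort size.
#' @param sex_ratio fraction of males in (0,1); counts are deterministic
#'   (`round(n * sex_ratio)` males).
#' @param age_range numeric length-2, years; ages are uniform on this range.
#' @param crossing_age year at which the planted sex effects change sign.
#' @param network_effect_profile named numeric vector: baseline Cohen's d
#'   (male minus female, at `age_range[1]`) for the intra-network edges of
#'   each named network; unnamed networks carry no sex effect. `NULL`
#'   (default) plants d = 0.7 / 0.65 / 0.6 on DMN / SN / FPN where those
#'   networks exist in the parcellation.
#' @param slope optional shared decay of d in d-units per year; `NULL`
#'   (default) derives a per-network slope from `crossing_age`.
#' @param parcellation a [parcellation()]; defaults to
#'   `make_parcellation(n_regions)`.
#' @param n_regions used only when `parcellation` is `NULL`.
#' @param fc_mean baseline edge connectivity.
#' @param edge_sd edge noise SD; planted mean differences are `d * edge_sd`
#'   so the standardized effect equals the requested d.
#' @param fc_age_slope common change of every edge mean per year of age
#'   (negative = connectivity declines with age); default 0.
#' @param network_age_slope named numeric vector: additional per-year change
#'   of the intra-network edge means of the named networks (on top of
#'   `fc_age_slope`), emulating network-specific aging such as the
#'   well-replicated decline of default-mode connectivity; default none.
#' @param family_block_sizes integer vector of family sizes summing to
#'   `n_subjects`, or `NULL` for all singletons.
#' @param confound_model list with elements `FD`, `SNR`, `TIV`, each
#'   `c(intercept=, sex=, age=, sd=)`: covariate = intercept + sex*male +
#'   age*(years-mean age) + N(0, sd). Defaults have zero sex/age loadings
#'   ("null" confounds), so adjustment must not change results.
#' @param behavior_model list `(a, c, sigma, base, family_sd)`:
#'   internalizing = base + a*(true_score - c)^2 + family effect + N(0,
#'   sigma^2). `a > 0` with `c` near 0.5 plants the U shape (androgynous
#'   center has the fewest symptoms).
#' @param site_offsets numeric vector of additive edge offsets, one per site
#'   (subjects assigned uniformly); default a single site at offset 0.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 600,
                             sex_ratio = 0.5,
                             age_range = c(17, 78),
                             crossing_age = 50,
                             network_effect_profile = NULL,
                             slope = NULL,
                             parcellation = NULL,
                             n_regions = 30,
                             fc_mean = 0.25,
                             edge_sd = 0.1,
                             fc_age_slope = 0,
                             network_age_slope = NULL,
                             family_block_sizes = NULL,
                             confound_model = NULL,
                             behavior_model = NULL,
                             site_offsets = 0,
                             seed = 1L) {
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0,1]")
  if (length(age_range) != 2L || diff(age_range) < 0)
    stop("age_range must be c(min, max) with min <= max")
  if (is.null(parcellation)) parcellation <- make_parcellation(n_regions)
  if (nrow(parcellation) < 2L) stop("need at least 2 regions")
  nets <- unique(parcellation$network)
  if (is.null(network_effect_profile)) {
    # default planted effects: young-adult-sized d on the association
    # networks the sex-difference literature highlights, when present
    def <- c(DMN = 0.7, SN = 0.65, FPN = 0.6)
    network_effect_profile <- def[names(def) %in% nets]
  }
  if (length(network_effect_profile) &&
      is.null(names(network_effect_profile)))
    stop("network_effect_profile must be named by network")
  bad <- setdiff(names(network_effect_profile), nets)
  if (length(bad))
    stop("network_effect_profile names not in parcellation: ",
         paste(bad, collapse = ", "))
  bad2 <- setdiff(names(network_age_slope), nets)
  if (length(bad2))
    stop("network_age_slope names not in parcellation: ",
         paste(bad2, collapse = ", "))
  if (!is.null(family_block_sizes) &&
      sum(family_block_sizes) != n_subjects)
    stop(sprintf("family_block_sizes sum to %d but n_subjects is %d",
                 sum(family_block_sizes), n_subjects))
  if (is.null(confound_model))
    confound_model <- list(
      FD  = c(intercept = 0.15, sex = 0, age = 0, sd = 0.05),
      SNR = c(intercept = 120,  sex = 0, age = 0, sd = 15),
      TIV = c(intercept = 1.45e6, sex = 0, age = 0, sd = 1.2e5))
  if (is.null(behavior_model))
    behavior_model <- list(a = 25, c = 0.5, sigma = 8, base = 8,
                           family_sd = 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 sex_ratio = sex_ratio,
                 age_range = as.numeric(age_range),
                 crossing_age = crossing_age,
                 network_effect_profile = network_effect_profile,
                 slope = slope,
                 parcellation = parcellation,
                 fc_mean = fc_mean, edge_sd = edge_sd,
                 fc_age_slope = fc_age_slope,
                 network_age_slope = network_age_slope,
                 family_block_sizes = family_block_sizes,
                 confound_model = confound_model,
                 behavior_model = behavior_model,
                 site_offsets = as.numeric(site_offsets),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# per-edge (baseline d, slope) implied by a config; E-vectors
planted_edge_profile <- function(config) {
  ei <- edge_index(config$parcellation)
  base <- numeric(nrow(ei))
  slp <- numeric(nrow(ei))
  prof <- config$network_effect_profile
  for (k in names(prof)) {
    sel <- ei$intra & ei$network_a == k
    base[sel] <- prof[[k]]
    slp[sel] <- if (is.null(config$slope)) {
      denom <- config$crossing_age - config$age_range[1L]
      if (denom <= 0) stop("crossing_age must exceed age_range[1]")
      prof[[k]] / denom
    } else config$slope
  }
  list(baseline = base, slope = slp)
}

#' Planted per-edge effect size at given ages
#'
#' Evaluates the generator's ground-truth Cohen's d profile for every edge at
#' one or more ages.
#' @param cohort a [generate_cohort()] result (or a `synthetic_config`).
#' @param age numeric vector of ages.
#' @return matrix, length(age) x edges, of planted d values.
#' @export
planted_effect <- function(cohort, age) {
  config <- if (inherits(cohort, "synthetic_config")) cohort
            else cohort$config
  pr <- planted_edge_profile(config)
  outer(rep(1, length(age)), pr$baseline) -
    outer(age - config$age_range[1L], pr$slope)
}

#' Generate a synthetic connectome cohort
#'
#' Draws one cohort from a [synthetic_config()]: edge vectors with the
#' planted age-dependent sex effects, phenotypes (sex, age, site, FD, SNR,
#' TIV, family, handedness, internalizing/externalizing and the three
#' internalizing subscales), and a `truth` element carrying the planted
#' per-edge profile, each subject's true male-posterior score, and the
#' behavior coefficients.
#'
#' Edges are generated directly as Gaussian-perturbed edge values (the fast
#' path consumed by all downstream stages); [generate_timeseries()] offers
#' the slower route through ROI time series. The true score is the Bayes
#' posterior of being male given the subject's edge vector and age under the
#' generative model.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort` list: `connectomes`
#'   (a [connectome_dataset()] with phenotypes attached), `phenotypes`,
#'   `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  parc <- config$parcellation
  e <- n_edges(parc)
  set.seed(config$seed)
  n_m <- round(n * config$sex_ratio)
  sex <- sample(rep(c("M", "F"), c(n_m, n - n_m)))
  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  site <- sample(seq_along(config$site_offsets), n, replace = TRUE)
  fam <- if (is.null(config$family_block_sizes)) seq_len(n) else
    rep(seq_along(config$family_block_sizes),
        times = config$family_block_sizes)
  hand <- sample(c("R", "L"), n, replace = TRUE, prob = c(0.9, 0.1))

  pr <- planted_edge_profile(config)
  # planted d per subject x edge, then half-difference in raw units per sex
  d_mat <- planted_effect(config, age)            # n x E
  s <- ifelse(sex == "M", 1, -1)
  edge_slope <- rep(config$fc_age_slope, e)
  if (length(config$network_age_slope)) {
    ei <- edge_index(parc)
    for (k in names(config$network_age_slope))
      edge_slope[ei$intra & ei$network_a == k] <-
        edge_slope[ei$intra & ei$network_a == k] +
        config$network_age_slope[[k]]
  }
  mu_mat <- config$fc_mean +
    outer(age - config$age_range[1L], edge_slope)
  fc <- matrix(stats::rnorm(n * e, sd = config$edge_sd), n, e)
  fc <- fc + mu_mat + 0.5 * s * d_mat * config$edge_sd +
    config$site_offsets[site]
  fc <- pmin(pmax(fc, -0.999), 0.999)
  rownames(fc) <- sprintf("sub%05d", seq_len(n))

  # Bayes posterior of male given edges and age (equal priors, shared
  # covariance): log-odds = sum_e delta_e(a) (x_e - mu_e(a)) / sd^2
  delta <- d_mat * config$edge_sd
  centered <- fc - mu_mat -
    config$site_offsets[site]  # remove known non-sex structure
  logodds <- rowSums(delta * centered) / config$edge_sd^2
  true_score <- stats::plogis(logodds)

  cm <- config$confound_model
  age_c <- age - mean(age)
  male <- as.numeric(sex == "M")
  conf <- sapply(cm, function(p)
    p[["intercept"]] + p[["sex"]] * male + p[["age"]] * age_c +
      stats::rnorm(n, sd = p[["sd"]]))
  colnames(conf) <- names(cm)

  bm <- config$behavior_model
  fam_eff <- if (bm$family_sd > 0) {
    u <- stats::rnorm(length(unique(fam)), sd = bm$family_sd)
    u[match(fam, unique(fam))]
  } else 0
  internal <- bm$base + bm$a * (true_score - bm$c)^2 + fam_eff +
    stats::rnorm(n, sd = bm$sigma)
  external <- 8.6 + stats::rnorm(n, sd = 6.3)
  sub_noise <- bm$sigma / sqrt(3)
  subscale <- function() bm$base / 3 + (bm$a / 3) * (true_score - bm$c)^2 +
    fam_eff / 3 + stats::rnorm(n, sd = sub_noise)
  ph <- data.frame(subject_id = rownames(fc),
                   sex = sex, age = age,
                   site = paste0("site", site),
                   FD = conf[, "FD"], SNR = conf[, "SNR"],
                   TIV = conf[, "TIV"],
                   family_id = paste0("fam", fam),
                   handedness = hand,
                   internalizing = internal,
                   externalizing = external,
                   anxious = subscale(), withdrawn = subscale(),
                   somatic = subscale(),
                   stringsAsFactors = FALSE)

  ds <- connectome_dataset(fc, parc, ph)
  structure(list(connectomes = ds,
                 phenotypes = ph,
                 truth = list(edge_baseline_d = pr$baseline,
                              edge_slope = pr$slope,
                              true_score = stats::setNames(true_score,
                                                           rownames(fc)),
                              behavior = bm),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d M / %d F), ages %.1f-%.1f\n",
              nrow(x$phenotypes), sum(x$phenotypes$sex == "M"),
              sum(x$phenotypes$sex == "F"),
              min(x$phenotypes$age), max(x$phenotypes$age)))
  print(x$connectomes)
  invisible(x)
}

#' Generate ROI time series realizing a cohort's connectomes
#'
#' For each subject, draws a multivariate Gaussian time series whose
#' population correlation matrix equals the subject's planted edge vector
#' (reassembled into a region x region matrix and projected to the nearest
#' positive-definite correlation matrix by eigenvalue clipping when needed).
#' The sample correlation of the series converges to the planted matrix as
#' `n_timepoints` grows.
#'
#' @param cohort a [generate_cohort()] result.
#' @param n_timepoints series length; fewer than `n_regions + 1` is rejected
#'   as under-determined.
#' @param subjects optional subject subset (indices or IDs).
#' @param seed integer seed.
#' @return named list of time x region matrices (a `RoiTimeSeriesSet`).
#' @export
generate_timeseries <- function(cohort, n_timepoints,
                                subjects = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  parc <- cohort$config$parcellation
  r <- nrow(parc)
  if (n_timepoints < r + 1L)
    stop(sprintf(
      "n_timepoints = %d is under-determined for %d regions (need >= %d)",
      n_timepoints, r, r + 1L))
  fc <- cohort$connectomes$fc
  if (!is.null(subjects)) {
    if (is.character(subjects)) subjects <- match(subjects, rownames(fc))
    fc <- fc[subjects, , drop = FALSE]
  }
  set.seed(seed)
  out <- lapply(seq_len(nrow(fc)), function(i) {
    cm <- edge_vector_to_matrix(fc[i, ], r)
    cm <- nearest_pd_correlation(cm)
    ts <- MASS::mvrnorm(n_timepoints, mu = rep(0, r), Sigma = cm)
    colnames(ts) <- parc$region_id
    ts
  })
  names(out) <- rownames(fc)
  out
}

# reassemble an edge vector (row-major upper triangle) into a symmetric
# matrix with unit diagonal
edge_vector_to_matrix <- function(edges, r) {
  m <- diag(r)
  tm <- t(m)
  tm[lower.tri(tm)] <- edges
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# clip eigenvalues to a small floor and rescale to unit diagonal
nearest_pd_correlation <- function(m, eps = 1e-6) {
  es <- eigen(m, symmetric = TRUE)
  if (min(es$values) > eps) return(m)
  v <- pmax(es$values, eps)
  m2 <- es$vectors %*% (v * t(es$vectors))
  d <- sqrt(diag(m2))
  m2 / tcrossprod(d)
}

#' Solve the behavior-model noise SD for a target quadratic partial r
#'
#' Given realized true scores, returns the noise SD `sigma` such that the
#' partial correlation between `score^2` and the generated internalizing
#' score, controlling for the linear term, is approximately `target_r` in
#' expectation: `sigma = a * sd(q) * sqrt(1/r^2 - 1)` where `q` is the
#' residual of `(score - c)^2` on `(1, score)`.
#'
#' @param true_score numeric vector of scores in [0,1].
#' @param a,c quadratic coefficients of the behavior model.
#' @param target_r desired partial correlation magnitude.
#' @return sigma (scalar).
#' @export
behavior_sigma_for_r <- function(true_score, a, c, target_r) {
  q <- stats::resid(stats::lm((true_score - c)^2 ~ true_score))
  a * stats::sd(q) * sqrt(1 / target_r^2 - 1)
}
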