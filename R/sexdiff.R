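#' Cohen's d for a sex difference (male minus female)
#'
#' Standardized mean difference using the classic two-sample pooled-variance
#' form:
#' \deqn{d = (\bar x_M - \bar x_F) / s_p,\qquad
#'       s_p^2 = \frac{(n_M-1) s_M^2 + (n_F-1) s_F^2}{n_M + n_F - 2}.}
#'
#' @param values numeric vector (one feature per subject) or a subjects x
#'   features matrix.
#' @param sex character/factor with levels `"F"`/`"M"`, same length as
#'   subjects.
#' @return scalar d, or named vector of d per feature for matrix input.
#' @export
cohens_d <- function(values, sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("F", "M"))) stop("sex must be coded 'F'/'M'")
  m <- sex == "M"
  if (sum(m) < 2L || sum(!m) < 2L)
    stop("need at least 2 subjects per sex")
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (anyNA(v) || any(!is.finite(v))) stop("values must be finite")
  nm <- sum(m); nf <- sum(!m)
  mm <- colMeans(v[m, , drop = FALSE])
  mf <- colMeans(v[!m, , drop = FALSE])
  vm <- apply(v[m, , drop = FALSE], 2L, stats::var)
  vf <- apply(v[!m, , drop = FALSE], 2L, stats::var)
  sp <- sqrt(((nm - 1) * vm + (nf - 1) * vf) / (nm + nf - 2))
  if (any(sp == 0)) stop("zero pooled SD")
  d <- (mm - mf) / sp
  if (is.matrix(values)) d else unname(d)
}

#' Residualize features on covariates by ordinary least squares
#'
#' Each feature is regressed on an intercept plus the covariate columns
#' (factors/characters expanded to indicator contrasts); the residuals are
#' returned. Residuals are exactly orthogonal to every covariate column.
#'
#' @param features numeric vector or subjects x features matrix.
#' @param covariates data frame (or matrix) of covariates; character and
#'   factor columns are expanded via `model.matrix`.
#' @return object of the same shape as `features`, residualized.
#' @export
residualize <- function(features, covariates) {
  v <- if (is.matrix(features)) features else matrix(features, ncol = 1L)
  x <- build_design(covariates, n = nrow(v))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- colnames(x)[setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  res <- qr.resid(qx, v)
  if (is.matrix(features)) {
    dimnames(res) <- dimnames(features)
    res
  } else as.vector(res)
}

# intercept + expanded covariate design
build_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) &&
                              ncol(covariates) == 0L))
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(covariates, stringsAsFactors = TRUE)
  if (nrow(df) != n) stop("covariates and features disagree on n")
  df[] <- lapply(df, function(col)
    if (is.character(col)) factor(col) else col)
  # single-level factors carry no information beyond the intercept
  keep <- vapply(df, function(col) !is.factor(col) || nlevels(droplevels(col)) > 1L,
                 logical(1L))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0L)
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = df)
}

#' Bootstrap percentile confidence interval for Cohen's d
#'
#' Resamples subjects with replacement within each sex group (preserving
#' group sizes) and reports the 2.5/97.5 percentiles of the resampled d.
#' Degenerate resamples (zero pooled SD) are redrawn and counted.
#'
#' @param values numeric vector, one value per subject.
#' @param sex `"F"`/`"M"` labels.
#' @param n_reps number of bootstrap repetitions (>= 100).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list `d` (point estimate), `ci` (length 2), `n_reps`,
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(values, sex, n_reps = 10000L, seed = 1L,
                         conf = 0.95) {
  if (n_reps < 100L) stop("n_reps must be >= 100")
  sex <- as.character(sex)
  im <- which(sex == "M"); iff <- which(sex == "F")
  d_obs <- cohens_d(values, sex)
  nm <- length(im); nf <- length(iff)
  boot_d <- function(reps) {
    # one column per resample, drawn within each sex stratum
    xm <- matrix(values[sample(im, nm * reps, replace = TRUE)], nm, reps)
    xf <- matrix(values[sample(iff, nf * reps, replace = TRUE)], nf, reps)
    mm <- colMeans(xm); mf <- colMeans(xf)
    vm <- (colSums(xm^2) - nm * mm^2) / (nm - 1)
    vf <- (colSums(xf^2) - nf * mf^2) / (nf - 1)
    sp <- sqrt(((nm - 1) * vm + (nf - 1) * vf) / (nm + nf - 2))
    (mm - mf) / sp
  }
  set.seed(seed)
  ds <- boot_d(n_reps)
  redrawn <- 0L
  while (any(bad <- !is.finite(ds))) {      # zero pooled SD resamples
    redrawn <- redrawn + sum(bad)
    ds[bad] <- boot_d(sum(bad))
  }
  alpha <- (1 - conf) / 2
  list(d = d_obs,
       ci = unname(stats::quantile(ds, c(alpha, 1 - alpha))),
       n_reps = n_reps, n_redrawn = redrawn)
}

#' Effect-size map of sex differences over a feature matrix
#'
#' Computes Cohen's d per feature, raw and (optionally) after residualizing
#' the features on confound covariates.
#'
#' @param features subjects x features matrix (edges, network categories,
#'   nodal degrees, or a one-column gFC).
#' @param sex `"F"`/`"M"` labels.
#' @param covariates optional confound data frame (e.g. FD, SNR, TIV, site).
#' @return data frame with `feature`, `d_raw` and, when covariates are
#'   given, `d_adjusted`.
#' @export
sex_difference_map <- function(features, sex, covariates = NULL) {
  if (!is.matrix(features)) features <- matrix(features, ncol = 1L)
  keep <- !apply(features, 2L, anyNA)
  d_raw <- cohens_d(features[, keep, drop = FALSE], sex)
  out <- data.frame(feature = colnames(features)[keep] %||%
                      as.character(which(keep)),
                    d_raw = unname(d_raw), stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    resid <- residualize(features[, keep, drop = FALSE], covariates)
    out$d_adjusted <- unname(cohens_d(resid, sex))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concordance of effect sizes before and after confound adjustment
#'
#' Pearson correlation across features between the raw and the
#' covariate-adjusted effect sizes, with `df = n_features - 2` (64 for the
#' 66 network categories; 4369 for the 4371 edges of a 94-region atlas).
#'
#' @param d_raw,d_adjusted numeric vectors over the same features.
#' @return list `r`, `df`, `n_features`.
#' @export
confound_concordance <- function(d_raw, d_adjusted) {
  if (length(d_raw) != length(d_adjusted))
    stop("effect-size vectors must cover the same features")
  keep <- stats::complete.cases(d_raw, d_adjusted)
  x <- d_raw[keep]; y <- d_adjusted[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant effect-size vector")
  list(r = stats::cor(x, y), df = length(x) - 2L, n_features = length(x))
}

#' Spline trajectory of gFC with age, per sex
#'
#' Fits a cubic smoothing spline (smoothing selected by generalized
#' cross-validation) of global connectivity against age separately for each
#' sex, and evaluates it on a regular age grid - by default 17 to 78 years in
#' steps of 0.2 (306 points). Grid points outside the observed age range of a
#' sex are masked to `NA` with a warning. When covariates are supplied the
#' fit is repeated on the residualized gFC (grand mean added back).
#'
#' @param age,gfc numeric vectors per subject.
#' @param sex `"F"`/`"M"` labels.
#' @param grid_min,grid_max,grid_step age grid specification (years).
#' @param covariates optional confound data frame for the adjusted variant.
#' @return a `trajectory_fit`: list with `grid`, `fitted` (grid x sex
#'   matrix), and `fitted_adjusted` when covariates were given.
#' @export
fit_trajectory <- function(age, gfc, sex, grid_min = 17, grid_max = 78,
                           grid_step = 0.2, covariates = NULL) {
  sex <- as.character(sex)
  if (min(table(sex)) < 10L) stop("need at least 10 subjects per sex")
  grid <- seq(grid_min, grid_max, by = grid_step)
  fit_one <- function(y) {
    out <- matrix(NA_real_, length(grid), 2L,
                  dimnames = list(NULL, c("F", "M")))
    for (s in c("F", "M")) {
      sel <- sex == s
      sp <- stats::smooth.spline(age[sel], y[sel], cv = FALSE)
      inside <- grid >= min(age[sel]) & grid <= max(age[sel])
      if (!all(inside))
        warning(sprintf(
          "%d grid points outside observed %s age range were masked",
          sum(!inside), s))
      out[inside, s] <- stats::predict(sp, grid[inside])$y
    }
    out
  }
  res <- list(grid = grid, fitted = fit_one(gfc))
  if (!is.null(covariates)) {
    adj <- residualize(gfc, covariates) + mean(gfc)
    res$fitted_adjusted <- fit_one(adj)
  }
  structure(res, class = "trajectory_fit")
}

#' Concordance of two fitted trajectories
#'
#' Pearson correlation over shared grid points (both sexes pooled), with
#' `df = n_points - 2`; 304 for the default 306-point grid when comparing
#' one sex's curve, or reported per sex.
#'
#' @param fit_a,fit_b `trajectory_fit` objects on identical grids. If
#'   `fit_b` is missing and `fit_a` carries a covariate-adjusted variant, the
#'   raw and adjusted curves of `fit_a` are compared.
#' @return list with per-sex `r` and `df`, and pooled `r_overall`.
#' @export
trajectory_concordance <- function(fit_a, fit_b) {
  if (missing(fit_b)) {
    if (is.null(fit_a$fitted_adjusted))
      stop("fit_a has no adjusted variant; supply fit_b")
    fit_b <- structure(list(grid = fit_a$grid,
                            fitted = fit_a$fitted_adjusted),
                       class = "trajectory_fit")
  }
  if (!isTRUE(all.equal(fit_a$grid, fit_b$grid)))
    stop("trajectory grids differ")
  per_sex <- lapply(c(F_ = "F", M_ = "M"), function(s) {
    keep <- stats::complete.cases(fit_a$fitted[, s], fit_b$fitted[, s])
    list(r = stats::cor(fit_a$fitted[keep, s], fit_b$fitted[keep, s]),
         df = sum(keep) - 2L)
  })
  keep <- stats::complete.cases(fit_a$fitted, fit_b$fitted)
  list(F = per_sex$F_, M = per_sex$M_,
       r_overall = stats::cor(as.vector(fit_a$fitted[keep, ]),
                              as.vector(fit_b$fitted[keep, ])))
}
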