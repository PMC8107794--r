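#' Regress a cubic age polynomial out of edge features
#'
#' For every edge, fits ordinary least squares on (1, age, age^2, age^3) and
#' returns the residuals together with the coefficients, so the same
#' residualization can be applied out-of-sample with the training-set
#' coefficients. Ages are centered and scaled (training statistics) before
#' powering to condition the cubic design; this leaves OLS residuals
#' unchanged.
#'
#' @param features subjects x edges matrix.
#' @param age numeric vector of ages (years).
#' @param fit an existing `age_poly_fit` to apply instead of fitting anew
#'   (out-of-sample mode).
#' @return list of class `age_poly_fit`: `residuals` (same shape as
#'   `features`), `coefficients` (4 x edges), `age_center`, `age_scale`.
#' @export
regress_age_poly <- function(features, age, fit = NULL) {
  features <- as.matrix(features)
  if (length(age) != nrow(features))
    stop("age must have one value per subject")
  if (is.null(fit)) {
    if (nrow(features) < 5L) stop("need at least 5 subjects")
    if (stats::sd(age) == 0)
      stop("age is constant: cubic age regression is not identifiable")
    ctr <- mean(age); scl <- stats::sd(age)
    x <- age_poly_design(age, ctr, scl)
    qx <- qr(x)
    if (qx$rank < 4L) stop("age polynomial design is singular")
    cf <- qr.coef(qx, features)
    res <- features - x %*% cf
    structure(list(residuals = res, coefficients = cf,
                   age_center = ctr, age_scale = scl),
              class = "age_poly_fit")
  } else {
    x <- age_poly_design(age, fit$age_center, fit$age_scale)
    res <- features - x %*% fit$coefficients
    structure(list(residuals = res, coefficients = fit$coefficients,
                   age_center = fit$age_center, age_scale = fit$age_scale),
              class = "age_poly_fit")
  }
}

age_poly_design <- function(age, center, scale) {
  z <- (age - center) / scale
  cbind(1, z, z^2, z^3)
}

#' Train a linear soft-margin classifier on residualized edges
#'
#' Fits a linear support vector machine (hinge loss, regularization constant
#' `cost`, default 1 - libsvm's default box constraint) on all edges without
#' feature selection, and extracts the primal weight vector `w` and offset
#' `b` oriented so that the decision value `f(x) = w.x + b` is on average
#' larger for males.
#'
#' @param residual_features subjects x edges matrix (age-residualized).
#' @param sex `"F"`/`"M"` labels.
#' @param cost box-constraint parameter C.
#' @return list `w` (edge-length weights), `b` (scalar), `cost`.
#' @export
train_classifier <- function(residual_features, sex, cost = 1) {
  sex <- factor(as.character(sex), levels = c("F", "M"))
  if (nlevels(droplevels(sex)) < 2L)
    stop("both sexes must be present in the training data")
  fit <- e1071::svm(x = residual_features, y = sex, kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- drop(residual_features %*% w) + b
  if (mean(f[sex == "M"]) < mean(f[sex == "F"])) {
    w <- -w; b <- -b
  }
  list(w = unname(w), b = unname(b), cost = cost)
}

#' Platt sigmoid calibration of decision values
#'
#' Maximum-likelihood fit of the sigmoid posterior
#' \deqn{P(male \mid f) = \frac{1}{1 + \exp(A f + B)}}
#' to the training decision values, using Platt's regularized targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` so that perfectly separated decision
#' values do not drive the likelihood to a degenerate optimum. With
#' male-high decision values the fitted `A` is negative, making the
#' posterior increase monotonically toward the male label.
#'
#' @param decision_values numeric vector `f(x)` per subject.
#' @param labels `"F"`/`"M"` per subject (`"M"` is the positive class).
#' @return list `A`, `B`, `converged`.
#' @export
calibrate_sigmoid <- function(decision_values, labels) {
  labels <- as.character(labels)
  if (!all(c("F", "M") %in% labels))
    stop("both labels must be present for calibration")
  y <- as.numeric(labels == "M")
  np <- sum(y == 1); nn <- sum(y == 0)
  t_i <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  f <- decision_values
  nll <- function(par) {
    p <- 1 / (1 + exp(par[1L] * f + par[2L]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t_i * log(p) + (1 - t_i) * log(1 - p))
  }
  grad <- function(par) {
    eta <- par[1L] * f + par[2L]
    p <- 1 / (1 + exp(eta))          # p = sigma(-eta), dp/deta = -p(1-p)
    d <- t_i - p                      # dnll/deta
    c(sum(d * f), sum(d))
  }
  opt <- stats::optim(c(A = 0, B = log((nn + 1) / (np + 1))), nll, grad,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(A = unname(opt$par[1L]), B = unname(opt$par[2L]),
       converged = opt$convergence == 0)
}

#' Fit the full brain-gender-continuum model
#'
#' One call chaining the three training stages: cubic age residualization of
#' every edge, linear SVM on the residuals, and Platt sigmoid calibration of
#' the training decision values. The returned model scores new subjects via
#' [score_continuum()].
#'
#' @param ds a [connectome_dataset()] with phenotypes carrying `sex` and
#'   `age`, or a subjects x edges matrix (then supply `sex` and `age`).
#' @param sex,age overrides / required for matrix input.
#' @param cost SVM box constraint.
#' @param residualize_age set `FALSE` to skip the age polynomial stage (used
#'   by the age-confounding sensitivity experiment).
#' @param calibration `"train"` (default) fits the sigmoid on the training
#'   decision values — the construct's definition; `"crossfit"` fits it on
#'   out-of-fold decision values from an internal stratified split, which
#'   avoids the score saturation that overfit training decisions produce.
#' @param cal_folds folds for `calibration = "crossfit"`.
#' @return object of class `continuum_model`: `age_fit`, `w`, `b`, `A`,
#'   `B`, `meta` (n per sex, edge count, cost, residualize_age).
#' @export
fit_continuum <- function(ds, sex = NULL, age = NULL, cost = 1,
                          residualize_age = TRUE,
                          calibration = c("train", "crossfit"),
                          cal_folds = 5L) {
  calibration <- match.arg(calibration)
  feat <- if (inherits(ds, "connectome_dataset")) ds$fc else as.matrix(ds)
  if (inherits(ds, "connectome_dataset") && !is.null(ds$phenotypes)) {
    sex <- sex %||% ds$phenotypes$sex
    age <- age %||% ds$phenotypes$age
  }
  if (is.null(sex) || is.null(age)) stop("sex and age are required")
  if (residualize_age) {
    ap <- regress_age_poly(feat, age)
    resid <- ap$residuals
  } else {
    ap <- NULL
    resid <- scale(feat, scale = FALSE)
    attr(resid, "scaled:center") -> ctr
    ap_center <- ctr
  }
  cls <- train_classifier(resid, sex, cost = cost)
  if (calibration == "train") {
    f <- drop(resid %*% cls$w) + cls$b
  } else {
    # out-of-fold decision values: refit the SVM without each fold and
    # score it, so the calibration sees honest (non-overfit) margins
    folds <- integer(length(sex))
    for (s in c("F", "M")) {
      idx <- which(sex == s)
      folds[idx] <- rep_len(seq_len(cal_folds), length(idx))
    }
    f <- numeric(length(sex))
    for (k in seq_len(cal_folds)) {
      tr <- folds != k
      sub <- train_classifier(resid[tr, , drop = FALSE], sex[tr],
                              cost = cost)
      f[!tr] <- drop(resid[!tr, , drop = FALSE] %*% sub$w) + sub$b
    }
  }
  cal <- calibrate_sigmoid(f, sex)
  structure(list(age_fit = if (residualize_age)
                   ap[c("coefficients", "age_center", "age_scale")]
                 else NULL,
                 center = if (!residualize_age) ap_center else NULL,
                 w = cls$w, b = cls$b, A = cal$A, B = cal$B,
                 meta = list(n_male = sum(sex == "M"),
                             n_female = sum(sex == "F"),
                             n_edges = ncol(feat), cost = cost,
                             residualize_age = residualize_age)),
            class = "continuum_model")
}

#' @export
print.continuum_model <- function(x, ...) {
  cat(sprintf(
    "Brain gender continuum model: %d edges, trained on %d M / %d F\n",
    x$meta$n_edges, x$meta$n_male, x$meta$n_female))
  cat(sprintf("  sigmoid A = %.4f, B = %.4f; age residualization: %s\n",
              x$A, x$B, x$meta$residualize_age))
  invisible(x)
}

#' Score subjects on the brain gender continuum
#'
#' Applies the stored age-polynomial coefficients (training-set fit; no
#' leakage from the scored sample), the linear weights, and the calibrated
#' sigmoid. Scores lie in [0,1]; 1 = most likely male. Bands: score < 0.35
#' female-typical, 0.35 <= score <= 0.65 androgynous, score > 0.65
#' male-typical.
#'
#' @param model a [fit_continuum()] model.
#' @param ds a [connectome_dataset()] or subjects x edges matrix with the
#'   model's edge count.
#' @param age ages of the scored subjects (taken from phenotypes when
#'   available).
#' @return data frame `subject_id`, `decision`, `score`, `band`.
#' @export
score_continuum <- function(model, ds, age = NULL) {
  feat <- if (inherits(ds, "connectome_dataset")) ds$fc else as.matrix(ds)
  if (inherits(ds, "connectome_dataset") && !is.null(ds$phenotypes))
    age <- age %||% ds$phenotypes$age
  if (ncol(feat) != model$meta$n_edges)
    stop(sprintf("edge count mismatch: model has %d edges, data has %d",
                 model$meta$n_edges, ncol(feat)))
  if (model$meta$residualize_age) {
    if (is.null(age)) stop("age is required to apply the stored coefficients")
    x <- age_poly_design(age, model$age_fit$age_center,
                         model$age_fit$age_scale)
    resid <- feat - x %*% model$age_fit$coefficients
  } else {
    resid <- sweep(feat, 2L, model$center)
  }
  f <- drop(resid %*% model$w) + model$b
  score <- 1 / (1 + exp(model$A * f + model$B))
  data.frame(subject_id = rownames(feat) %||%
               as.character(seq_along(f)),
             decision = f, score = score,
             band = assign_band(score), stringsAsFactors = FALSE)
}

#' Band assignment on the continuum
#'
#' @param score numeric scores in [0,1].
#' @param lower,upper band thresholds (both boundaries belong to the
#'   androgynous band).
#' @return factor with levels `female-typical`, `androgynous`,
#'   `male-typical`.
#' @export
assign_band <- function(score, lower = 0.35, upper = 0.65) {
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop("scores must lie in [0,1]")
  out <- ifelse(score < lower, "female-typical",
                ifelse(score > upper, "male-typical", "androgynous"))
  factor(out, levels = c("female-typical", "androgynous", "male-typical"))
}

#' Predicted sex from a continuum score
#'
#' Ties at exactly 0.5 are classified male (documented convention).
#' @param score numeric scores in [0,1].
#' @return character `"F"`/`"M"`.
#' @export
predict_sex <- function(score) ifelse(score >= 0.5, "M", "F")

#' Classification accuracy of a model on a dataset
#'
#' @param model a [fit_continuum()] model.
#' @param ds dataset (or matrix) to score.
#' @param sex,age true labels / ages (from phenotypes when available).
#' @return list `accuracy`, `accuracy_male`, `accuracy_female`, `n`.
#' @export
evaluate_accuracy <- function(model, ds, sex = NULL, age = NULL) {
  if (inherits(ds, "connectome_dataset") && !is.null(ds$phenotypes)) {
    sex <- sex %||% ds$phenotypes$sex
    age <- age %||% ds$phenotypes$age
  }
  sc <- score_continuum(model, ds, age)
  pred <- predict_sex(sc$score)
  list(accuracy = mean(pred == sex),
       accuracy_male = mean(pred[sex == "M"] == "M"),
       accuracy_female = mean(pred[sex == "F"] == "F"),
       n = length(pred))
}

#' Stratified k-fold cross-validation of the continuum classifier
#'
#' Folds are stratified by sex; age residualization, SVM training and
#' sigmoid calibration are all refit inside each training fold and applied
#' to the held-out fold with the training-fold coefficients.
#'
#' @param ds a [connectome_dataset()] (phenotypes supply sex/age) or matrix.
#' @param sex,age per-subject labels / ages.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param cost SVM box constraint.
#' @param residualize_age passed to [fit_continuum()].
#' @return list `fold_accuracy` (length k), `mean`, `sd`, `folds`
#'   (assignment vector).
#' @export
crossval <- function(ds, sex = NULL, age = NULL, k = 10L, seed = 1L,
                     cost = 1, residualize_age = TRUE) {
  feat <- if (inherits(ds, "connectome_dataset")) ds$fc else as.matrix(ds)
  if (inherits(ds, "connectome_dataset") && !is.null(ds$phenotypes)) {
    sex <- sex %||% ds$phenotypes$sex
    age <- age %||% ds$phenotypes$age
  }
  if (k < 2L) stop("k must be >= 2")
  sex <- as.character(sex)
  set.seed(seed)
  folds <- integer(length(sex))
  for (s in c("F", "M")) {
    idx <- which(sex == s)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold; te <- !tr
    if (length(unique(sex[te])) < 2L || length(unique(sex[tr])) < 2L)
      stop("a fold lost one sex; decrease k")
    m <- fit_continuum(feat[tr, , drop = FALSE], sex[tr], age[tr],
                       cost = cost, residualize_age = residualize_age)
    evaluate_accuracy(m, feat[te, , drop = FALSE], sex[te],
                      age[te])$accuracy
  }, numeric(1L))
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       folds = folds)
}

#' Test-retest reliability of continuum scores
#'
#' Pairwise Pearson correlations of scores for the same subjects across
#' repeated runs (e.g. the 4 resting-state runs of a session).
#'
#' @param score_sets named list of numeric score vectors; all must share the
#'   same subjects. Vectors may be named by subject ID, in which case they
#'   are aligned to the first set.
#' @return correlation matrix (runs x runs).
#' @export
test_retest <- function(score_sets) {
  if (length(score_sets) < 2L) stop("need at least 2 runs")
  ref <- names(score_sets[[1L]])
  n <- length(score_sets[[1L]])
  mat <- sapply(score_sets, function(s) {
    if (length(s) != n) stop("runs have different subject counts")
    if (!is.null(ref) && !is.null(names(s))) {
      if (!setequal(names(s), ref)) stop("subject IDs differ across runs")
      s <- s[ref]
    }
    s
  })
  stats::cor(mat)
}

#' Rank-based ROC AUC (male as positive class)
#'
#' @param values scores or decision values.
#' @param labels `"F"`/`"M"`.
#' @return scalar AUC.
#' @export
roc_auc <- function(values, labels) {
  y <- as.character(labels) == "M"
  r <- rank(values)
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}
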