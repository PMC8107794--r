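test_that("cubic age regression captures polynomial structure exactly", {
  set.seed(2)
  n <- 80
  age <- runif(n, 20, 70)
  # edge that is an exact cubic in age -> residuals vanish
  feat <- cbind(e1 = 2 + 0.01 * age^3,
                e2 = rnorm(n),
                e3 = 0.5 - 0.002 * age + 1e-4 * age^2)
  ap <- regress_age_poly(feat, age)
  expect_true(max(abs(ap$residuals[, "e1"])) < 1e-8)
  expect_true(max(abs(ap$residuals[, "e3"])) < 1e-8)
  # age-independent edge: residuals track the centered values (the cubic
  # absorbs only O(1/sqrt(n)) of the noise)
  expect_gt(cor(ap$residuals[, "e2"], feat[, "e2"] - mean(feat[, "e2"])),
            0.97)
  expect_error(regress_age_poly(feat, rep(40, n)), "constant")
})

test_that("stored age coefficients apply out of sample without refitting", {
  set.seed(3)
  age_tr <- runif(100, 20, 70); age_te <- runif(30, 20, 70)
  f <- function(a) cbind(1 + 0.02 * a - 3e-4 * a^2, 0.5 - 0.01 * a)
  ap <- regress_age_poly(f(age_tr) + rnorm(200, sd = 1e-3), age_tr)
  out <- regress_age_poly(f(age_te), age_te, fit = ap)
  # the true age structure is removed up to the training noise level
  expect_true(max(abs(out$residuals)) < 0.01)
  expect_identical(out$coefficients, ap$coefficients)
})

test_that("linear classifier finds the separating direction", {
  set.seed(5)
  n <- 100
  x <- matrix(rnorm(n * 5), n, 5)
  sex <- rep(c("F", "M"), each = n / 2)
  x[sex == "M", 3] <- x[sex == "M", 3] + 4   # separation only on edge 3
  cls <- train_classifier(x, sex)
  expect_equal(which.max(abs(cls$w)), 3L)
  f <- drop(x %*% cls$w) + cls$b
  expect_equal(mean((f > 0) == (sex == "M")), 1.0)  # separable toy: 100%
  expect_error(train_classifier(x, rep("M", n)), "both sexes")
})

test_that("classifier weights localize on the planted network", {
  co <- young_cohort(n = 600, d = 1.2, seed = 7)
  m <- fit_continuum(co$connectomes)
  ei <- co$connectomes$edges
  w_dmn <- mean(abs(m$w[ei$category == "DMN"]))
  w_null <- mean(abs(m$w[!ei$network_a %in% "DMN" &
                           !ei$network_b %in% "DMN"]))
  expect_gt(w_dmn, w_null)
})

test_that("Platt calibration has the sigmoid's basic properties", {
  set.seed(8)
  f <- rnorm(200)
  labels <- ifelse(plogis(2 * f) > runif(200), "M", "F")
  cal <- calibrate_sigmoid(f, labels)
  # at A f + B = 0 the posterior is exactly 0.5
  f_mid <- -cal$B / cal$A
  expect_equal(1 / (1 + exp(cal$A * f_mid + cal$B)), 0.5)
  expect_lt(cal$A, 0)  # male-high decision values -> increasing posterior
  # labels independent of f -> near-constant posterior at the base rate
  lab0 <- sample(rep(c("F", "M"), c(120, 80)))
  cal0 <- calibrate_sigmoid(f, lab0)
  p0 <- 1 / (1 + exp(cal0$A * f + cal0$B))
  expect_true(all(abs(p0 - 0.4) < 0.15))
})

test_that("Platt calibration matches a brute-force likelihood grid", {
  set.seed(9)
  f <- rnorm(20)
  labels <- ifelse(f + rnorm(20, sd = 0.8) > 0, "M", "F")
  if (length(unique(labels)) < 2) labels[1:2] <- c("F", "M")
  cal <- calibrate_sigmoid(f, labels)
  y <- as.numeric(labels == "M")
  np <- sum(y); nn <- sum(1 - y)
  t_i <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(a, b) {
    p <- pmin(pmax(1 / (1 + exp(a * f + b)), 1e-12), 1 - 1e-12)
    -sum(t_i * log(p) + (1 - t_i) * log(1 - p))
  }
  # coarse-to-fine grid search, independent of the optimizer
  best <- c(0, 0); rng_a <- seq(-20, 5, 0.5); rng_b <- seq(-5, 5, 0.25)
  for (pass in 1:3) {
    grid <- expand.grid(a = rng_a, b = rng_b)
    vals <- mapply(nll, grid$a, grid$b)
    best <- unlist(grid[which.min(vals), ])
    rng_a <- seq(best[1] - 0.5, best[1] + 0.5, length.out = 41)
    rng_b <- seq(best[2] - 0.25, best[2] + 0.25, length.out = 41)
  }
  expect_lt(abs(cal$A - best[1]), 0.01)
  expect_lt(abs(cal$B - best[2]), 0.01)
})

test_that("perfect separation stays finite via regularized targets", {
  f <- c(-3, -2, -1, 1, 2, 3)
  labels <- c("F", "F", "F", "M", "M", "M")
  cal <- calibrate_sigmoid(f, labels)
  expect_true(is.finite(cal$A) && is.finite(cal$B))
  p <- 1 / (1 + exp(cal$A * f + cal$B))
  expect_true(all(p > 0 & p < 1))
})

test_that("continuum scores behave like calibrated posteriors", {
  co <- young_cohort(n = 300, d = 2, seed = 11)
  m <- fit_continuum(co$connectomes)
  sc <- score_continuum(m, co$connectomes)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # a subject at the decision boundary scores exactly 0.5
  x0 <- co$connectomes$fc[1, , drop = FALSE]
  age0 <- co$phenotypes$age[1]
  z <- age_poly_design(age0, m$age_fit$age_center, m$age_fit$age_scale)
  r0 <- x0 - z %*% m$age_fit$coefficients
  shift <- -(drop(r0 %*% m$w) + m$b) / sum(m$w^2)
  x_bound <- x0 + shift * m$w
  s_bound <- score_continuum(m, x_bound, age = age0)
  expect_equal(s_bound$decision, 0, tolerance = 1e-9)
  expect_equal(s_bound$score, 0.5, tolerance = 1e-9)
  # moving along +w from the boundary strictly increases the score
  # decision shifts sized against the sigmoid slope to avoid saturation
  deltas <- c(0.5, 1, 2) / (abs(m$A) * sum(m$w^2))
  s_up <- sapply(deltas, function(d)
    score_continuum(m, x_bound + d * m$w, age = age0)$score)
  expect_true(all(diff(c(s_bound$score, s_up)) > 0))
})

test_that("band assignment follows the 0.35/0.65 thresholds", {
  expect_equal(as.character(assign_band(c(0, 0.3499, 0.35, 0.5, 0.65,
                                          0.6500001, 1))),
               c("female-typical", "female-typical", "androgynous",
                 "androgynous", "androgynous", "male-typical",
                 "male-typical"))
  expect_error(assign_band(1.2), "0,1")
  expect_equal(predict_sex(c(0.5, 0.4999)), c("M", "F"))
})

test_that("separable cohorts cross-validate near 100%, shuffled near 50%", {
  co <- young_cohort(n = 400, d = 3, seed = 13)
  cv <- crossval(co$connectomes, k = 5, seed = 1)
  expect_gte(cv$mean, 0.98)
  set.seed(2)
  sex_shuf <- sample(co$phenotypes$sex)
  cv0 <- crossval(co$connectomes, sex = sex_shuf,
                  age = co$phenotypes$age, k = 5, seed = 1)
  expect_lt(abs(cv0$mean - 0.5), 0.06)
})

test_that("cross-validation is stratified and deterministic", {
  co <- young_cohort(n = 120, d = 1, seed = 17)
  cv1 <- crossval(co$connectomes, k = 4, seed = 9)
  cv2 <- crossval(co$connectomes, k = 4, seed = 9)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  sex <- co$phenotypes$sex
  for (f in 1:4)
    expect_true(all(table(sex[cv1$folds == f]) >= 1))
})

test_that("AUC from scores equals AUC from decision values", {
  co <- young_cohort(n = 200, d = 1, seed = 19)
  m <- fit_continuum(co$connectomes)
  sc <- score_continuum(m, co$connectomes)
  sex <- co$phenotypes$sex
  expect_equal(roc_auc(sc$score, sex), roc_auc(sc$decision, sex))
  # cross-check the rank AUC against an independent implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    auc_ref <- as.numeric(pROC::auc(pROC::roc(
      response = sex, predictor = sc$score, levels = c("F", "M"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(sc$score, sex), auc_ref, tolerance = 1e-10)
  }
})

test_that("swapping sex labels reflects the score around 0.5", {
  co <- young_cohort(n = 300, d = 1.5, seed = 23)
  ph <- co$phenotypes
  m1 <- fit_continuum(co$connectomes)
  m2 <- fit_continuum(co$connectomes,
                      sex = ifelse(ph$sex == "M", "F", "M"), age = ph$age)
  s1 <- score_continuum(m1, co$connectomes)$score
  s2 <- score_continuum(m2, co$connectomes)$score
  expect_lt(max(abs(s2 - (1 - s1))), 0.05)
})

test_that("test-retest correlations follow the attenuation formula", {
  set.seed(29)
  n <- 400
  truth <- rnorm(n)
  # independent run noise with var ratio 2/3 -> expected r = 0.6
  runs <- lapply(1:4, function(i)
    setNames(truth + rnorm(n, sd = sqrt(2 / 3)),
             sprintf("s%03d", 1:n)))
  rr <- test_retest(runs)
  off <- rr[upper.tri(rr)]
  expect_true(all(off > 0.5 & off < 0.7))
  # identical runs -> r = 1; independent runs -> r ~ 0
  expect_equal(unname(test_retest(list(truth, truth))[1, 2]), 1.0)
  r0 <- test_retest(list(rnorm(n), rnorm(n)))[1, 2]
  expect_lt(abs(r0), 0.1)
  expect_error(test_retest(list(a = setNames(truth, paste0("s", 1:n)),
                                b = setNames(truth, paste0("x", 1:n)))),
               "IDs differ")
})

test_that("edge-count mismatches are rejected at scoring time", {
  co <- young_cohort(n = 60, seed = 31)
  m <- fit_continuum(co$connectomes)
  expect_error(score_continuum(m, co$connectomes$fc[, 1:10],
                               age = co$phenotypes$age),
               "edge count mismatch")
})
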