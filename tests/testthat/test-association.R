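test_that("partial correlation matches the recursive formula", {
  # with one covariate z: r_xy.z = (r_xy - r_xz r_yz) /
  #                                sqrt((1-r_xz^2)(1-r_yz^2))
  set.seed(61)
  x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pc <- partial_corr(x, y, data.frame(z = z))
  expect_equal(pc$r, oracle, tolerance = 1e-10)
  expect_equal(pc$df, 6 - 1 - 2)
  # empty covariate set reduces to plain Pearson
  expect_equal(partial_corr(x, y)$r, cor(x, y), tolerance = 1e-12)
  # y identical to a covariate -> zero residual variance -> error
  expect_error(partial_corr(x, z, data.frame(z = z)), "constant")
})

test_that("quadratic association isolates curvature from linear trend", {
  set.seed(62)
  s <- runif(300)
  # perfect U: quadratic partial r ~ 1
  y_u <- (s - 0.5)^2
  a_u <- quadratic_assoc(s, y_u)
  expect_gt(a_u$r, 0.999)
  expect_equal(a_u$vertex, 0.5, tolerance = 1e-6)
  # linear outcome: the linear covariate absorbs the trend, leaving a
  # quadratic partial r consistent with zero (sampling noise ~ 1/sqrt(n))
  y_lin <- 3 * s + rnorm(300, sd = 0.5)
  expect_lt(abs(quadratic_assoc(s, y_lin)$r), 2.5 / sqrt(300))
})

test_that("U-shape vertex and power behave as planted on synthetic cohorts", {
  co <- generate_cohort(synthetic_config(
    n_subjects = 700, age_range = c(22, 36),
    network_effect_profile = c(DMN = 1.5), slope = 0,
    parcellation = tiny_parc(),
    behavior_model = list(a = 25, c = 0.5, sigma = 8, base = 8,
                          family_sd = 0), seed = 63))
  ph <- co$phenotypes
  a <- quadratic_assoc(co$truth$true_score, ph$internalizing,
                       ph[, c("sex", "age", "handedness", "FD")])
  expect_gt(a$r, 0)
  expect_lt(abs(a$vertex - 0.5), 0.1)
  # power simulation at planted quadratic partial r ~ 0.15
  s0 <- co$truth$true_score
  sigma_r <- behavior_sigma_for_r(s0, a = 25, c = 0.5, target_r = 0.15)
  hits <- 0L
  set.seed(64)
  for (i in 1:200) {
    y <- 8 + 25 * (s0 - 0.5)^2 + rnorm(700, sd = sigma_r)
    if (quadratic_assoc(s0, y)$p_param < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.8)
})

test_that("exchangeability blocks admit exactly the enumerated rearrangements", {
  # two families of size 2: 2 block swaps x 2 x 2 within = 8
  expect_equal(nrow(enumerate_scheme(build_scheme(c("a", "a", "b", "b")))),
               8L)
  # one family of 3 + a singleton: 3! within, no cross-size swap = 6
  expect_equal(nrow(enumerate_scheme(build_scheme(c("f", "f", "f", "x")))),
               6L)
  # all singletons: the full symmetric group
  expect_equal(nrow(enumerate_scheme(build_scheme(1:4))), 24L)
})

test_that("sampled rearrangements are admissible bijections", {
  fam <- c("a", "a", "b", "b", "c", "c", "c", "d", "e")
  scheme <- build_scheme(fam)
  perms <- scheme_permutations(scheme, 50)
  admissible <- enumerate_scheme_keys <- NULL
  for (b in 1:50) {
    p <- perms[, b]
    expect_equal(sort(p), 1:9)                      # bijection
    # block structure: each family maps onto one family of the same size
    for (blk in scheme$blocks) {
      img_fams <- unique(fam[p[blk]])
      expect_length(img_fams, 1L)
      expect_equal(sum(fam == img_fams), length(blk))
    }
  }
  # within-family value sets are preserved under permutation
  y <- rnorm(9)
  p <- perms[, 1]
  expect_setequal(unlist(lapply(scheme$blocks, function(b)
    sort(tapply(y[p], fam, sort)[[fam[b[1]]]]))), sort(y))
})

test_that("permutation p-values hit their exact bounds and are never zero", {
  y <- rnorm(120)
  # statistic blind to order -> p = 1
  expect_equal(perm_test(function(v) 1, y, n_perm = 100, seed = 1)$p, 1.0)
  # observed larger than every permutation can be -> p = 1/(n_perm+1)
  x <- seq_along(y)
  y_mono <- x + rnorm(120, sd = 1e-6)
  pt <- perm_test(function(v) cor(x, v), y_mono, n_perm = 500, seed = 2)
  expect_equal(pt$p, 1 / 501)
  expect_true(pt$p > 0)
})

test_that("failed statistics are redrawn and counted", {
  y <- rnorm(100)
  flaky_env <- new.env(); flaky_env$k <- 0L
  flaky <- function(v) {
    flaky_env$k <- flaky_env$k + 1L
    if (flaky_env$k %% 7 == 0) stop("numerical failure")
    mean(v)
  }
  pt <- perm_test(flaky, y, n_perm = 100, seed = 3)
  expect_gt(pt$n_failed, 0)
  expect_length(pt$null, 100)
})

test_that("BH adjustment matches the hand step-up oracle", {
  # hand-computed: p_(i) * m / i with step-up monotonicity
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(65)
  p <- runif(20)
  m <- length(p)
  o <- order(p)
  stepup <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    stepup[o[i]] <- prev
  }
  expect_equal(fdr_bh(p), stepup, tolerance = 1e-12)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("block permutation test for the quadratic term is calibrated", {
  # null outcome, singleton families: rejection rate at alpha = .05 must
  # sit near .05
  n <- 150
  set.seed(66)
  rejections <- 0L
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    s <- runif(n)
    y <- rnorm(n)
    covs <- data.frame(z = rnorm(n))
    a <- quadratic_assoc(s, y, covs, scheme = build_scheme(seq_len(n)),
                         n_perm = 500, seed = i)
    if (a$p_perm <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_sim, 0.03)
  expect_lte(rejections / n_sim, 0.07)
})

test_that("family effects leave the block-permutation null valid", {
  # families of 3 with strong shared outcome effects: block permutation
  # respects relatedness, so the null quadratic test still holds its level
  set.seed(67)
  n_fam <- 60
  fam <- rep(seq_len(n_fam), each = 3)
  rej <- 0L
  for (i in 1:150) {
    u <- rnorm(n_fam, sd = 2)[fam]
    y <- u + rnorm(length(fam))
    s <- runif(length(fam))
    a <- quadratic_assoc(s, y, scheme = build_scheme(fam),
                         n_perm = 400, seed = i)
    if (a$p_perm <= 0.05) rej <- rej + 1L
  }
  expect_lte(rej / 150, 0.10)
})

test_that("band ANOVA matches the textbook sums-of-squares oracle", {
  set.seed(68)
  v <- c(rnorm(100, -1), rnorm(100, 0), rnorm(100, 1))
  bands <- factor(rep(c("female-typical", "androgynous", "male-typical"),
                      each = 100),
                  levels = c("female-typical", "androgynous",
                             "male-typical"))
  res <- band_anova(v, bands)
  ref <- summary(aov(v ~ bands))[[1]]     # independent implementation
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-6)
  expect_equal(unname(res$df), c(2, 297))
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  # post-hoc: androgynous vs each end, pooled-variance t with BH
  expect_equal(nrow(res$posthoc), 2L)
  expect_equal(res$posthoc$df, c(198, 198))
  expect_true(all(res$posthoc$p_fdr >= res$posthoc$p))
  # identical means -> F near zero expectation, no significant post-hocs
  v0 <- rnorm(300)
  res0 <- band_anova(v0, bands)
  expect_gt(res0$p, 0.01)
})

test_that("bands with too few subjects are dropped with a warning", {
  v <- rnorm(52)
  bands <- factor(c(rep("female-typical", 25), rep("androgynous", 25),
                    rep("male-typical", 2)),
                  levels = c("female-typical", "androgynous",
                             "male-typical"))
  bands[51:52] <- c("male-typical", NA)
  expect_warning(band_anova(v[1:51], bands[1:51]), "excluded")
})

test_that("the full association table carries its FDR families", {
  co <- generate_cohort(synthetic_config(
    n_subjects = 400, age_range = c(22, 36),
    network_effect_profile = c(DMN = 1.5), slope = 0,
    parcellation = tiny_parc(), seed = 69))
  tab <- association_table(co$truth$true_score, co$phenotypes,
                           scheme = build_scheme(co$phenotypes$family_id),
                           n_perm = 200, seed = 1)
  expect_equal(sum(tab$family == "main"), 8L)  # 2 sexes x 2 terms x 2 outcomes
  expect_equal(sum(tab$family == "subscales_male"), 3L)
  expect_true(all(tab$p_fdr >= pmin(tab$p_perm, tab$p), na.rm = TRUE))
  expect_true(all(tab$p_perm > 0, na.rm = TRUE))
  # the planted U shape surfaces as a positive quadratic internalizing term
  qrow <- tab[tab$group == "all" & tab$term == "quadratic" &
                tab$outcome == "internalizing", ]
  expect_gt(qrow$r, 0)
  expect_lt(qrow$p_perm, 0.05)
})
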