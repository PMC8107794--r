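#' Partial Pearson correlation
#'
#' Correlation of the OLS residuals of `x` and `y` on an intercept plus the
#' covariates, with `df = n - n_covariate_columns - 2` (covariate columns
#' counted after factor expansion, excluding the intercept).
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame / matrix of covariates.
#' @return list `r`, `df`, `n`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  design <- build_design(covariates, n)
  p <- ncol(design) - 1L
  if (n <= p + 2L) stop("too few observations for the covariate set")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1))
    stop("residualized variable is (numerically) constant")
  list(r = stats::cor(rx, ry), df = n - p - 2L, n = n)
}

#' U-shape (quadratic) association of the continuum score with an outcome
#'
#' Partial Pearson correlation between the squared score and the outcome,
#' with the linear score term appended to the covariates so the quadratic
#' term captures curvature beyond any linear trend. A positive `r` with the
#' vertex inside (0,1) indicates a U shape (minimum near the vertex). When a
#' permutation scheme is supplied, a two-sided permutation p-value is
#' computed Freedman-Lane style: both sides are residualized on the full
#' covariate set (including the linear term), the outcome residuals are
#' permuted within the admissible block structure, and the correlation is
#' recomputed.
#'
#' @param score continuum scores in [0,1].
#' @param outcome numeric outcome (e.g. internalizing score).
#' @param covariates optional data frame (e.g. sex, age, handedness, FD).
#' @param scheme optional [build_scheme()] permutation scheme.
#' @param n_perm number of permutations (>= 100) when `scheme` is given.
#' @param seed integer seed for the permutations.
#' @return an `association_result` list: `r`, `df`, `n`, `vertex` (score at
#'   the fitted minimum of the quadratic), `p_param` (parametric two-sided
#'   t-based p), and `p_perm` when a scheme was supplied.
#' @export
quadratic_assoc <- function(score, outcome, covariates = NULL,
                            scheme = NULL, n_perm = 10000L, seed = 1L) {
  covars <- if (is.null(covariates))
    data.frame(score_linear = score)
  else cbind(as.data.frame(covariates), score_linear = score)
  pc <- partial_corr(score^2, outcome, covars)
  # vertex of outcome ~ b0 + b1 s + b2 s^2 (+ covariates)
  x <- cbind(build_design(covariates, length(score)),
             s = score, s2 = score^2)
  cf <- stats::lm.fit(x, outcome)$coefficients
  b1 <- cf[["s"]]; b2 <- cf[["s2"]]
  vertex <- if (b2 != 0) -b1 / (2 * b2) else NA_real_
  tval <- pc$r * sqrt(pc$df / (1 - pc$r^2))
  out <- list(r = pc$r, df = pc$df, n = pc$n, vertex = vertex,
              quad_coef = b2,
              p_param = 2 * stats::pt(-abs(tval), pc$df))
  if (!is.null(scheme)) {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    rx <- residualize(score^2, covars)
    ry <- residualize(outcome, covars)
    xs <- (rx - mean(rx)) / stats::sd(rx)
    ys <- (ry - mean(ry)) / stats::sd(ry)
    set.seed(seed)
    perm_idx <- scheme_permutations(scheme, n_perm)
    # a permutation of ys keeps its mean/sd, so correlation reduces to a
    # cross product; all permutations in one matrix multiply
    r_obs <- sum(xs * ys) / (pc$n - 1)
    r_null <- drop(crossprod(matrix(ys[perm_idx], nrow = pc$n),
                             xs)) / (pc$n - 1)
    out$p_perm <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
    out$n_perm <- n_perm
  }
  structure(out, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Quadratic association: r = %.4f (df = %d, n = %d)\n",
              x$r, x$df, x$n))
  cat(sprintf("  vertex at score = %.4f; parametric p = %.4g%s\n",
              x$vertex, x$p_param,
              if (!is.null(x$p_perm))
                sprintf("; p.perm = %.4g (%d permutations)",
                        x$p_perm, x$n_perm) else ""))
  invisible(x)
}

#' Exchangeability-block permutation scheme from family IDs
#'
#' Families form exchangeability blocks. Admissible rearrangements are the
#' compositions of (i) permutations of whole blocks among blocks of
#' identical size and (ii) permutations of subjects within each block -- the
#' standard multilevel block-permutation rule, which preserves the family
#' covariance structure under the null.
#'
#' @param family_ids vector of family identifiers, one per subject
#'   (singletons allowed).
#' @return a `permutation_scheme`: list `blocks` (list of index vectors),
#'   `sizes`, `n`.
#' @export
build_scheme <- function(family_ids) {
  if (anyNA(family_ids)) stop("every subject needs a family ID")
  fam <- as.character(family_ids)
  blocks <- split(seq_along(fam), fam)
  blocks <- blocks[order(match(names(blocks), fam))]  # first-appearance order
  structure(list(blocks = unname(blocks),
                 sizes = lengths(unname(blocks)),
                 n = length(fam)),
            class = "permutation_scheme")
}

#' @export
print.permutation_scheme <- function(x, ...) {
  cat(sprintf(
    "Permutation scheme: %d subjects in %d blocks (sizes: %s)\n",
    x$n, length(x$blocks),
    paste(names(table(x$sizes)), "x", table(x$sizes), collapse = ", ")))
  invisible(x)
}

#' Draw admissible rearrangements from a permutation scheme
#'
#' Each column of the returned matrix is one admissible permutation of
#' `1:n`: block positions are shuffled within each size class and subjects
#' are shuffled within each block.
#'
#' @param scheme a [build_scheme()] scheme.
#' @param n_perm number of rearrangements to draw.
#' @return integer matrix, n x n_perm.
#' @export
scheme_permutations <- function(scheme, n_perm) {
  n <- scheme$n
  blocks <- scheme$blocks
  sizes <- scheme$sizes
  if (all(sizes == 1L)) {        # unrelated sample: unrestricted shuffles
    pos <- unlist(blocks)
    out <- matrix(0L, n, n_perm)
    for (b in seq_len(n_perm)) out[pos, b] <- sample(pos)
    return(out)
  }
  size_class <- split(seq_along(blocks), sizes)
  out <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) {
    perm <- integer(n)
    for (cls in size_class) {
      s <- length(blocks[[cls[1L]]])
      target <- if (length(cls) > 1L) sample(cls) else cls
      if (s == 1L) {
        perm[unlist(blocks[cls])] <- unlist(blocks[target])
      } else {
        for (j in seq_along(cls)) {
          dst <- blocks[[target[j]]]
          perm[blocks[[cls[j]]]] <- sample(dst)
        }
      }
    }
    out[, b] <- perm
  }
  out
}

#' Exhaustively enumerate a scheme's admissible rearrangements
#'
#' Brute-force filter of all n! permutations (tiny n only): a permutation is
#' admissible iff it maps every block onto a block of the same size. Used to
#' validate the sampler; e.g. two families of size 2 admit 8 rearrangements
#' and a size-3 family plus a singleton admit 6.
#'
#' @param scheme a [build_scheme()] scheme with `n <= 8`.
#' @return integer matrix, one admissible permutation per row.
#' @export
enumerate_scheme <- function(scheme) {
  n <- scheme$n
  if (n > 8L) stop("exhaustive enumeration is limited to n <= 8")
  block_of <- integer(n)
  for (i in seq_along(scheme$blocks)) block_of[scheme$blocks[[i]]] <- i
  perms <- all_permutations(n)
  ok <- apply(perms, 1L, function(p) {
    for (blk in scheme$blocks) {
      img <- block_of[p[blk]]
      if (length(unique(img)) != 1L) return(FALSE)
      if (length(scheme$blocks[[img[1L]]]) != length(blk)) return(FALSE)
    }
    TRUE
  })
  perms[ok, , drop = FALSE]
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Generic permutation test under an exchangeability scheme
#'
#' Recomputes `statistic_fn` on scheme-admissible permutations of `y` and
#' returns the two-sided p-value `(1 + #\{|t*| >= |t_obs|\}) / (n_perm + 1)`
#' (never zero). Permutations on which the statistic fails are logged,
#' dropped and redrawn.
#'
#' @param statistic_fn function of a permuted `y` returning a scalar.
#' @param y outcome vector to permute.
#' @param scheme a [build_scheme()] scheme (defaults to all-singleton,
#'   i.e. unrestricted permutation).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (absolute value) or `"greater"`.
#' @return list `p`, `observed`, `null` (vector), `n_failed`.
#' @export
perm_test <- function(statistic_fn, y, scheme = NULL, n_perm = 1000L,
                      seed = 1L, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.null(scheme)) scheme <- build_scheme(seq_along(y))
  if (scheme$n != length(y)) stop("scheme and y disagree on n")
  obs <- statistic_fn(y)
  set.seed(seed)
  null <- numeric(n_perm)
  failed <- 0L
  b <- 1L
  while (b <= n_perm) {
    idx <- scheme_permutations(scheme, 1L)[, 1L]
    val <- tryCatch(statistic_fn(y[idx]), error = function(e) NA_real_)
    if (is.na(val)) {
      failed <- failed + 1L
      if (failed > 10L * n_perm) stop("statistic failed on most permutations")
      next
    }
    null[b] <- val
    b <- b + 1L
  }
  p <- if (alternative == "two.sided")
    (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  else (1 + sum(null >= obs)) / (n_perm + 1)
  list(p = p, observed = obs, null = null, n_failed = failed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1 (delegates to
#' `stats::p.adjust`). Inputs outside (0, 1] are rejected.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' One-way ANOVA of network connectivity across continuum bands
#'
#' Compares a network-level connectivity value across the three continuum
#' bands: one-way F (between/within mean squares), then post-hoc pooled-
#' variance two-sample t-tests of the androgynous band against each extreme
#' band, BH-adjusted. Bands with fewer than 2 subjects are excluded with a
#' warning.
#'
#' @param values numeric vector (e.g. a subject's DMN mean connectivity).
#' @param bands factor from [assign_band()].
#' @return a `band_comparison` list: `F`, `df` (c(between, within)), `p`,
#'   `group_n`, `group_means`, `posthoc` (data frame with t, df, p, p_fdr).
#' @export
band_anova <- function(values, bands) {
  bands <- factor(bands)
  keep_lv <- names(which(table(bands) >= 2L))
  if (length(keep_lv) < length(levels(bands)))
    warning("band(s) with fewer than 2 subjects excluded: ",
            paste(setdiff(levels(bands), keep_lv), collapse = ", "))
  if (length(keep_lv) < 2L) stop("need at least 2 non-empty bands")
  sel <- bands %in% keep_lv
  v <- values[sel]; g <- droplevels(bands[sel])
  n <- length(v); k <- nlevels(g)
  gm <- tapply(v, g, mean); gn <- tapply(v, g, length)
  ss_between <- sum(gn * (gm - mean(v))^2)
  ss_within <- sum((v - gm[g])^2)
  fstat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  pval <- stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  mid <- "androgynous"
  ends <- setdiff(levels(g), mid)
  posthoc <- NULL
  if (mid %in% levels(g) && length(ends)) {
    rows <- lapply(ends, function(e) {
      a <- v[g == mid]; b <- v[g == e]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(comparison = paste(mid, "vs", e),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, rows)
    posthoc$p_fdr <- fdr_bh(posthoc$p)
  }
  structure(list(F = fstat, df = c(between = k - 1, within = n - k),
                 p = pval,
                 group_n = gn, group_means = gm, posthoc = posthoc),
            class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf("Band comparison: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc (pooled-variance t, BH-adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Full U-shape association table with FDR families
#'
#' Runs the quadratic (and linear) association of the continuum score with
#' internalizing and externalizing outcomes in all subjects and within each
#' sex, then BH-adjusts within the family enumerated by the design: 2 sex
#' groups x linear/quadratic x internalizing/externalizing. Subscale results
#' (anxious, withdrawn, somatic) form their own 3-test family per sex.
#'
#' @param score continuum scores.
#' @param phenotypes data frame with `sex`, `age`, `handedness`, `FD`,
#'   `internalizing`, `externalizing` and optionally the subscale columns.
#' @param scheme optional [build_scheme()] scheme for permutation p-values.
#' @param n_perm permutations per test when `scheme` is given.
#' @param seed integer seed.
#' @return data frame with `group`, `outcome`, `term`, `r`, `df`, `p`
#'   (parametric), `p_perm` (if permuted), `p_fdr`, `family`.
#' @export
association_table <- function(score, phenotypes, scheme = NULL,
                              n_perm = 2000L, seed = 1L) {
  run_one <- function(sel, outcome_col, term, covars, grp) {
    s <- score[sel]; yy <- phenotypes[[outcome_col]][sel]
    cv <- covars[sel, , drop = FALSE]
    sch <- if (!is.null(scheme))
      build_scheme(phenotypes$family_id[sel]) else NULL
    if (term == "quadratic") {
      a <- quadratic_assoc(s, yy, cv, scheme = sch, n_perm = n_perm,
                           seed = seed)
      data.frame(group = grp, outcome = outcome_col, term = term,
                 r = a$r, df = a$df, p = a$p_param,
                 p_perm = a$p_perm %||% NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      pc <- partial_corr(s, yy, cv)
      tv <- pc$r * sqrt(pc$df / (1 - pc$r^2))
      pp <- if (!is.null(sch)) {
        rx <- residualize(s, cv); ry <- residualize(yy, cv)
        xs <- (rx - mean(rx)) / stats::sd(rx)
        ys <- (ry - mean(ry)) / stats::sd(ry)
        set.seed(seed)
        pi_ <- scheme_permutations(sch, n_perm)
        rn <- drop(crossprod(matrix(ys[pi_], nrow = pc$n), xs)) / (pc$n - 1)
        (1 + sum(abs(rn) >= abs(pc$r))) / (n_perm + 1)
      } else NA_real_
      data.frame(group = grp, outcome = outcome_col, term = term,
                 r = pc$r, df = pc$df,
                 p = 2 * stats::pt(-abs(tv), pc$df), p_perm = pp,
                 stringsAsFactors = FALSE)
    }
  }
  base_cov <- phenotypes[, c("age", "handedness", "FD")]
  rows <- list()
  for (grp in c("male", "female")) {
    sel <- phenotypes$sex == ifelse(grp == "male", "M", "F")
    for (outc in c("internalizing", "externalizing"))
      for (term in c("linear", "quadratic"))
        rows[[length(rows) + 1L]] <-
          cbind(run_one(sel, outc, term, base_cov, grp), family = "main")
  }
  cov_all <- cbind(base_cov, sex = phenotypes$sex)
  for (outc in c("internalizing", "externalizing"))
    for (term in c("linear", "quadratic"))
      rows[[length(rows) + 1L]] <-
        cbind(run_one(rep(TRUE, nrow(phenotypes)), outc, term, cov_all,
                      "all"), family = "all")
  sub_cols <- intersect(c("anxious", "withdrawn", "somatic"),
                        names(phenotypes))
  for (grp in c("male", "female"))
    for (outc in sub_cols) {
      sel <- phenotypes$sex == ifelse(grp == "male", "M", "F")
      rows[[length(rows) + 1L]] <-
        cbind(run_one(sel, outc, "quadratic", base_cov, grp),
              family = paste0("subscales_", grp))
    }
  out <- do.call(rbind, rows)
  raw <- ifelse(is.na(out$p_perm), out$p, out$p_perm)
  out$p_fdr <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_fdr[sel] <- fdr_bh(raw[sel])
  }
  out
}
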