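#' Test accuracy as a function of training sample size
#'
#' For each requested size, repeatedly draws a sex-balanced training subset
#' from the pool, fits the full continuum model (age residualization + SVM +
#' calibration) and evaluates accuracy on the fixed independent test set.
#'
#' @param train_pool a [connectome_dataset()] with phenotypes (the pool to
#'   draw training subsets from).
#' @param test_set a [connectome_dataset()] with phenotypes.
#' @param sizes integer vector of training sizes (each split evenly by sex).
#' @param n_repeats repeats per size.
#' @param seed integer seed.
#' @param cost SVM box constraint.
#' @return a `sensitivity_report` data frame: `size`, `mean_accuracy`,
#'   `sd_accuracy`, plus attribute `accuracy` (sizes x repeats matrix).
#' @export
sample_size_curve <- function(train_pool, test_set, sizes,
                              n_repeats = 20L, seed = 1L, cost = 1) {
  ph <- train_pool$phenotypes
  im <- which(ph$sex == "M"); iff <- which(ph$sex == "F")
  if (any(sizes > nrow(ph)))
    stop("requested size exceeds the training pool")
  if (any(ceiling(sizes / 2) > min(length(im), length(iff))))
    stop("pool too small for a sex-balanced draw at the largest size")
  set.seed(seed)
  acc <- matrix(NA_real_, length(sizes), n_repeats)
  for (i in seq_along(sizes)) {
    half <- sizes[i] %/% 2L
    for (rpt in seq_len(n_repeats)) {
      idx <- c(sample(im, half), sample(iff, sizes[i] - half))
      tr <- subset_subjects(train_pool, idx)
      m <- fit_continuum(tr, cost = cost)
      acc[i, rpt] <- evaluate_accuracy(m, test_set)$accuracy
    }
  }
  structure(data.frame(size = sizes,
                       mean_accuracy = rowMeans(acc),
                       sd_accuracy = apply(acc, 1L, stats::sd)),
            accuracy = acc, experiment = "sample_size",
            class = c("sensitivity_report", "data.frame"))
}

#' Test accuracy as a function of elderly percentage in training
#'
#' Holds the training size fixed and varies the fraction of subjects older
#' than `elderly_cutoff`; reports per-level mean accuracy and the Pearson
#' correlation between percentage and accuracy (df = levels - 2).
#'
#' @param train_pool,test_set [connectome_dataset()]s with phenotypes.
#' @param percentages numeric vector in [0,1].
#' @param fixed_n total training size per cell.
#' @param elderly_cutoff years (default 65: "elderly" = older than this).
#' @param n_repeats repeats per percentage.
#' @param seed integer seed.
#' @param cost SVM box constraint.
#' @return a `sensitivity_report` data frame with `percentage`,
#'   `mean_accuracy`, `sd_accuracy`; attributes `trend_r`, `trend_df`,
#'   `accuracy`.
#' @export
age_composition_experiment <- function(train_pool, test_set, percentages,
                                       fixed_n = 3000L, elderly_cutoff = 65,
                                       n_repeats = 20L, seed = 1L,
                                       cost = 1) {
  ph <- train_pool$phenotypes
  old <- which(ph$age > elderly_cutoff)
  yng <- which(ph$age <= elderly_cutoff)
  n_old <- round(percentages * fixed_n)
  if (any(n_old > length(old)) || any(fixed_n - n_old > length(yng)))
    stop("pool cannot supply the requested old/young stratum counts")
  set.seed(seed)
  acc <- matrix(NA_real_, length(percentages), n_repeats)
  for (i in seq_along(percentages)) {
    for (rpt in seq_len(n_repeats)) {
      idx <- c(sample(old, n_old[i]), sample(yng, fixed_n - n_old[i]))
      m <- fit_continuum(subset_subjects(train_pool, idx), cost = cost)
      acc[i, rpt] <- evaluate_accuracy(m, test_set)$accuracy
    }
  }
  mean_acc <- rowMeans(acc)
  trend <- stats::cor(percentages, mean_acc)
  structure(data.frame(percentage = percentages,
                       mean_accuracy = mean_acc,
                       sd_accuracy = apply(acc, 1L, stats::sd)),
            trend_r = trend, trend_df = length(percentages) - 2L,
            accuracy = acc, experiment = "age_composition",
            class = c("sensitivity_report", "data.frame"))
}

#' Remove one network's regions (and all their edges) from a dataset
#'
#' Ablation removes every region of the named network and every edge
#' touching any of those regions, leaving `(R-k)(R-k-1)/2` edges.
#'
#' @param ds a [connectome_dataset()].
#' @param network network label present in the parcellation.
#' @return a reduced [connectome_dataset()].
#' @export
drop_network <- function(ds, network) {
  parc <- ds$parcellation
  if (!network %in% parc$network)
    stop(sprintf("network '%s' not in parcellation", network))
  keep_regions <- parc$region_id[parc$network != network]
  if (length(keep_regions) < 2L)
    stop("ablation would leave fewer than 2 regions")
  sub_parc <- parcellation(keep_regions,
                           parc$network[parc$network != network],
                           parc$region_name[parc$network != network],
                           atlas = attr(parc, "atlas"))
  keep_edges <- ds$edges$region_a %in% keep_regions &
    ds$edges$region_b %in% keep_regions
  connectome_dataset(ds$fc[, keep_edges, drop = FALSE], sub_parc,
                     ds$phenotypes)
}

#' Network-ablation experiment
#'
#' Retrains the continuum model with one network's edges removed and
#' compares test accuracy against the full model, over repeated balanced
#' training draws; the accuracy change gets a percentile bootstrap CI over
#' the repeat-level differences.
#'
#' @param train_pool,test_set [connectome_dataset()]s with phenotypes.
#' @param network network label to ablate.
#' @param train_n training size per repeat (balanced by sex).
#' @param n_repeats repeats.
#' @param seed integer seed.
#' @param n_boot bootstrap resamples for the CI of the mean change.
#' @param cost SVM box constraint.
#' @return list `network`, `acc_full`, `acc_ablated` (per-repeat vectors),
#'   `delta` (mean change, ablated minus full), `ci` (95% bootstrap),
#'   `n_edges_full`, `n_edges_ablated`.
#' @export
ablate_network <- function(train_pool, test_set, network,
                           train_n = 1000L, n_repeats = 20L, seed = 1L,
                           n_boot = 2000L, cost = 1) {
  tr_red <- drop_network(train_pool, network)
  te_red <- drop_network(test_set, network)
  ph <- train_pool$phenotypes
  im <- which(ph$sex == "M"); iff <- which(ph$sex == "F")
  half <- train_n %/% 2L
  set.seed(seed)
  acc_full <- acc_abl <- numeric(n_repeats)
  for (rpt in seq_len(n_repeats)) {
    idx <- c(sample(im, half), sample(iff, train_n - half))
    m_full <- fit_continuum(subset_subjects(train_pool, idx), cost = cost)
    m_abl <- fit_continuum(subset_subjects(tr_red, idx), cost = cost)
    acc_full[rpt] <- evaluate_accuracy(m_full, test_set)$accuracy
    acc_abl[rpt] <- evaluate_accuracy(m_abl, te_red)$accuracy
  }
  diffs <- acc_abl - acc_full
  boot <- replicate(n_boot, mean(sample(diffs, replace = TRUE)))
  list(network = network,
       acc_full = acc_full, acc_ablated = acc_abl,
       delta = mean(diffs),
       ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       n_edges_full = ncol(train_pool$fc),
       n_edges_ablated = ncol(tr_red$fc))
}

#' Enrichment of top-|weight| edges in network categories
#'
#' Selects the `top_fraction` of edges with the largest absolute model
#' weights, counts how many fall into each network connection category, and
#' compares each count against a null built by permuting the edge-to-
#' category assignment. One-sided p per category:
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param model a [fit_continuum()] model.
#' @param parcellation the [parcellation()] the model was trained on.
#' @param top_fraction fraction of edges to select (default 0.05).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @return data frame `category`, `n_edges` (category size), `observed`
#'   (top-weight edges in category), `expected` (null mean), `p`.
#' @export
weight_enrichment <- function(model, parcellation, top_fraction = 0.05,
                              n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("need at least 100 permutations")
  ei <- edge_index(parcellation)
  if (nrow(ei) != length(model$w))
    stop("parcellation does not match the model's edge count")
  n_top <- floor(top_fraction * length(model$w))
  if (n_top < 1L) stop("top_fraction selects no edges")
  set.seed(seed)
  # random tie-breaking so exactly n_top edges are selected without bias
  top <- rank(-abs(model$w), ties.method = "random") <= n_top
  cats <- network_categories(parcellation)
  obs <- vapply(cats, function(cc) sum(top & ei$category == cc), integer(1L))
  null_counts <- matrix(0L, n_perm, length(cats))
  for (b in seq_len(n_perm)) {
    perm_cat <- sample(ei$category)
    null_counts[b, ] <- vapply(cats, function(cc)
      sum(top & perm_cat == cc), integer(1L))
  }
  p <- (1 + colSums(sweep(null_counts, 2L, obs, ">="))) / (n_perm + 1)
  data.frame(category = cats,
             n_edges = as.integer(table(factor(ei$category,
                                               levels = cats))),
             observed = as.integer(obs),
             expected = colMeans(null_counts),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Concordance of continuum scores across two parcellations
#'
#' @param scores_a,scores_b numeric score vectors for the same subjects
#'   (aligned by names when present).
#' @return list `r`, `df`, `n`.
#' @export
atlas_concordance <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors have different lengths")
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    if (!setequal(names(scores_a), names(scores_b)))
      stop("subject IDs differ between score sets")
    scores_b <- scores_b[names(scores_a)]
  }
  list(r = stats::cor(scores_a, scores_b),
       df = length(scores_a) - 2L, n = length(scores_a))
}
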