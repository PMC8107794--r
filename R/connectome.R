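#' Connectome datasets
#'
#' A `connectome_dataset` holds one edge vector of functional connectivity per
#' subject (subjects x edges matrix), the canonical edge index of its
#' parcellation, and (optionally) linked subject phenotypes. Edges follow the
#' row-major upper-triangle order defined by [edge_index()]; values are signed
#' and kept as-is (no absolute value, no thresholding, no Fisher transform by
#' default).
#'
#' @param fc numeric matrix, subjects x edges; rownames are subject IDs.
#' @param parcellation a [parcellation()] with `R` regions such that
#'   `ncol(fc) == R*(R-1)/2`.
#' @param phenotypes optional data frame with a `subject_id` column matching
#'   `rownames(fc)`.
#' @return a `connectome_dataset` object.
#' @export
connectome_dataset <- function(fc, parcellation, phenotypes = NULL) {
  fc <- as.matrix(fc)
  if (!is.numeric(fc)) stop("fc must be numeric")
  e <- n_edges(parcellation)
  if (ncol(fc) != e)
    stop(sprintf("fc has %d columns but parcellation implies %d edges",
                 ncol(fc), e))
  if (is.null(rownames(fc)))
    rownames(fc) <- sprintf("sub%05d", seq_len(nrow(fc)))
  ei <- edge_index(parcellation)
  colnames(fc) <- paste(ei$region_a, ei$region_b, sep = "--")
  if (!is.null(phenotypes)) {
    if (!"subject_id" %in% names(phenotypes))
      stop("phenotypes must have a subject_id column")
    if (!setequal(phenotypes$subject_id, rownames(fc)))
      stop("phenotype subject IDs do not match connectome subjects")
    phenotypes <- phenotypes[match(rownames(fc), phenotypes$subject_id), ,
                             drop = FALSE]
    rownames(phenotypes) <- NULL
  }
  structure(list(fc = fc, edges = ei, parcellation = parcellation,
                 phenotypes = phenotypes),
            class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat(sprintf(
    "Connectome dataset: %d subjects x %d edges (%d regions, atlas '%s')\n",
    nrow(x$fc), ncol(x$fc), nrow(x$parcellation),
    attr(x$parcellation, "atlas")))
  if (!is.null(x$phenotypes))
    cat(sprintf("  phenotypes: %s\n",
                paste(names(x$phenotypes), collapse = ", ")))
  invisible(x)
}

#' @export
dim.connectome_dataset <- function(x) dim(x$fc)

#' Subset a connectome dataset by subjects
#'
#' @param ds a [connectome_dataset()].
#' @param subjects integer/logical index or character subject IDs.
#' @return a [connectome_dataset()] restricted to those subjects.
#' @export
subset_subjects <- function(ds, subjects) {
  if (is.character(subjects))
    subjects <- match(subjects, rownames(ds$fc))
  fc <- ds$fc[subjects, , drop = FALSE]
  ph <- if (!is.null(ds$phenotypes))
    ds$phenotypes[subjects, , drop = FALSE] else NULL
  if (!is.null(ph)) rownames(ph) <- NULL
  structure(list(fc = fc, edges = ds$edges,
                 parcellation = ds$parcellation, phenotypes = ph),
            class = "connectome_dataset")
}

#' Functional connectivity from ROI time series
#'
#' Computes the Pearson correlation between every pair of region time series
#' for each subject, yielding the subjects x edges matrix in canonical edge
#' order.
#'
#' @param ts a list of time x region matrices (one per subject, shared region
#'   columns in parcellation order), or a single such matrix. Optionally named
#'   by subject ID.
#' @param parcellation a [parcellation()]; region count must match the number
#'   of columns.
#' @param phenotypes optional phenotype table passed to
#'   [connectome_dataset()].
#' @return a [connectome_dataset()].
#' @export
compute_fc <- function(ts, parcellation, phenotypes = NULL) {
  if (is.matrix(ts)) ts <- list(ts)
  r <- nrow(parcellation)
  rows <- lapply(seq_along(ts), function(i) {
    m <- as.matrix(ts[[i]])
    if (ncol(m) != r)
      stop(sprintf("subject %d has %d regions, parcellation has %d",
                   i, ncol(m), r))
    if (nrow(m) < 3L) stop("need at least 3 timepoints")
    if (anyNA(m)) stop(sprintf("NA in time series of subject %d", i))
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0))
      stop(sprintf("zero-variance time series in subject %d, region(s): %s",
                   i, paste(parcellation$region_id[sds == 0],
                            collapse = ", ")))
    cm <- stats::cor(m)
    # row-major upper triangle == column-major lower triangle of transpose
    t(cm)[lower.tri(cm)]
  })
  fc <- do.call(rbind, rows)
  rownames(fc) <- if (!is.null(names(ts))) names(ts) else
    sprintf("sub%05d", seq_along(ts))
  connectome_dataset(fc, parcellation, phenotypes)
}

#' Network-level aggregation of edge connectivity
#'
#' Averages edges within each network connection category: for each of the K
#' networks the mean over all intra-network edges, and for each unordered pair
#' of networks the mean over all edges linking them - K + K*(K-1)/2
#' categories per subject (66 for 11 networks). A category with no edges
#' (e.g. a single-region network has no intra edges) is reported as `NA`.
#'
#' @param ds a [connectome_dataset()].
#' @return numeric matrix, subjects x categories, columns ordered as
#'   [network_categories()].
#' @export
network_aggregate <- function(ds) {
  cats <- network_categories(ds$parcellation)
  memb <- outer(ds$edges$category, cats, "==")
  counts <- colSums(memb)
  sums <- ds$fc %*% memb
  out <- sweep(sums, 2L, counts, "/")   # 0/0 -> NaN for empty categories
  out[, counts == 0] <- NA_real_
  colnames(out) <- cats
  out
}

#' Global functional connectivity (gFC)
#'
#' The arithmetic mean of all edges of a subject's connectome.
#' @param ds a [connectome_dataset()].
#' @return named numeric vector, one value per subject.
#' @export
global_fc <- function(ds) {
  if (ncol(ds$fc) == 0L) stop("dataset has no edges")
  rowMeans(ds$fc)
}

#' Nodal weighted degree
#'
#' For each region, the mean of its R-1 incident edge values. Under
#' `sign_mode = "positive_only"` (resp. `"negative_only"`) the mean is
#' restricted to incident edges with positive (negative) values; if a region
#' has none of that sign the value is `NA`.
#'
#' @param ds a [connectome_dataset()].
#' @param sign_mode one of `"all"`, `"positive_only"`, `"negative_only"`.
#' @return numeric matrix, subjects x regions.
#' @export
nodal_degree <- function(ds,
                         sign_mode = c("all", "positive_only",
                                       "negative_only")) {
  sign_mode <- match.arg(sign_mode)
  parc <- ds$parcellation
  r <- nrow(parc)
  inc <- matrix(0, nrow = ncol(ds$fc), ncol = r,
                dimnames = list(NULL, parc$region_id))
  ia <- match(ds$edges$region_a, parc$region_id)
  ib <- match(ds$edges$region_b, parc$region_id)
  inc[cbind(seq_len(nrow(inc)), ia)] <- 1
  inc[cbind(seq_len(nrow(inc)), ib)] <- 1
  if (sign_mode == "all") {
    deg <- (ds$fc %*% inc) / (r - 1)
  } else {
    keep <- if (sign_mode == "positive_only") ds$fc > 0 else ds$fc < 0
    num <- (ds$fc * keep) %*% inc
    den <- keep %*% inc
    deg <- num / den        # 0/0 -> NaN where a region has no such edge
    deg[den == 0] <- NA_real_
  }
  rownames(deg) <- rownames(ds$fc)
  deg
}

#' Write / read a connectome dataset as plain text
#'
#' Writes three tab-separated files under `dir`: `connectome.tsv`
#' (subjects x edges, full precision), `edges.tsv` (the edge-index sidecar
#' naming region pairs and categories) and `parcellation.tsv`; plus
#' `phenotypes.tsv` when phenotypes are attached.
#'
#' @param ds a [connectome_dataset()].
#' @param dir output directory (created if missing).
#' @export
write_connectome <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- data.frame(subject_id = rownames(ds$fc),
                   ds$fc, check.names = FALSE)
  utils::write.table(format(fc, digits = 17, trim = TRUE),
                     file.path(dir, "connectome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_parcellation(ds$parcellation, file.path(dir, "parcellation.tsv"))
  if (!is.null(ds$phenotypes))
    utils::write.table(ds$phenotypes, file.path(dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_connectome
#' @param atlas atlas label for the re-read parcellation.
#' @export
read_connectome <- function(dir, atlas = "file") {
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"), atlas)
  tb <- utils::read.delim(file.path(dir, "connectome.tsv"),
                          check.names = FALSE)
  fc <- as.matrix(tb[, -1L, drop = FALSE])
  rownames(fc) <- tb$subject_id
  ph_path <- file.path(dir, "phenotypes.tsv")
  ph <- if (file.exists(ph_path))
    utils::read.delim(ph_path, stringsAsFactors = FALSE) else NULL
  connectome_dataset(fc, parc, ph)
}
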