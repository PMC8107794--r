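#' Parcellation objects
#'
#' A parcellation is an ordered set of brain regions, each assigned to exactly
#' one functional network (e.g. the 94 AAL2 regions grouped into the 11
#' networks of Power's scheme). The region order is fixed at construction and
#' defines the canonical edge ordering used throughout the package.
#'
#' @param region_id character or integer vector of unique region identifiers,
#'   in the order that defines edge indexing.
#' @param network character vector, same length, network label per region.
#' @param region_name optional human-readable names (defaults to `region_id`).
#' @param atlas single string naming the atlas (e.g. `"AAL2"`, `"synthetic"`).
#' @return A `parcellation` object: a data frame with columns `region_id`,
#'   `region_name`, `network` and an `atlas` attribute.
#' @examples
#' p <- parcellation(paste0("R", 1:6), rep(c("DMN", "VIS"), each = 3))
#' n_edges(p)
#' @export
parcellation <- function(region_id, network, region_name = NULL,
                         atlas = "custom") {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stop("duplicated region_id in parcellation")
  if (length(network) != length(region_id))
    stop("network must have one label per region")
  network <- as.character(network)
  if (any(!nzchar(network)) || anyNA(network))
    stop("every region must carry a non-empty network label")
  if (length(region_id) < 2L)
    stop("a parcellation needs at least 2 regions")
  if (is.null(region_name)) region_name <- region_id
  out <- data.frame(region_id = region_id,
                    region_name = as.character(region_name),
                    network = network,
                    stringsAsFactors = FALSE)
  attr(out, "atlas") <- as.character(atlas)[1L]
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Build a synthetic parcellation with equally sized networks
#'
#' @param n_regions number of regions.
#' @param networks character vector of network names; regions are dealt out in
#'   contiguous blocks, remainder going to the last network.
#' @param atlas atlas label.
#' @return a [parcellation()].
#' @export
make_parcellation <- function(n_regions,
                              networks = c("DMN", "SN", "FPN",
                                           "SMN", "VIS", "SUB"),
                              atlas = "synthetic") {
  if (n_regions < length(networks))
    stop("need at least one region per network")
  per <- n_regions %/% length(networks)
  lab <- rep(networks, times = c(rep(per, length(networks) - 1L),
                                 n_regions - per * (length(networks) - 1L)))
  parcellation(sprintf("R%03d", seq_len(n_regions)), lab, atlas = atlas)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation '%s': %d regions, %d networks\n",
              attr(x, "atlas"), nrow(x), length(unique(x$network))))
  invisible(x)
}

#' Number of regions / edges of a parcellation
#'
#' The edge count is `R * (R - 1) / 2` for `R` regions (all unordered pairs).
#' @param parc a [parcellation()].
#' @return integer count.
#' @export
n_regions <- function(parc) nrow(parc)

#' @rdname n_regions
#' @export
n_edges <- function(parc) {
  r <- nrow(parc)
  as.integer(r * (r - 1L) / 2L)
}

#' Canonical edge index of a parcellation
#'
#' Edges are the upper triangle of the region-by-region matrix in row-major
#' order: (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R), with regions in
#' parcellation order. Each edge carries its endpoint networks and a category
#' label: `"A"` for an intra-network edge within network A, `"A|B"` (names
#' sorted) for an inter-network edge.
#'
#' @param parc a [parcellation()].
#' @return data frame with columns `edge` (1-based position), `region_a`,
#'   `region_b`, `network_a`, `network_b`, `category`, `intra` (logical).
#' @export
edge_index <- function(parc) {
  r <- nrow(parc)
  ia <- rep.int(seq_len(r - 1L), times = (r - 1L):1L)
  ib <- unlist(lapply(seq_len(r - 1L), function(i) (i + 1L):r),
               use.names = FALSE)
  na <- parc$network[ia]
  nb <- parc$network[ib]
  cat <- ifelse(na == nb, na,
                paste(pmin(na, nb), pmax(na, nb), sep = "|"))
  data.frame(edge = seq_along(ia),
             region_a = parc$region_id[ia],
             region_b = parc$region_id[ib],
             network_a = na, network_b = nb,
             category = cat, intra = na == nb,
             stringsAsFactors = FALSE)
}

#' All network connection categories of a parcellation
#'
#' For K networks there are K intra-network categories and K*(K-1)/2
#' inter-network categories, i.e. 66 for the 11-network scheme.
#' @param parc a [parcellation()].
#' @return character vector of category labels (intra first, alphabetical).
#' @export
network_categories <- function(parc) {
  nets <- sort(unique(parc$network))
  intra <- nets
  inter <- if (length(nets) > 1L) {
    cmb <- utils::combn(nets, 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "|")
  } else character(0)
  c(intra, inter)
}

#' Read / write a parcellation as TSV
#'
#' The on-disk format is a 3-column tab-separated table with header
#' `region_id  region_name  network`, one row per region in canonical order.
#' @param path file path.
#' @param atlas atlas label used when reading.
#' @export
read_parcellation <- function(path, atlas = "file") {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("region_id", "region_name", "network")
  if (!all(need %in% names(tb)))
    stop("parcellation file must have columns: ",
         paste(need, collapse = ", "))
  parcellation(tb$region_id, tb$network, tb$region_name, atlas = atlas)
}

#' @rdname read_parcellation
#' @param parc a [parcellation()].
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc)[, c("region_id", "region_name",
                                             "network")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
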