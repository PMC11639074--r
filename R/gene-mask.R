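#' Derive the per-view gene mask from a prior network
#'
#' The mask restricts which genes a view's decoder output may contribute
#' to: gene g is admitted (mask 1) when it is reachable from any receptor
#' subunit of the pair within `hops` steps in the prior network. GRN edges
#' are followed in their stated direction; PPI edges are treated as
#' bidirectional. Receptor subunits themselves are always admitted. When no
#' receptor subunit occurs in the network (or the network is empty) there is
#' no usable prior constraint and an all-ones mask is returned with a
#' warning.
#'
#' @param prior a [prior_network()].
#' @param lr an `lr_pair`.
#' @param gene_names gene panel defining mask positions.
#' @param hops maximum path length from a receptor subunit (default 2:
#'   receptor -> intermediate -> target is the shortest biologically
#'   meaningful chain).
#' @return A `gene_mask`: list with `lr_id` and `mask`, a 0/1 vector named
#'   by `gene_names`.
#' @export
derive_gene_mask <- function(prior, lr, gene_names, hops = 2) {
  stopifnot(hops >= 1)
  mask <- stats::setNames(rep(0, length(gene_names)), gene_names)
  edges <- prior$edges
  roots <- intersect(lr$receptor_subunits, c(edges$source, edges$target))
  if (nrow(edges) == 0 || length(roots) == 0) {
    warning("receptor of ", lr$id, " absent from the prior network; ",
            "using an all-ones mask (no prior constraint)", call. = FALSE)
    mask[] <- 1
  } else {
    g <- igraph::graph_from_data_frame(
      edges, directed = (prior$kind == "GRN"))
    reach <- igraph::ego(g, order = hops, nodes = roots, mode = "out")
    hit <- unique(c(lr$receptor_subunits,
                    unlist(lapply(reach, function(v) v$name))))
    mask[intersect(hit, gene_names)] <- 1
    mask[intersect(lr$receptor_subunits, gene_names)] <- 1
  }
  structure(list(lr_id = lr$id, mask = mask), class = "gene_mask")
}

#' Gene masks for a whole view set
#'
#' One mask per view; with `prior = NULL` (prior disabled) every mask is
#' all ones.
#'
#' @param lr an `lr_table` (only pairs named in `view_ids` are used).
#' @param view_ids character vector of active pair ids.
#' @inheritParams derive_gene_mask
#' @return Named list of `gene_mask` objects.
#' @export
derive_gene_masks <- function(prior, lr, view_ids, gene_names, hops = 2) {
  masks <- lapply(view_ids, function(id) {
    if (is.null(prior)) {
      structure(list(lr_id = id,
                     mask = stats::setNames(rep(1, length(gene_names)),
                                            gene_names)),
                class = "gene_mask")
    } else {
      derive_gene_mask(prior, lr[[id]], gene_names, hops)
    }
  })
  names(masks) <- view_ids
  masks
}
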