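#' Regulatory score of an LR pair for a cell and gene
#'
#' The score is the pair's micro-environment contribution to the imputed
#' expression of gene `gene` in cell `cell`: the stored component entry of
#' the trained decomposition (no recomputation). Genes masked out of a view
#' by the prior score exactly zero in that view.
#'
#' @param result an `imputation_result`.
#' @param lr_id id of an LR pair in `result$views_used`.
#' @param cell,gene cell id and gene name (or integer indices).
#' @return Scalar score.
#' @export
regulatory_score <- function(result, lr_id, cell, gene) {
  comp <- result$components[[lr_id]]
  if (is.null(comp))
    stop("lookup error: LR pair '", lr_id, "' is not among the views used")
  if (is.character(cell) && !(cell %in% rownames(comp)))
    stop("lookup error: unknown cell '", cell, "'")
  if (is.character(gene) && !(gene %in% colnames(comp)))
    stop("lookup error: unknown gene '", gene, "'")
  comp[cell, gene]
}

#' Rank LR pairs by regulatory score for one cell and gene
#'
#' Descending sort of the scores of all active pairs; ties are broken by
#' lexicographic pair id so rankings are reproducible.
#'
#' @param result an `imputation_result`.
#' @param cell,gene cell id and gene name (or integer indices).
#' @return A `regulatory_ranking`: data frame with columns `lr_id`, `psi`,
#'   rows in rank order, plus attributes `cell` and `gene`.
#' @export
rank_lr_pairs <- function(result, cell, gene) {
  ids <- result$views_used
  psi <- vapply(ids, function(id) result$components[[id]][cell, gene],
                numeric(1))
  ord <- order(-psi, ids)
  out <- data.frame(lr_id = ids[ord], psi = unname(psi[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "cell") <- cell
  attr(out, "gene") <- gene
  class(out) <- c("regulatory_ranking", "data.frame")
  out
}

#' Average regulatory ranking over a set of cells
#'
#' Mean score per LR pair across the given cells (raw averaging, no
#' per-cell normalisation), then a descending sort with lexicographic tie
#' break.
#'
#' @param result an `imputation_result`.
#' @param cells non-empty vector of cell ids (or indices).
#' @param gene gene name (or index).
#' @return Data frame `lr_id`, `mean_psi` in rank order.
#' @export
aggregate_rankings <- function(result, cells, gene) {
  if (length(cells) == 0)
    stop("empty cell subset")
  ids <- result$views_used
  mean_psi <- vapply(ids, function(id)
    mean(result$components[[id]][cells, gene]), numeric(1))
  ord <- order(-mean_psi, ids)
  data.frame(lr_id = ids[ord], mean_psi = unname(mean_psi[ord]),
             stringsAsFactors = FALSE)
}

#' Pairwise Jaccard similarity of top-K LR sets
#'
#' For a list of per-cell rankings, the Jaccard index of the top-K pair-id
#' sets for every pair of cells, quantifying how heterogeneously cells use
#' LR signals.
#'
#' @param rankings list of `regulatory_ranking` objects (or data frames
#'   with an `lr_id` column in rank order).
#' @param K set size (default 5).
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
top_k_jaccard <- function(rankings, K = 5) {
  stopifnot(K >= 1)
  tops <- lapply(rankings, function(r) utils::head(r$lr_id, K))
  p <- length(tops)
  J <- diag(1, p)
  if (p > 1) {
    for (a in seq_len(p - 1)) {
      for (b in seq(a + 1, p)) {
        u <- length(union(tops[[a]], tops[[b]]))
        J[a, b] <- J[b, a] <-
          if (u == 0) 1 else length(intersect(tops[[a]], tops[[b]])) / u
      }
    }
  }
  nm <- names(rankings)
  if (!is.null(nm)) dimnames(J) <- list(nm, nm)
  J
}

#' Long-form export of rankings
#'
#' @param result an `imputation_result`.
#' @param pairs data frame with columns `cell` and `gene` naming the
#'   (cell, gene) combinations to rank.
#' @return Data frame cell_id, gene, rank, lr_id, psi.
#' @export
ranking_table <- function(result, pairs) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- rank_lr_pairs(result, pairs$cell[i], pairs$gene[i])
    data.frame(cell_id = pairs$cell[i], gene = pairs$gene[i],
               rank = seq_len(nrow(r)), lr_id = r$lr_id, psi = r$psi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
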