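#' Per-cell ligand and receptor levels for one LR pair
#'
#' For each cell, the ligand (receptor) level is the geometric mean of the
#' expression of the ligand (receptor) subunit genes in that cell; a
#' single-subunit ligand is its own expression, and a zero subunit makes the
#' whole complex zero (all subunits of a complex are required, no
#' pseudocount). The expressed fractions `xi_l` / `xi_r` are the proportion
#' of cells whose level exceeds `positive_tol`.
#'
#' @param data a [spatial_expression()] (or any object with `$X` and
#'   `$gene_names`); `X` may also be the imputed matrix when re-screening
#'   pairs during iterative refinement.
#' @param lr an `lr_pair`.
#' @param positive_tol level above which a cell counts as expressing
#'   (0 for raw counts; a small epsilon for continuous imputed values).
#' @return A list of class `lr_summary`: `lr`, `E_l`, `E_r` (length-n
#'   vectors), `xi_l`, `xi_r`.
#' @export
summarize_lr_expression <- function(data, lr, positive_tol = 0) {
  X <- data$X
  gene_names <- data$gene_names
  subunit_levels <- function(genes, role) {
    miss <- setdiff(genes, gene_names)
    if (length(miss) > 0)
      stop("lookup error: ", role, " subunit gene(s) not in panel: ",
           paste(miss, collapse = ", "))
    cols <- as.matrix(X[, match(genes, gene_names), drop = FALSE])
    if (ncol(cols) == 1L) return(as.numeric(cols))
    out <- numeric(nrow(cols))
    pos <- rowSums(cols <= 0) == 0
    if (any(pos))
      out[pos] <- exp(rowMeans(log(cols[pos, , drop = FALSE])))
    out
  }
  E_l <- subunit_levels(lr$ligand_subunits, "ligand")
  E_r <- subunit_levels(lr$receptor_subunits, "receptor")
  structure(list(lr = lr,
                 E_l = E_l, E_r = E_r,
                 xi_l = mean(E_l > positive_tol),
                 xi_r = mean(E_r > positive_tol)),
            class = "lr_summary")
}

#' Active-pair filter
#'
#' An LR pair is active when both its ligand and its receptor are expressed
#' in strictly more than a fraction `theta` of cells.
#'
#' @param summaries list of `lr_summary` objects.
#' @param theta expression-fraction threshold in (0, 1); default 0.15.
#' @return Character vector of active pair ids (possibly empty), in input
#'   order.
#' @export
filter_expressed_pairs <- function(summaries, theta = 0.15) {
  stopifnot(theta > 0, theta < 1)
  ids <- vapply(summaries, function(s) s$lr$id, "")
  keep <- vapply(summaries, function(s) s$xi_l > theta && s$xi_r > theta,
                 logical(1))
  ids[keep]
}

#' Pairwise Euclidean distance matrix with a coincidence clamp
#'
#' Off-diagonal distances smaller than `eps` are clamped to `eps` so that
#' inverse-distance edge weights stay finite for coincident spots; `eps`
#' defaults to 1e-6 times the bounding-box diagonal of the coordinates.
#' The diagonal stays zero (self-communication is never modelled).
#'
#' @param coords n x 2 coordinate matrix, n >= 2.
#' @param eps clamp value; `NULL` for the bounding-box default.
#' @return Symmetric n x n matrix, zero diagonal.
#' @export
compute_distance_matrix <- function(coords, eps = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2)
    stop("at least 2 cells are required to build a distance matrix")
  D <- as.matrix(stats::dist(coords))
  if (is.null(eps)) {
    bbox <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    eps <- if (bbox > 0) 1e-6 * bbox else 1e-6
  }
  low <- D < eps
  diag(low) <- FALSE
  D[low] <- eps
  dimnames(D) <- list(rownames(coords), rownames(coords))
  D
}

# k nearest neighbours per row of D (excluding self), distance ties broken
# by smaller column index. Returns an n x k index matrix.
knn_index <- function(D, k) {
  n <- nrow(D)
  k <- as.integer(min(k, n - 1L))
  idx <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(idx, ncol = 1) else t(idx)
}

#' Build one communication view
#'
#' The candidate weight from sender i to receiver j is
#' `E_l[i] * E_r[j] / D[i, j]` (ligand in the sender, receptor in the
#' receiver, attenuated by inverse distance). Self-pairs are excluded, each
#' sender keeps outgoing edges only to its `k` nearest neighbours by spatial
#' distance (ties broken by smaller cell index), and zero-weight edges are
#' dropped from storage.
#'
#' @param summary an `lr_summary`.
#' @param D distance matrix from [compute_distance_matrix()].
#' @param k neighbours retained per sender (>= 1).
#' @return A `ccc_view`: list with `lr_id` and `edges`, a sparse n x n
#'   `dgCMatrix` whose entry (i, j) is the weight of edge i -> j.
#' @export
build_ccc_view <- function(summary, D, k = 5) {
  stopifnot(k >= 1)
  n <- nrow(D)
  nn <- knn_index(D, k)
  kk <- ncol(nn)
  i <- rep(seq_len(n), each = kk)
  j <- as.vector(t(nn))
  w <- summary$E_l[i] * summary$E_r[j] / D[cbind(i, j)]
  keep <- w > 0
  edges <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                                dims = c(n, n), dimnames = dimnames(D))
  structure(list(lr_id = summary$lr$id, edges = edges), class = "ccc_view")
}

#' @export
print.ccc_view <- function(x, ...) {
  cat("<ccc_view> ", x$lr_id, ": ", Matrix::nnzero(x$edges),
      " directed edges over ", nrow(x$edges), " cells\n", sep = "")
  invisible(x)
}

#' Assemble the multi-view communication network
#'
#' Screens every LR pair whose subunits are in the gene panel, keeps the
#' pairs passing the expressed-fraction filter at `theta`, and builds one
#' directed k-nearest-neighbour communication view per retained pair.
#' Views are ordered by pair id so the result is deterministic.
#'
#' @param data a [spatial_expression()].
#' @param lr an `lr_table`.
#' @param theta expression-fraction threshold (default 0.15).
#' @param k neighbours per sender (default 5).
#' @param D optional precomputed distance matrix.
#' @param positive_tol passed to [summarize_lr_expression()].
#' @return A `multiview_ccc`: list with `views` (named list of `ccc_view`),
#'   `theta`, `k`, `D`.
#' @export
assemble_multiview <- function(data, lr, theta = 0.15, k = 5, D = NULL,
                               positive_tol = 0) {
  lr <- match_lr_table(lr, data$gene_names)
  if (is.null(D)) D <- compute_distance_matrix(data$coords)
  summaries <- lapply(lr, function(p)
    summarize_lr_expression(data, p, positive_tol = positive_tol))
  active <- filter_expressed_pairs(summaries, theta)
  if (length(active) == 0)
    stop("no active LR pairs at theta = ", theta,
         "; consider lowering theta")
  active <- sort(active)
  views <- lapply(active, function(id) build_ccc_view(summaries[[id]], D, k))
  names(views) <- active
  structure(list(views = views, theta = theta, k = k, D = D),
            class = "multiview_ccc")
}

#' @export
print.multiview_ccc <- function(x, ...) {
  cat("<multiview_ccc> ", length(x$views), " views (theta = ", x$theta,
      ", k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Export a communication view (or all views) as a long edge table
#'
#' @param x a `ccc_view` or `multiview_ccc`.
#' @return data frame with columns sender_id, receiver_id, weight, lr_id.
#' @export
ccc_edge_table <- function(x) {
  one <- function(v) {
    e <- Matrix::summary(v$edges)
    ids <- rownames(v$edges)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(v$edges)))
    data.frame(sender_id = ids[e$i], receiver_id = ids[e$j],
               weight = e$x, lr_id = v$lr_id, stringsAsFactors = FALSE)
  }
  if (inherits(x, "ccc_view")) return(one(x))
  do.call(rbind, c(lapply(x$views, one), list(make.row.names = FALSE)))
}
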