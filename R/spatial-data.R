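#' Spatial expression dataset
#'
#' Container for a spatially resolved expression experiment: a sparse
#' non-negative cell-by-gene matrix, 2-D coordinates and a cell-by-cell-type
#' matrix. The cell-type matrix may hold one-hot assignments (cell-resolution
#' platforms) or proportions (spot-resolution platforms); each row must sum
#' to one. Downstream computations consume either form identically.
#'
#' @param X non-negative cell-by-gene matrix (dense or `Matrix` sparse);
#'   rows are cells, columns genes.
#' @param coords numeric matrix or data frame with two columns (x, y), one
#'   row per cell. Coordinates are continuous Euclidean positions in
#'   arbitrary length units; no grid is assumed.
#' @param cell_types non-negative matrix, cells by cell types, rows summing
#'   to one (one-hot or proportions).
#' @param gene_names,cell_ids character identifiers; taken from dimnames of
#'   `X` when omitted.
#' @return An object of class `spatial_expression` with elements `X`
#'   (a `dgCMatrix`), `coords` (n x 2 matrix), `cell_types` (n x t matrix),
#'   `gene_names` and `cell_ids`.
#' @export
spatial_expression <- function(X, coords, cell_types,
                               gene_names = colnames(X),
                               cell_ids = rownames(X)) {
  X <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  cell_types <- as.matrix(cell_types)
  storage.mode(cell_types) <- "double"
  n <- nrow(X)
  m <- ncol(X)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(m))
  if (is.null(cell_ids)) cell_ids <- paste0("C", seq_len(n))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)

  if (length(gene_names) != m)
    stop("gene_names length (", length(gene_names), ") does not match ncol(X) (", m, ")")
  if (anyDuplicated(gene_names))
    stop("gene_names must be unique")
  if (length(cell_ids) != n)
    stop("cell_ids length does not match nrow(X)")
  if (nrow(coords) != n)
    stop("alignment error: coordinates have ", nrow(coords),
         " rows but the expression matrix has ", n, " cells")
  if (ncol(coords) != 2)
    stop("coordinates must have exactly 2 columns")
  if (nrow(cell_types) != n)
    stop("alignment error: cell-type matrix has ", nrow(cell_types),
         " rows but the expression matrix has ", n, " cells")
  if (any(X@x < 0))
    stop("validation error: expression matrix contains negative entries")
  if (any(cell_types < 0))
    stop("validation error: cell-type matrix contains negative entries")
  rs <- rowSums(cell_types)
  if (any(abs(rs - 1) > 1e-6))
    stop("validation error: cell-type rows must sum to 1 (one-hot or proportions); ",
         "max deviation ", format(max(abs(rs - 1))))

  dimnames(X) <- list(cell_ids, gene_names)
  rownames(coords) <- cell_ids
  colnames(coords) <- c("x", "y")
  rownames(cell_types) <- cell_ids
  if (is.null(colnames(cell_types)))
    colnames(cell_types) <- paste0("type_", seq_len(ncol(cell_types)))

  structure(
    list(X = X, coords = coords, cell_types = cell_types,
         gene_names = gene_names, cell_ids = cell_ids),
    class = "spatial_expression"
  )
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat("<spatial_expression> ", nrow(x$X), " cells x ", ncol(x$X), " genes, ",
      ncol(x$cell_types), " cell types; density ",
      sprintf("%.3f", Matrix::nnzero(x$X) / prod(dim(x$X))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_expression <- function(x) dim(x$X)

#' Ligand-receptor pair table
#'
#' Builds the LR pair list used to define communication views. Multi-subunit
#' complexes are written with `+` between subunit gene symbols inside the
#' ligand or receptor field (the CellChatDB-style convention), e.g.
#' `"ITGA1+ITGB1"`.
#'
#' @param id character vector of unique pair identifiers.
#' @param ligand,receptor character vectors; `+`-separated subunits.
#' @return A list of `lr_pair` objects (class `lr_table`), each with fields
#'   `id`, `ligand_subunits`, `receptor_subunits`.
#' @export
lr_table <- function(id, ligand, receptor) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate LR pair id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  pairs <- lapply(seq_along(id), function(i) {
    bad <- function(x) grepl("(^|\\+)\\s*(\\+|$)", x)  # empty subunit slot
    if (bad(ligand[i]))
      stop("parse error at row ", i, ": empty ligand subunit field")
    if (bad(receptor[i]))
      stop("parse error at row ", i, ": empty receptor subunit field")
    lig <- trimws(strsplit(as.character(ligand[i]), "+", fixed = TRUE)[[1]])
    rec <- trimws(strsplit(as.character(receptor[i]), "+", fixed = TRUE)[[1]])
    if (length(lig) == 0 || any(!nzchar(lig)))
      stop("parse error at row ", i, ": empty ligand subunit field")
    if (length(rec) == 0 || any(!nzchar(rec)))
      stop("parse error at row ", i, ": empty receptor subunit field")
    structure(list(id = id[i], ligand_subunits = lig, receptor_subunits = rec),
              class = "lr_pair")
  })
  names(pairs) <- id
  structure(pairs, class = "lr_table")
}

#' @export
print.lr_table <- function(x, ...) {
  cat("<lr_table> ", length(x), " ligand-receptor pairs\n", sep = "")
  invisible(x)
}

#' Read a ligand-receptor pair table from CSV
#'
#' Expects columns `id`, `ligand`, `receptor` (an `id` column is synthesised
#' as `ligand_receptor` when absent). Subunits of a complex are separated by
#' `+` inside a field.
#'
#' @param path CSV file path.
#' @return An `lr_table`.
#' @export
read_lr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor")
  if (!all(need %in% names(df)))
    stop("LR table ", path, " must have columns 'ligand' and 'receptor'")
  if (!"id" %in% names(df))
    df$id <- paste(df$ligand, df$receptor, sep = "_")
  lr_table(df$id, df$ligand, df$receptor)
}

#' @rdname read_lr_table
#' @param x an `lr_table`.
#' @export
write_lr_table <- function(x, path) {
  df <- data.frame(
    id = vapply(x, `[[`, "", "id"),
    ligand = vapply(x, function(p) paste(p$ligand_subunits, collapse = "+"), ""),
    receptor = vapply(x, function(p) paste(p$receptor_subunits, collapse = "+"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gene-gene prior network (GRN or PPI)
#'
#' Directed regulator-to-target edge list used to mask which genes a
#' receptor may regulate. PPI edges are treated as bidirectional when the
#' mask is derived.
#'
#' @param edges two-column data frame or matrix (`source`, `target`).
#' @param kind `"GRN"` (directed) or `"PPI"` (undirected semantics).
#' @return An object of class `prior_network`.
#' @export
prior_network <- function(edges, kind = c("GRN", "PPI")) {
  kind <- match.arg(kind)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2)
    stop("prior network edge list needs two columns (source, target)")
  edges <- data.frame(source = as.character(edges[[1]]),
                      target = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, kind = kind), class = "prior_network")
}

#' @rdname prior_network
#' @param path edge-list CSV with columns source,target.
#' @export
read_prior_network <- function(path, kind = c("GRN", "PPI")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prior_network(df, match.arg(kind))
}

#' @rdname prior_network
#' @param x a `prior_network`.
#' @export
write_prior_network <- function(x, path) {
  utils::write.csv(x$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spatial expression dataset from files
#'
#' Assembles a [spatial_expression()] from an on-disk file set: an
#' expression matrix in MatrixMarket (`.mtx`, with `genes`/`cells` name
#' sidecars) or delimited dense form (cells in rows, header = gene names,
#' first column = cell ids), a coordinate CSV (`cell_id,x,y`) and a
#' cell-type CSV (`cell_id,<type columns>`). When cell identifiers are
#' present in the sidecar files, rows are aligned by identifier rather than
#' by order; a missing or extra identifier raises an alignment error naming
#' the offending file.
#'
#' @param matrix_path path to `.mtx`/`.csv`/`.tsv` expression matrix.
#' @param coords_path path to coordinates CSV.
#' @param cell_types_path path to cell-type CSV.
#' @param genes_path,cells_path name sidecars (one name per line), required
#'   for `.mtx` input.
#' @return A validated `spatial_expression`.
#' @export
read_spatial_dataset <- function(matrix_path, coords_path, cell_types_path,
                                 genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", matrix_path)) {
    X <- Matrix::readMM(matrix_path)
    if (is.null(genes_path) || is.null(cells_path))
      stop("MatrixMarket input requires genes_path and cells_path sidecars")
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (length(cells) != nrow(X))
      stop("alignment error in ", cells_path, ": ", length(cells),
           " cell ids for ", nrow(X), " matrix rows")
    if (length(genes) != ncol(X))
      stop("alignment error in ", genes_path, ": ", length(genes),
           " gene names for ", ncol(X), " matrix columns")
    dimnames(X) <- list(cells, genes)
  } else {
    sep <- if (grepl("\\.tsv$", matrix_path)) "\t" else ","
    df <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    X <- as.matrix(df)
  }

  co <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  ty <- utils::read.csv(cell_types_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ids <- rownames(X)

  align <- function(df, what, path) {
    if ("cell_id" %in% names(df) && !is.null(ids)) {
      if (!setequal(df$cell_id, ids) || nrow(df) != length(ids))
        stop("alignment error in ", path, ": ", what,
             " cell ids do not match the expression matrix (",
             nrow(df), " vs ", length(ids), " cells)")
      df <- df[match(ids, df$cell_id), , drop = FALSE]
      df$cell_id <- NULL
    } else {
      if (nrow(df) != nrow(X))
        stop("alignment error in ", path, ": ", nrow(df), " rows for ",
             nrow(X), " cells")
      df[["cell_id"]] <- NULL
    }
    df
  }
  co <- align(co, "coordinate", coords_path)
  ty <- align(ty, "cell-type", cell_types_path)

  spatial_expression(X, co[, 1:2], as.matrix(ty))
}

#' Write a spatial expression dataset to a directory
#'
#' Emits `matrix.mtx` + `genes.txt` + `cells.txt`, `coords.csv` and
#' `cell_types.csv` under `dir`. [read_spatial_dataset()] on these files
#' reproduces the object (integer counts bit-exactly; reals to MatrixMarket
#' full precision).
#'
#' @param x a `spatial_expression`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spatial_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$X, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_names, file.path(dir, "genes.txt"))
  writeLines(x$cell_ids, file.path(dir, "cells.txt"))
  utils::write.csv(
    data.frame(cell_id = x$cell_ids, x = x$coords[, 1], y = x$coords[, 2]),
    file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    cbind(data.frame(cell_id = x$cell_ids), as.data.frame(x$cell_types)),
    file.path(dir, "cell_types.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

# Drop LR pairs whose subunit genes are not all present in the panel.
# Databases always exceed a measured panel, so this warns rather than errors.
match_lr_table <- function(lr, gene_names) {
  keep <- vapply(lr, function(p) {
    all(c(p$ligand_subunits, p$receptor_subunits) %in% gene_names)
  }, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " LR pair(s) dropped: subunit gene(s) absent from the panel",
            call. = FALSE)
  }
  structure(lr[keep], class = "lr_table")
}
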