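#' Simulation configuration
#'
#' Parameters of the synthetic spatial-transcriptomics generator: cells
#' scattered uniformly in a square, location-driven cell types, negative-
#' binomial expression with per-type marker blocks, circular high-
#' communication zones for planted LR pairs, and uniform masking down to a
#' target density.
#'
#' Negative-binomial parameters are (number of successes n, success
#' probability p), mean `n (1 - p) / p` (the `size`/`prob`
#' parameterisation of [stats::rnbinom()]).
#'
#' @param n_cells number of cells (default 1000).
#' @param side square side length in spatial units (default 100).
#' @param n_genes gene panel size (default 50).
#' @param n_lr_pairs number of planted LR pairs (default 50).
#' @param n_cell_types number of cell types (default 5).
#' @param k_b anchors per cell type; more anchors give smaller, more
#'   interleaved type territories (more mixing).
#' @param r communication-zone radius in spatial units.
#' @param nb_high,nb_low,nb_comm length-2 vectors (n, p) for marker genes,
#'   background genes and communication increments.
#' @param target_density non-zero fraction after masking (default 0.2).
#' @param prior_noise_frac number of spurious prior-network edges as a
#'   fraction of `n_lr_pairs` (default 0.1).
#' @param seed integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 1000, side = 100, n_genes = 50,
                              n_lr_pairs = 50, n_cell_types = 5,
                              k_b = 2, r = 10,
                              nb_high = c(8, 0.5), nb_low = c(2, 0.8),
                              nb_comm = c(4, 0.8),
                              target_density = 0.2,
                              prior_noise_frac = 0.1, seed = 1) {
  stopifnot(target_density > 0, target_density <= 1, r < side,
            n_genes >= n_cell_types, k_b >= 1,
            nb_high[2] > 0, nb_high[2] < 1,
            nb_low[2] > 0, nb_low[2] < 1,
            nb_comm[2] > 0, nb_comm[2] < 1)
  structure(list(n_cells = as.integer(n_cells), side = side,
                 n_genes = as.integer(n_genes),
                 n_lr_pairs = as.integer(n_lr_pairs),
                 n_cell_types = as.integer(n_cell_types),
                 k_b = as.integer(k_b), r = r,
                 nb_high = nb_high, nb_low = nb_low, nb_comm = nb_comm,
                 target_density = target_density,
                 prior_noise_frac = prior_noise_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Preset simulation settings
#'
#' Nine parameter combinations covering weak/strong communication
#' (`nb_comm`), low/high background (`nb_low`), small/large zones (`r`)
#' and increasing cell-type mixing (`k_b` 2 to 20). Setting 1 is the
#' baseline: `k_b = 2, r = 10, nb_high = (8, 0.5), nb_low = (2, 0.8),
#' nb_comm = (4, 0.8)`.
#'
#' @param id setting id, 1 to 9.
#' @param ... overrides passed to [simulation_config()] (e.g. a smaller
#'   `n_cells` for quick runs).
#' @return A `simulation_config`.
#' @export
simulation_setting <- function(id, ...) {
  tab <- list(
    list(k_b = 2,  r = 10, nb_low = c(2, 0.8), nb_comm = c(4, 0.8)),
    list(k_b = 2,  r = 10, nb_low = c(2, 0.8), nb_comm = c(8, 0.8)),
    list(k_b = 5,  r = 10, nb_low = c(2, 0.8), nb_comm = c(4, 0.8)),
    list(k_b = 5,  r = 10, nb_low = c(2, 0.8), nb_comm = c(8, 0.8)),
    list(k_b = 5,  r = 10, nb_low = c(4, 0.8), nb_comm = c(4, 0.8)),
    list(k_b = 5,  r = 10, nb_low = c(4, 0.8), nb_comm = c(8, 0.8)),
    list(k_b = 5,  r = 20, nb_low = c(2, 0.8), nb_comm = c(4, 0.8)),
    list(k_b = 10, r = 10, nb_low = c(2, 0.8), nb_comm = c(8, 0.8)),
    list(k_b = 20, r = 10, nb_low = c(2, 0.8), nb_comm = c(8, 0.8))
  )
  if (!(is.numeric(id) && length(id) == 1 && id %in% seq_along(tab)))
    stop("usage error: setting id must be an integer in 1..9")
  args <- tab[[id]]
  args$nb_high <- c(8, 0.5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

#' Place cells and assign location-driven cell types
#'
#' Cells are uniform in the square. Each type seeds `k_b` anchor points
#' uniform in the square and every cell adopts the type of its nearest
#' anchor, producing contiguous Voronoi territories; larger `k_b` yields
#' more, smaller, interleaved territories.
#'
#' @param n_cells,side,n_cell_types,k_b see [simulation_config()].
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @return List with `coords` (n x 2) and `types` (integer labels 1..t).
#' @export
assign_cell_types <- function(n_cells, side, n_cell_types, k_b,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coords <- cbind(x = stats::runif(n_cells, 0, side),
                  y = stats::runif(n_cells, 0, side))
  anchors <- cbind(stats::runif(n_cell_types * k_b, 0, side),
                   stats::runif(n_cell_types * k_b, 0, side))
  anchor_type <- rep(seq_len(n_cell_types), each = k_b)
  d2 <- outer(coords[, 1], anchors[, 1], "-")^2 +
        outer(coords[, 2], anchors[, 2], "-")^2
  types <- anchor_type[max.col(-d2, ties.method = "first")]
  list(coords = coords, types = types)
}

#' Sample baseline negative-binomial expression
#'
#' The gene panel is partitioned into disjoint marker blocks of size
#' `floor(n_genes / n_cell_types)`, one per type (any remainder genes are
#' background for every type). A cell draws its own type's markers from
#' `NB(nb_high)` and every other gene from `NB(nb_low)`.
#'
#' @param types integer type labels.
#' @param config a [simulation_config()].
#' @param seed optional seed.
#' @return List with `X` (n x m integer count matrix) and `marker_map`
#'   (gene index -> owning type, 0 for background).
#' @export
sample_expression <- function(types, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(types)
  m <- config$n_genes
  t <- config$n_cell_types
  X <- matrix(stats::rnbinom(n * m, size = config$nb_low[1],
                             prob = config$nb_low[2]), n, m)
  bs <- m %/% t
  marker_map <- integer(m)
  for (j in seq_len(t)) {
    genes <- ((j - 1) * bs + 1):(j * bs)
    marker_map[genes] <- j
    cells <- which(types == j)
    if (length(cells) > 0)
      X[cells, genes] <- stats::rnbinom(length(cells) * length(genes),
                                        size = config$nb_high[1],
                                        prob = config$nb_high[2])
  }
  list(X = X, marker_map = marker_map)
}

#' Plant ligand-receptor communication zones
#'
#' Each planted pair gets one disjoint target gene (gene `p` for pair `p`,
#' cycling through the panel), ligand/receptor genes drawn from the rest of
#' the panel, and a circular zone with uniform centre and radius `r`.
#' Inside a pair's zone, ligand- and receptor-gene counts are incremented
#' by `NB(nb_comm)` draws; target-gene counts are incremented by
#' `NB(nb_comm)` draws scaled by each cell's incoming communication weight
#' from its zone neighbours (ligand times receptor over distance), so the
#' planted signal follows the same physics the model assumes. Ground truth
#' records the pair as regulating its target gene in every zone cell.
#'
#' @param X dense count matrix (modified copy returned).
#' @param coords n x 2 coordinates.
#' @param config a [simulation_config()].
#' @param seed optional seed.
#' @return List: `X` (updated counts), `lr_info` (data frame id, ligand,
#'   receptor, target), `truth` (data frame cell, gene, lr_id; indices),
#'   `zones` (data frame lr_id, x, y, radius).
#' @export
plant_communication <- function(X, coords, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X); m <- ncol(X)
  P <- config$n_lr_pairs
  ids <- sprintf("LR%02d", seq_len(P))
  target <- ((seq_len(P) - 1) %% m) + 1
  lig <- integer(P); rec <- integer(P)
  for (p in seq_len(P)) {
    pick <- sample(setdiff(seq_len(m), target[p]), 2)
    lig[p] <- pick[1]; rec[p] <- pick[2]
  }
  centers <- cbind(stats::runif(P, 0, config$side),
                   stats::runif(P, 0, config$side))
  truth <- vector("list", P)
  for (p in seq_len(P)) {
    d2 <- (coords[, 1] - centers[p, 1])^2 + (coords[, 2] - centers[p, 2])^2
    zone <- which(d2 <= config$r^2)
    if (length(zone) == 0) next
    nz <- length(zone)
    X[zone, lig[p]] <- X[zone, lig[p]] +
      stats::rnbinom(nz, size = config$nb_comm[1], prob = config$nb_comm[2])
    X[zone, rec[p]] <- X[zone, rec[p]] +
      stats::rnbinom(nz, size = config$nb_comm[1], prob = config$nb_comm[2])
    if (nz >= 2) {
      Dz <- as.matrix(stats::dist(coords[zone, , drop = FALSE]))
      Dz[Dz < 1e-9] <- 1e-9
      El <- X[zone, lig[p]]; Er <- X[zone, rec[p]]
      W <- outer(El, Er) / Dz
      diag(W) <- 0
      w_in <- colSums(W)               # incoming weight per zone cell
      if (any(w_in > 0)) {
        scale <- w_in / mean(w_in[w_in > 0])
        inc <- round(stats::rnbinom(nz, size = config$nb_comm[1],
                                    prob = config$nb_comm[2]) * scale)
        X[zone, target[p]] <- X[zone, target[p]] + inc
      }
    }
    truth[[p]] <- data.frame(cell = zone, gene = target[p], lr_id = ids[p],
                             stringsAsFactors = FALSE)
  }
  list(X = X,
       lr_info = data.frame(id = ids, ligand = lig, receptor = rec,
                            target = target, stringsAsFactors = FALSE),
       truth = do.call(rbind, truth),
       zones = data.frame(lr_id = ids, x = centers[, 1], y = centers[, 2],
                          radius = config$r, stringsAsFactors = FALSE))
}

#' Mask a dense matrix down to a target density
#'
#' Uniformly zeroes randomly chosen non-zero entries until the non-zero
#' fraction equals `target_density` to the nearest entry. Zero entries are
#' never turned on.
#'
#' @param X dense matrix.
#' @param target_density desired non-zero fraction.
#' @param seed optional seed.
#' @return Masked matrix.
#' @export
mask_to_density <- function(X, target_density, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nz <- which(X != 0)
  target_nnz <- round(target_density * length(X))
  if (length(nz) < target_nnz)
    stop("cannot reach density ", target_density, ": matrix has only ",
         length(nz), " non-zero entries (achievable density ",
         signif(length(nz) / length(X), 4), ")")
  drop <- sample(nz, length(nz) - target_nnz)
  X[drop] <- 0
  X
}

#' Generate a full synthetic dataset
#'
#' Composes cell placement, baseline expression, communication planting and
#' masking, and derives the companion inputs: the LR pair table, a gene
#' regulatory prior containing every receptor-to-target edge plus a small
#' fraction of spurious edges, one-hot cell types, and ground-truth
#' ligand-gene relevance.
#'
#' @param config a [simulation_config()] (or [simulation_setting()]).
#' @return A `simulated_dataset`: `data` (masked [spatial_expression()]),
#'   `dense` (pre-mask), `lr` (`lr_table`), `prior`
#'   ([prior_network()]), `truth` (data frame cell_id, gene, lr_id),
#'   `zones`, `lr_info`, `marker_map`, `types`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  set.seed(config$seed)
  geo <- assign_cell_types(config$n_cells, config$side,
                           config$n_cell_types, config$k_b)
  expr <- sample_expression(geo$types, config)
  planted <- plant_communication(expr$X, geo$coords, config)

  gene_names <- sprintf("G%02d", seq_len(config$n_genes))
  cell_ids <- sprintf("C%04d", seq_len(config$n_cells))
  Tmat <- matrix(0, config$n_cells, config$n_cell_types,
                 dimnames = list(cell_ids,
                                 paste0("type_", seq_len(config$n_cell_types))))
  Tmat[cbind(seq_len(config$n_cells), geo$types)] <- 1

  lr <- lr_table(planted$lr_info$id,
                 gene_names[planted$lr_info$ligand],
                 gene_names[planted$lr_info$receptor])

  real_edges <- data.frame(
    source = gene_names[planted$lr_info$receptor],
    target = gene_names[planted$lr_info$target],
    stringsAsFactors = FALSE)
  n_noise <- round(config$prior_noise_frac * config$n_lr_pairs)
  noise <- if (n_noise > 0) {
    data.frame(source = gene_names[sample.int(config$n_genes, n_noise,
                                              replace = TRUE)],
               target = gene_names[sample.int(config$n_genes, n_noise,
                                              replace = TRUE)],
               stringsAsFactors = FALSE)
  } else NULL
  prior <- prior_network(unique(rbind(real_edges, noise)), kind = "GRN")

  masked <- mask_to_density(planted$X, config$target_density)

  mk <- function(X) {
    dimnames(X) <- list(cell_ids, gene_names)
    spatial_expression(X, geo$coords, Tmat)
  }
  truth <- planted$truth
  if (!is.null(truth)) {
    truth <- data.frame(cell_id = cell_ids[truth$cell],
                        gene = gene_names[truth$gene],
                        lr_id = truth$lr_id, stringsAsFactors = FALSE)
  }
  structure(list(data = mk(masked), dense = mk(planted$X), lr = lr,
                 prior = prior, truth = truth, zones = planted$zones,
                 lr_info = planted$lr_info, marker_map = expr$marker_map,
                 types = geo$types, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", x$config$n_cells, " cells x ",
      x$config$n_genes, " genes, ", x$config$n_lr_pairs,
      " planted LR pairs, ", nrow(x$truth), " truth entries\n", sep = "")
  invisible(x)
}

#' Oracle ranking from the planted generative process
#'
#' Ranks pairs for a (cell, gene) combination directly from the zones and
#' target assignment: a pair scores 1 when the cell lies in its zone and
#' the gene is its target, 0 otherwise. Used to check that the ground
#' truth is self-consistent (the oracle attains perfect precision).
#'
#' @param dataset a `simulated_dataset`.
#' @param cell_id,gene identifiers.
#' @return Data frame `lr_id`, `psi` in rank order.
#' @export
oracle_ranking <- function(dataset, cell_id, gene) {
  info <- dataset$lr_info
  gene_names <- dataset$data$gene_names
  ci <- match(cell_id, dataset$data$cell_ids)
  gi <- match(gene, gene_names)
  xy <- dataset$data$coords[ci, ]
  d2 <- (dataset$zones$x - xy[1])^2 + (dataset$zones$y - xy[2])^2
  in_zone <- d2 <= dataset$zones$radius^2
  psi <- as.numeric(in_zone & info$target == gi)
  ord <- order(-psi, info$id)
  data.frame(lr_id = info$id[ord], psi = psi[ord], stringsAsFactors = FALSE)
}

#' Write a simulated dataset as the standard file set
#'
#' Emits the masked matrix file set (see [write_spatial_dataset()]), the
#' dense pre-mask matrix under `dense/`, `lr_table.csv`, `prior.csv`,
#' `truth.csv` and `zones.csv`.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spatial_dataset(dataset$data, dir)
  write_spatial_dataset(dataset$dense, file.path(dir, "dense"))
  write_lr_table(dataset$lr, file.path(dir, "lr_table.csv"))
  write_prior_network(dataset$prior, file.path(dir, "prior.csv"))
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$zones, file.path(dir, "zones.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
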