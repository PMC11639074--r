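# Small in-code fixtures shared across test files.

# hand-sized expression object: 4 cells, 5 genes, 2 types
tiny_dataset <- function() {
  X <- matrix(c(0, 4, 0, 9,
                2, 0, 3, 1,
                5, 5, 0, 0,
                1, 2, 3, 4,
                0, 0, 0, 2), nrow = 4,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
  coords <- cbind(x = c(0, 3, 0, 10), y = c(0, 4, 1, 10))
  Tm <- matrix(c(1, 0,
                 1, 0,
                 0, 1,
                 0, 1), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("c", 1:4), c("A", "B")))
  spatial_expression(X, coords, Tm)
}

# a small simulated instance used by several model-level tests
small_sim <- function(seed = 7, n_cells = 60, n_lr_pairs = 5,
                      n_genes = 15, n_cell_types = 3) {
  simulate_dataset(simulation_setting(
    1, n_cells = n_cells, n_lr_pairs = n_lr_pairs, n_genes = n_genes,
    n_cell_types = n_cell_types, seed = seed))
}

# numeric central-difference gradient of f at params, at one leaf index
numeric_grad <- function(f, params, path, i, eps = 1e-6) {
  bump <- function(root, v) {
    g <- function(x, d) {
      if (d > length(path)) { x[i] <- x[i] + v; return(x) }
      x[[path[[d]]]] <- g(x[[path[[d]]]], d + 1)
      x
    }
    g(root, 1)
  }
  (f(bump(params, eps)) - f(bump(params, -eps))) / (2 * eps)
}

leaf_value <- function(obj, path, i) {
  for (k in path) obj <- obj[[k]]
  obj[i]
}
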