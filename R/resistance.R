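#' Build the conductance graph of a resistance raster
#'
#' Cells are graph nodes; 4- or 8-neighbour cells are joined by a resistor.
#' The cell-to-cell conductance uses the average-resistance rule
#' `g = 2 / (r_a + r_b)`, divided by `sqrt(2)` for diagonal neighbours (the
#' longer hop). Masked (NA) cells are excluded from the graph.
#'
#' @param raster a [landscape_raster()] of strictly positive resistances.
#' @param connectivity 4 (rook) or 8 (queen, default).
#' @return a list with the sparse graph `laplacian` (rows summing to zero),
#'   `cells` (data.frame of `row`, `col` for each graph node), and the raster
#'   dimensions.
#' @export
build_graph <- function(raster, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- raster$values
  if (any(m <= 0, na.rm = TRUE)) {
    stop("resistance values must be strictly positive")
  }
  nr <- nrow(m); nc <- ncol(m)
  unmasked <- which(!is.na(m))
  if (length(unmasked) < 2) stop("need at least 2 unmasked cells")
  node_of <- rep(NA_integer_, nr * nc)
  node_of[unmasked] <- seq_along(unmasked)

  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))

  rows_all <- ((unmasked - 1L) %% nr) + 1L
  cols_all <- ((unmasked - 1L) %/% nr) + 1L
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (o in offs) {
    r2 <- rows_all + o[1]; c2 <- cols_all + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    from_cell <- unmasked[ok]
    to_cell <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(node_of[to_cell])
    from_cell <- from_cell[keep]; to_cell <- to_cell[keep]
    if (!length(from_cell)) next
    g <- 2 / (m[from_cell] + m[to_cell])
    if (any(o != 0L) && all(abs(o) == 1L)) g <- g / sqrt(2)
    ei <- c(ei, node_of[from_cell])
    ej <- c(ej, node_of[to_cell])
    ew <- c(ew, g)
  }
  n <- length(unmasked)
  A <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(ew, ew),
                            dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  list(
    laplacian = L,
    cells = data.frame(row = rows_all, col = cols_all),
    nrow = nr, ncol = nc, connectivity = connectivity
  )
}

graph_node_index <- function(graph, nodes) {
  idx <- match(
    paste(nodes$row, nodes$col),
    paste(graph$cells$row, graph$cells$col)
  )
  if (any(is.na(idx))) {
    bad <- nodes$site[is.na(idx)]
    stop("node cells masked or outside raster: ",
         paste(bad, collapse = ", "))
  }
  idx
}

#' Pairwise effective resistance between site nodes
#'
#' Circuit-theory distance on the raster conductance graph:
#' `R_eff(s, t) = (e_s - e_t)' L^+ (e_s - e_t)` with `L` the graph Laplacian.
#' Computed by grounding one node and solving the reduced symmetric system
#' with a sparse Cholesky factorization (one factorization, one solve per
#' site). All node cells must lie in one connected component.
#'
#' @param graph output of [build_graph()].
#' @param nodes data.frame with columns `site`, `row`, `col` placing each
#'   site on the raster grid.
#' @return a [dist_matrix()] of effective resistances (metric
#'   `"effective_resistance"`).
#' @export
effective_resistance <- function(graph, nodes) {
  node_idx <- graph_node_index(graph, nodes)
  L <- graph$laplacian
  n <- nrow(L)

  # connectivity check on the graph the Laplacian encodes
  g <- igraph::graph_from_adjacency_matrix(
    Matrix::Diagonal(x = Matrix::diag(L)) - L,
    mode = "undirected", weighted = TRUE
  )
  comp <- igraph::components(g)$membership
  if (length(unique(comp[node_idx])) > 1) {
    stop("disconnected landscape: site nodes span multiple components")
  }
  keep <- which(comp == comp[node_idx[1]])
  L <- L[keep, keep, drop = FALSE]
  node_idx <- match(node_idx, keep)

  ground <- nrow(L)  # arbitrary grounded node in the component
  red <- setdiff(seq_len(nrow(L)), ground)
  Lr <- L[red, red, drop = FALSE]
  pos_in_red <- match(node_idx, red)  # NA if a site sits on the ground node
  E <- matrix(0, nrow(Lr), length(node_idx))
  for (k in seq_along(node_idx)) {
    if (!is.na(pos_in_red[k])) E[pos_in_red[k], k] <- 1
  }
  X <- as.matrix(Matrix::solve(Lr, E))
  # quadratic forms: R_st = G_ss + G_tt - 2 G_st with G = E' Lr^-1 E
  G <- crossprod(E, X)
  P <- length(node_idx)
  R <- matrix(0, P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      R[i, j] <- G[i, i] + G[j, j] - 2 * G[i, j]
    }
  }
  dist_matrix(R, as.character(nodes$site),
              metric = "effective_resistance", level = "population")
}

#' Isolation-by-distance predictor from a uniform surface
#'
#' Effective resistance on the all-ones resistance raster with the same
#' shape: the circuit-theoretic analogue of geographic distance.
#'
#' @param raster any [landscape_raster()] supplying the grid shape and mask.
#' @param nodes site node data.frame (see [effective_resistance()]).
#' @param connectivity 4 or 8.
#' @return a [dist_matrix()] of effective resistances.
#' @export
uniform_ibd_predictor <- function(raster, nodes, connectivity = 8) {
  uni <- parameterize(raster, "uniform")
  effective_resistance(build_graph(uni, connectivity), nodes)
}

#' Variance-inflation-factor screen of resistance predictors
#'
#' Each predictor's lower-triangle vector is regressed on all the others;
#' `VIF = 1 / (1 - R^2)`. The predictor with the largest VIF is removed
#' iteratively while any VIF is at or above `threshold`. A perfectly
#' collinear predictor yields infinite VIF and is removed first.
#'
#' @param predictors named list of population-level [dist_matrix()] objects
#'   sharing labels.
#' @param threshold VIF threshold (default 4).
#' @return a list with `retained` (the surviving named list), `removed`
#'   (character vector in removal order), and `vif` (final VIF scores).
#' @export
vif_screen <- function(predictors, threshold = 4) {
  stopifnot(length(predictors) >= 2)
  vecs <- lapply(predictors, lower_triangle)
  if (any(vapply(vecs, stats::sd, numeric(1)) == 0)) {
    stop("constant predictor matrix")
  }
  active <- names(predictors)
  removed <- character(0)
  vif_of <- function(active) {
    vapply(active, function(nm) {
      y <- vecs[[nm]]
      X <- do.call(cbind, vecs[setdiff(active, nm)])
      # perfect collinearity gives R^2 = 1; lm warns, VIF is +Inf by design
      r2 <- suppressWarnings(summary(stats::lm(y ~ X))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (length(active) >= 2) {
    v <- vif_of(active)
    if (max(v) < threshold) break
    worst <- names(which.max(v))
    removed <- c(removed, worst)
    active <- setdiff(active, worst)
  }
  final_vif <- if (length(active) >= 2) vif_of(active) else {
    stats::setNames(rep(1, length(active)), active)
  }
  list(retained = predictors[active], removed = removed, vif = final_vif)
}

#' Read or write a site node file
#'
#' Node files are CSVs with columns `site`, `row`, `col` (1-based raster
#' cell indices).
#'
#' @param path file path.
#' @return `read_nodes` returns the data.frame; `write_nodes` returns `path`
#'   invisibly.
#' @export
read_nodes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "row", "col") %in% names(df))) {
    stop("node file needs site,row,col columns")
  }
  df$site <- as.character(df$site)
  df
}

#' @rdname read_nodes
#' @param nodes node data.frame.
#' @export
write_nodes <- function(nodes, path) {
  utils::write.csv(nodes[, c("site", "row", "col")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
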