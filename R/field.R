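#' Build a rectangular field layout with its CAR ingredients
#'
#' Plots are laid out row-major on an `n_rows` by `n_cols` grid of plot
#' centroids (`plot_dx`/`plot_dy` metres apart).  The neighborhood matrix
#' `M` is rook adjacency (plots sharing an edge) by default, or queen
#' (edges and corners).  Also computed: the diagonal of row sums `D_M`, the
#' ordered eigenvalues of the scaled adjacency `D_M^{-1/2} M D_M^{-1/2}`,
#' and the open support `(1/lambda_(1), 1/lambda_(n))` for the CAR
#' autocorrelation parameter phi (with `lambda_(1) < 0 < lambda_(n)`, so the
#' support always contains 0).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param plot_dx,plot_dy centroid spacing in metres (plot footprint).
#' @param n_plots number of plots; defaults to the full grid, may be fewer
#'   (plots fill the grid row-major).
#' @param adjacency `"rook"` (default) or `"queen"`.
#' @param plot_ids optional character ids, length `n_plots`.
#' @return A `field_structure`: list with `plot_ids`, `coords` (n x 2,
#'   metres), `M`, `d_m` (row sums), `lambda` (sorted eigenvalues),
#'   `phi_support`, and the layout parameters.
#' @export
build_layout <- function(n_rows = 21, n_cols = 6, plot_dx = 3.2, plot_dy = 5,
                         n_plots = n_rows * n_cols,
                         adjacency = c("rook", "queen"), plot_ids = NULL) {
  adjacency <- match.arg(adjacency)
  stopifnot(n_rows >= 1, n_cols >= 1, plot_dx > 0, plot_dy > 0,
            n_plots <= n_rows * n_cols)
  idx <- seq_len(n_plots) - 1L
  row <- idx %/% n_cols
  col <- idx %% n_cols
  coords <- cbind(x = col * plot_dx, y = row * plot_dy)
  if (is.null(plot_ids))
    plot_ids <- sprintf("P%03d", seq_len(n_plots))
  stopifnot(length(plot_ids) == n_plots, !anyDuplicated(plot_ids))
  M <- matrix(0, n_plots, n_plots, dimnames = list(plot_ids, plot_ids))
  for (i in seq_len(n_plots)) {
    dr <- abs(row - row[i])
    dc <- abs(col - col[i])
    nb <- if (adjacency == "rook") (dr + dc) == 1 else (pmax(dr, dc) == 1)
    M[i, nb] <- 1
  }
  finalize_field(plot_ids, coords, M,
                 layout = list(n_rows = n_rows, n_cols = n_cols,
                               plot_dx = plot_dx, plot_dy = plot_dy,
                               adjacency = adjacency,
                               row = row + 1L, col = col + 1L))
}

# Shared constructor: validates M, computes D_M, eigenvalues of the scaled
# adjacency, and the CAR phi support.
finalize_field <- function(plot_ids, coords, M, layout = NULL) {
  n <- length(plot_ids)
  stopifnot(isSymmetric(unname(M)), all(diag(M) == 0), all(M %in% c(0, 1)))
  d_m <- rowSums(M)
  isolated <- plot_ids[d_m == 0]
  if (length(isolated))
    stop("plot(s) with no neighbor: ", paste(isolated, collapse = ", "))
  ds <- 1 / sqrt(d_m)
  L <- M * tcrossprod(ds)            # D_M^{-1/2} M D_M^{-1/2}
  lambda <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (!(lambda[1] < 0 && lambda[n] > 0))
    stop("scaled adjacency must have eigenvalues of both signs")
  structure(list(plot_ids = plot_ids, coords = coords, M = M, d_m = d_m,
                 lambda = lambda,
                 phi_support = c(1 / lambda[1], 1 / lambda[n]),
                 layout = layout, n = n),
            class = "field_structure")
}

#' @export
print.field_structure <- function(x, ...) {
  cat("field_structure:", x$n, "plots;",
      if (!is.null(x$layout)) paste0(x$layout$n_rows, "x", x$layout$n_cols,
                                     " grid (", x$layout$adjacency, "); "),
      "phi support (", round(x$phi_support[1], 4), ",",
      round(x$phi_support[2], 4), ")\n")
  invisible(x)
}

#' Read a field layout from a CSV of grid positions
#'
#' Overrides the generated grid with explicit `(plot_id, row, col)`
#' positions; adjacency and the CAR ingredients are rebuilt from them.
#'
#' @param path CSV with columns `plot_id`, `row`, `col`.
#' @param plot_dx,plot_dy centroid spacing in metres.
#' @param adjacency `"rook"` or `"queen"`.
#' @return A `field_structure`.
#' @export
read_layout <- function(path, plot_dx = 3.2, plot_dy = 5,
                        adjacency = c("rook", "queen")) {
  adjacency <- match.arg(adjacency)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("plot_id", "row", "col") %in% names(df)))
  n <- nrow(df)
  coords <- cbind(x = (df$col - 1) * plot_dx, y = (df$row - 1) * plot_dy)
  M <- matrix(0, n, n, dimnames = list(df$plot_id, df$plot_id))
  for (i in seq_len(n)) {
    dr <- abs(df$row - df$row[i])
    dc <- abs(df$col - df$col[i])
    nb <- if (adjacency == "rook") (dr + dc) == 1 else
      (pmax(dr, dc) == 1)
    M[i, nb] <- 1
  }
  finalize_field(as.character(df$plot_id), coords, M,
                 layout = list(adjacency = adjacency,
                               row = df$row, col = df$col,
                               plot_dx = plot_dx, plot_dy = plot_dy))
}

#' Adjacency as an edge list
#'
#' @param fs a `field_structure`.
#' @return Data frame with columns `from`, `to` (plot ids), one row per
#'   undirected edge; suitable for CSV export.
#' @export
adjacency_edges <- function(fs) {
  idx <- which(upper.tri(fs$M) & fs$M == 1, arr.ind = TRUE)
  data.frame(from = fs$plot_ids[idx[, 1]], to = fs$plot_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Euclidean distance matrix of plot centroids
#'
#' @param fs a `field_structure` (or any list with an n x 2 `coords`).
#' @return Symmetric n x n matrix of distances in metres.
#' @export
distance_matrix <- function(fs) {
  as.matrix(stats::dist(fs$coords))
}

#' Exponential correlogram
#'
#' `H(phi)_ij = exp(-phi * d_ij)`: isotropic exponential decay of
#' correlation with Euclidean distance.
#'
#' @param D distance matrix in metres.
#' @param phi decay rate (1/metres), strictly positive.
#' @return Correlation matrix with unit diagonal.
#' @export
exp_correlation <- function(D, phi) {
  if (phi <= 0) stop("phi must be > 0")
  exp(-phi * D)
}

#' CAR precision matrix
#'
#' Returns `(D_M - phi M) / tau2`, the precision of the joint CAR
#' distribution `y ~ N(X beta, tau2 (D_M - phi M)^{-1})`.  `phi` must lie
#' strictly inside the field's `phi_support`, which guarantees positive
#' definiteness.
#'
#' @param fs a `field_structure`.
#' @param phi CAR autocorrelation parameter.
#' @param tau2 conditional variance, > 0.
#' @return Symmetric positive definite n x n precision matrix.
#' @export
car_precision <- function(fs, phi, tau2 = 1) {
  if (tau2 <= 0) stop("tau2 must be > 0")
  if (phi <= fs$phi_support[1] || phi >= fs$phi_support[2])
    stop("phi = ", phi, " outside the open support (",
         fs$phi_support[1], ", ", fs$phi_support[2],
         "): precision singular or indefinite")
  (diag(fs$d_m) - phi * fs$M) / tau2
}

# Restrict a field structure to a subset of plots (training rows in CV).
# D_M keeps the FULL-field row sums and M is the induced submatrix, so the
# restricted precision D_t - phi M_tt is the conditional precision of the
# retained plots; its scaled adjacency is a principal submatrix of the full
# one, hence (Cauchy interlacing) positive definite for every phi in the
# full field's support, which is retained as the prior support.
subset_field <- function(fs, rows) {
  M <- fs$M[rows, rows, drop = FALSE]
  d_m <- fs$d_m[rows]
  ds <- 1 / sqrt(d_m)
  L <- M * tcrossprod(ds)
  lambda <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(plot_ids = fs$plot_ids[rows],
                 coords = fs$coords[rows, , drop = FALSE],
                 M = M, d_m = d_m, lambda = lambda,
                 phi_support = fs$phi_support, layout = NULL,
                 n = length(rows)),
            class = "field_structure")
}
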