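#' Rectangular quadrature grid over the latent space
#'
#' Builds a direct-product lattice of latent-trait values with
#' normalized prior weights proportional to the multivariate normal
#' density (mean 0, unit variances, correlation `R`) at each node.
#' Either give `nodes_per_dim` with a common range, or an explicit list
#' of per-dimension node vectors via `nodes`.
#'
#' @param nodes_per_dim Number of equally spaced nodes per dimension
#'   (default 49, the scoring convention).
#' @param lo,hi Range endpoints (default -6, 6).
#' @param R `D x D` latent correlation matrix; its order defines the
#'   dimension order of the grid.  A `1 x 1` matrix (or `D = 1`) gives a
#'   one-dimensional grid.
#' @param nodes Optional named list of node vectors, one per dimension
#'   (overrides `nodes_per_dim`/`lo`/`hi`); names must match
#'   `colnames(R)` when both are named.
#' @return An object of class `latent_grid`: list with `X` (`Q x D`
#'   node matrix), `W` (normalized weights summing to 1), `nodes`
#'   (per-dimension node vectors), `R`, and `dims`.
#' @examples
#' g <- latent_grid(nodes = list(QOL = c(-1, 0, 1), ERS = c(-2, 0, 2)),
#'                  R = matrix(c(1, -0.18, -0.18, 1), 2))
#' sum(g$W)
#' @export
latent_grid <- function(nodes_per_dim = 49L, lo = -6, hi = 6, R = diag(1L),
                        nodes = NULL) {
  R <- as.matrix(R)
  D <- nrow(R)
  check_correlation(R, D)
  dims <- colnames(R)
  if (is.null(nodes)) {
    if (nodes_per_dim < 2L) stop("nodes_per_dim must be >= 2")
    if (!(lo < hi)) stop("need lo < hi")
    nodes <- rep(list(seq(lo, hi, length.out = nodes_per_dim)), D)
  } else {
    if (length(nodes) != D)
      stop("nodes list length (", length(nodes), ") != D (", D, ")")
    if (!is.null(names(nodes)) && !is.null(dims) &&
        !identical(names(nodes), dims))
      stop("names(nodes) must match colnames(R)")
    if (is.null(dims)) dims <- names(nodes)
  }
  if (is.null(dims)) dims <- paste0("dim", seq_len(D))
  names(nodes) <- dims
  X <- as.matrix(expand.grid(nodes, KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- dims
  Ri <- solve(R)
  # density up to a constant: exp(-q/2); constants cancel in normalization
  q <- rowSums((X %*% Ri) * X)
  w <- exp(-(q - min(q)) / 2)
  W <- w / sum(w)
  structure(list(X = X, W = W, nodes = nodes, R = R, dims = dims),
            class = "latent_grid")
}

#' @export
print.latent_grid <- function(x, ...) {
  cat("<latent_grid>", nrow(x$X), "nodes over",
      paste(x$dims, collapse = " x "), "\n")
  invisible(x)
}

# default grids: estimation uses a coarser lattice than the 49-point
# scoring convention because cost grows as points^D
default_grid <- function(R, purpose = c("scoring", "estimation")) {
  purpose <- match.arg(purpose)
  D <- nrow(as.matrix(R))
  if (purpose == "scoring") {
    latent_grid(49L, -6, 6, R)
  } else {
    pts <- if (D <= 2L) 21L else 15L
    latent_grid(pts, -5, 5, R)
  }
}
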