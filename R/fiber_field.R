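#' Laplace potential on the muscle region
#'
#' Solves the Laplace equation on the muscle region of a mesh with a linear
#' tetrahedron Galerkin discretization, fixing the potential to 0 on the
#' `source_set` nodes and 1 on the `sink_set` nodes. The gradient of the
#' resulting harmonic potential defines the fiber directions
#' ([fiber_directions()]). Non-muscle nodes carry `NA`.
#'
#' @param mesh A [fem_mesh()] containing muscle elements.
#' @param source_set,sink_set Names of disjoint, non-empty node sets on the
#'   muscle boundary (typically the proximal and distal tendon-attachment
#'   surfaces).
#' @return Numeric vector of nodal potentials (class `scalar_field`), `NA`
#'   outside the muscle region; attributes record the Dirichlet sets and the
#'   relative residual of the reduced linear solve.
#' @export
solve_laplace <- function(mesh, source_set, sink_set) {
  src <- mesh_set_nodes(mesh, source_set)
  snk <- mesh_set_nodes(mesh, sink_set)
  if (!length(src) || !length(snk))
    stop("source and sink node sets must be non-empty")
  if (length(intersect(src, snk)))
    stop("source and sink node sets overlap")
  mus <- which(mesh$region == "muscle")
  if (!length(mus)) stop("mesh has no muscle elements")
  el <- mesh$elems[mus, , drop = FALSE]
  mnodes <- sort(unique(as.vector(el)))
  if (!all(src %in% mnodes) || !all(snk %in% mnodes))
    stop("Dirichlet sets must lie on the muscle region")

  sub <- fem_mesh(mesh$nodes, el, rep("muscle", nrow(el)))
  sg <- shape_gradients(sub)
  m <- nrow(el)
  ii <- jj <- xx <- vector("list", m)
  for (e in seq_len(m)) {
    G <- sg$G[4 * (e - 1) + 1:4, ]
    Ke <- sg$V[e] * tcrossprod(G)               # V * G G'
    ii[[e]] <- rep(el[e, ], each = 4)
    jj[[e]] <- rep(el[e, ], times = 4)
    xx[[e]] <- as.vector(t(Ke))
  }
  n <- nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  phi <- rep(NA_real_, n)
  phi[mnodes] <- 0
  phi[src] <- 0
  phi[snk] <- 1
  fixed <- c(src, snk)
  free <- setdiff(mnodes, fixed)
  if (length(free)) {
    rhs <- -K[free, fixed, drop = FALSE] %*% phi[fixed]
    Kff <- K[free, free, drop = FALSE]
    sol <- Matrix::solve(Kff, rhs)
    phi[free] <- as.numeric(sol)
    res <- Kff %*% sol - rhs
    rel <- sqrt(sum(res@x^2)) / max(sqrt(sum((rhs@x %||% 0)^2)), 1e-300)
  } else rel <- 0
  # connectivity check: a disconnected muscle component yields a singular
  # reduced system and NaNs
  if (any(!is.finite(phi[mnodes])))
    stop("muscle region appears disconnected from the Dirichlet sets")
  structure(phi, class = "scalar_field",
            source = source_set, sink = sink_set, residual = rel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-element fiber directions from a potential field
#'
#' The fiber direction of each muscle element is the (element-constant)
#' gradient of the linear interpolant of the Laplace potential, normalized
#' to unit length. The orientation sign is fixed for reproducibility:
#' directions point with positive component along the source-to-sink
#' centroid axis.
#'
#' @param mesh A [fem_mesh()].
#' @param phi A nodal potential from [solve_laplace()].
#' @return Matrix (number of muscle elements x 3) of unit vectors (class
#'   `fiber_field`), with attribute `elements` giving the muscle element
#'   indices in the mesh.
#' @export
fiber_directions <- function(mesh, phi) {
  mus <- which(mesh$region == "muscle")
  el <- mesh$elems[mus, , drop = FALSE]
  sub <- fem_mesh(mesh$nodes, el, rep("muscle", nrow(el)))
  sg <- shape_gradients(sub)
  dirs <- matrix(0, nrow(el), 3)
  for (e in seq_len(nrow(el))) {
    G <- sg$G[4 * (e - 1) + 1:4, ]
    g <- drop(crossprod(G, phi[el[e, ]]))       # sum_a phi_a grad N_a
    nrm <- sqrt(sum(g^2))
    if (!is.finite(nrm) || nrm < 1e-14)
      stop(sprintf("degenerate fiber field: zero potential gradient in muscle element %d",
                   e))
    dirs[e, ] <- g / nrm
  }
  src <- attr(phi, "source"); snk <- attr(phi, "sink")
  if (!is.null(src) && !is.null(snk)) {
    axis <- colMeans(mesh$nodes[mesh_set_nodes(mesh, snk), , drop = FALSE]) -
      colMeans(mesh$nodes[mesh_set_nodes(mesh, src), , drop = FALSE])
    flip <- drop(dirs %*% axis) < 0
    dirs[flip, ] <- -dirs[flip, ]
  }
  structure(dirs, class = "fiber_field", elements = mus)
}
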