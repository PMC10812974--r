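#' Tetrahedral mesh with region labels and named node sets
#'
#' The geometric substrate of every solve: node coordinates (mm), linear
#' tetrahedron connectivity (1-based node indices), one region label per
#' element (`"muscle"`, `"bone"` or `"tendon"`), and named node sets used
#' for boundary conditions, loads and the fiber-field Laplace problem.
#'
#' @param nodes Numeric n x 3 matrix of node coordinates (mm).
#' @param elems Integer m x 4 matrix of tetrahedron connectivity (1-based).
#'   All tetrahedra must have positive signed volume.
#' @param region Character vector of length m with the region label of each
#'   element.
#' @param sets Named list of integer node-index vectors.
#' @param elem_patch Optional integer vector of length m grouping elements
#'   into patches (e.g. the parent hexahedra of a structured generator);
#'   used by the optional mean-dilatation incompressibility averaging.
#' @return An object of class `fem_mesh`.
#' @seealso [make_unit_fixture()], [make_synthetic_forearm()], [read_mesh()]
#' @export
fem_mesh <- function(nodes, elems, region, sets = list(),
                     elem_patch = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 matrix")
  if (ncol(elems) != 4) stop("elems must be an m x 4 matrix")
  if (length(region) != nrow(elems))
    stop("region labels must cover all elements")
  region <- as.character(region)
  bad <- setdiff(unique(region), c("muscle", "bone", "tendon"))
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  if (min(elems) < 1 || max(elems) > nrow(nodes))
    stop("connectivity indices out of range")
  if (!is.null(elem_patch) && length(elem_patch) != nrow(elems))
    stop("elem_patch must have one entry per element")
  m <- structure(list(nodes = nodes, elems = elems, region = region,
                      sets = lapply(sets, function(s) sort(unique(as.integer(s)))),
                      elem_patch = elem_patch),
                 class = "fem_mesh")
  v <- tet_volumes(m)
  if (any(v <= 0))
    stop(sprintf("%d tetrahedra have non-positive signed volume (first: element %d, V = %g)",
                 sum(v <= 0), which(v <= 0)[1], min(v)))
  m
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("tetrahedral mesh: %d nodes, %d elements\n",
              nrow(x$nodes), nrow(x$elems)))
  tab <- table(x$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  if (length(x$sets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$sets),
                                      vapply(x$sets, length, 1L)),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh A [fem_mesh()].
#' @return Numeric vector of signed volumes (mm^3), positive for correctly
#'   oriented elements.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cc <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Constant shape-function gradients of the linear tetrahedra.
# Returns a list: G is a (4m) x 3 matrix (rows 4(e-1)+a give grad N_a of
# element e in the reference configuration), V the element volumes.
shape_gradients <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  m <- nrow(el)
  G <- matrix(0, 4 * m, 3)
  V <- numeric(m)
  for (e in seq_len(m)) {
    X <- nd[el[e, ], ]
    D <- cbind(1, X)
    Dinv <- solve(D)                     # rows: coefficients of N_a
    G[4 * (e - 1) + 1:4, ] <- t(Dinv[2:4, ])
    V[e] <- det(D) / 6
  }
  list(G = G, V = V)
}

# Map each named set through a node renumbering (used by IO round-trips).
mesh_set_nodes <- function(mesh, name) {
  s <- mesh$sets[[name]]
  if (is.null(s)) stop(sprintf("mesh has no node set named '%s'", name))
  s
}
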