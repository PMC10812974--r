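# Structured tetrahedral mesh generation.
#
# All block meshes are built from structured hexahedral grids split by the
# Kuhn (Freudenthal) subdivision into 6 tetrahedra per cell. Every face of a
# Kuhn-split cube is cut along the diagonal from its index-minimal to its
# index-maximal corner, so two blocks sharing a full grid of node ids with
# aligned, increasing index axes produce a conforming interface.

kuhn_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# Tets of a structured block given its 3D array of global node ids.
# Returns list(conn = m x 4, cell = parent-cell linear index).
block_tets <- function(ids) {
  d <- dim(ids)
  n1 <- d[1] - 1; n2 <- d[2] - 1; n3 <- d[3] - 1
  corner <- function(di, dj, dk)
    as.vector(ids[(1:n1) + di, (1:n2) + dj, (1:n3) + dk])
  ncell <- n1 * n2 * n3
  conn <- vector("list", 6)
  for (p in seq_along(kuhn_perms)) {
    perm <- kuhn_perms[[p]]
    off <- matrix(0L, 4, 3)
    off[2, perm[1]] <- 1L
    off[3, ] <- off[2, ]; off[3, perm[2]] <- 1L
    off[4, ] <- 1L
    conn[[p]] <- cbind(corner(off[1, 1], off[1, 2], off[1, 3]),
                       corner(off[2, 1], off[2, 2], off[2, 3]),
                       corner(off[3, 1], off[3, 2], off[3, 3]),
                       corner(off[4, 1], off[4, 2], off[4, 3]))
  }
  list(conn = do.call(rbind, conn),
       cell = rep.int(seq_len(ncell), 6L))
}

# Node accumulator shared by all blocks of one mesh.
node_pool <- function() {
  env <- new.env(parent = emptyenv())
  env$coords <- list()
  env$n <- 0L
  env$add <- function(xyz) {
    xyz <- matrix(xyz, ncol = 3)
    ids <- env$n + seq_len(nrow(xyz))
    env$coords[[length(env$coords) + 1L]] <- xyz
    env$n <- env$n + nrow(xyz)
    ids
  }
  env$all <- function() do.call(rbind, env$coords)
  env
}

# Fill the NA entries of a block id array, creating nodes at coord_fn(i,j,k)
# (1-based block indices). Pre-assigned entries are kept (shared interfaces).
fill_block_ids <- function(ids, pool, coord_fn) {
  d <- dim(ids)
  idx <- which(is.na(ids), arr.ind = TRUE)
  if (nrow(idx)) {
    xyz <- t(apply(idx, 1, function(r) coord_fn(r[1], r[2], r[3])))
    ids[idx] <- pool$add(xyz)
  }
  ids
}

# Square-to-disc cross-section template: (q+1)^2 grid on [-1,1]^2 mapped so
# boundary nodes lie on the unit circle, then scaled so the polygonal
# cross-section area equals pi (volume-conservative meshing).
cross_template <- function(q) {
  s <- seq(-1, 1, length.out = q + 1)
  u <- outer(s, s, function(a, b) a * sqrt(1 - b^2 / 2))
  v <- outer(s, s, function(a, b) b * sqrt(1 - a^2 / 2))
  area <- 0
  for (i in 1:q) for (j in 1:q) {
    x <- c(u[i, j], u[i + 1, j], u[i + 1, j + 1], u[i, j + 1])
    y <- c(v[i, j], v[i + 1, j], v[i + 1, j + 1], v[i, j + 1])
    area <- area + abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  scl <- sqrt(pi / area)
  list(u = u * scl, v = v * scl, q = q)
}

# Enforce positive orientation by swapping the last two nodes of inverted
# tets (does not affect face conformity).
orient_tets <- function(nodes, conn) {
  a <- nodes[conn[, 2], , drop = FALSE] - nodes[conn[, 1], , drop = FALSE]
  b <- nodes[conn[, 3], , drop = FALSE] - nodes[conn[, 1], , drop = FALSE]
  cc <- nodes[conn[, 4], , drop = FALSE] - nodes[conn[, 1], , drop = FALSE]
  v6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  neg <- v6 < 0
  if (any(neg)) conn[neg, 3:4] <- conn[neg, 4:3]
  conn
}

#' Unit validation fixtures
#'
#' Small watertight meshes used by the uniaxial validation suite: a single
#' tetrahedron, or the unit cube subdivided into a structured grid with six
#' tetrahedra per cell. Face node sets are named `x0, x1, y0, y1, z0, z1`.
#'
#' @param kind `"single_tet"` or `"unit_cube"`.
#' @param subdivisions Grid subdivisions per edge of the cube (`>= 1`).
#' @param region Region label given to all elements (default `"muscle"`).
#' @return A [fem_mesh()].
#' @examples
#' make_unit_fixture("unit_cube")   # 6 tetrahedra, volume 1
#' @export
make_unit_fixture <- function(kind = c("single_tet", "unit_cube"),
                              subdivisions = 1, region = "muscle") {
  kind <- match.arg(kind)
  stopifnot(subdivisions >= 1)
  if (kind == "single_tet") {
    nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    conn <- matrix(c(1L, 2L, 3L, 4L), 1)
  } else {
    s <- subdivisions
    g <- seq(0, 1, length.out = s + 1)
    ids <- array(seq_len((s + 1)^3), dim = c(s + 1, s + 1, s + 1))
    nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
    dimnames(nodes) <- NULL
    bt <- block_tets(ids)
    conn <- orient_tets(nodes, bt$conn)
  }
  tol <- 1e-12
  sets <- list(x0 = which(nodes[, 1] < tol),
               x1 = which(nodes[, 1] > 1 - tol),
               y0 = which(nodes[, 2] < tol),
               y1 = which(nodes[, 2] > 1 - tol),
               z0 = which(nodes[, 3] < tol),
               z1 = which(nodes[, 3] > 1 - tol))
  fem_mesh(nodes, conn, rep(region, nrow(conn)), sets,
           elem_patch = if (kind == "unit_cube") block_tets(
             array(seq_len((subdivisions + 1)^3),
                   dim = rep(subdivisions + 1, 3)))$cell else NULL)
}

#' Straight cylinder fixture
#'
#' A structured cylinder along the z axis with end-cap node sets `z0` and
#' `z1`, used to validate the fiber-field Laplace solver (the axial
#' potential is exactly linear there).
#'
#' @param length Cylinder length (mm).
#' @param radius Cylinder radius (mm).
#' @param n_axial Number of axial element layers.
#' @param q Cross-section grid divisions per side.
#' @param region Region label (default `"muscle"`).
#' @return A [fem_mesh()].
#' @export
make_cylinder_fixture <- function(length = 50, radius = 5, n_axial = 10,
                                  q = 2, region = "muscle") {
  tmpl <- cross_template(q)
  pool <- node_pool()
  ids <- array(NA_integer_, dim = c(q + 1, q + 1, n_axial + 1))
  z <- seq(0, length, length.out = n_axial + 1)
  ids <- fill_block_ids(ids, pool, function(i, j, k)
    c(radius * tmpl$u[i, j], radius * tmpl$v[i, j], z[k]))
  nodes <- pool$all()
  bt <- block_tets(ids)
  conn <- orient_tets(nodes, bt$conn)
  sets <- list(z0 = as.vector(ids[, , 1]),
               z1 = as.vector(ids[, , n_axial + 1]))
  fem_mesh(nodes, conn, rep(region, nrow(conn)), sets,
           elem_patch = bt$cell)
}

#' Parameters of the synthetic forearm geometry
#'
#' Generative parameters of the idealized three-region forearm: a slender
#' cylindrical radius (bone) along +x, a fusiform biceps (muscle) with a
#' sinusoidal radius profile on an inclined axis in the sagittal x-z plane,
#' tendon straps continuing both muscle ends, and a tendon bridge tying the
#' distal strap to the radius surface near its proximal quarter (the
#' insertion). Axes: x distal, z vertical (loads act along -z), y
#' mediolateral. The default scale (250 mm radius, 200 mm muscle) is
#' representative of an adult forearm, not taken from any specific subject.
#'
#' @param radius_length,radius_radius Bone length and radius (mm).
#' @param muscle_length,muscle_max_radius Muscle length and maximal
#'   (mid-belly) radius (mm).
#' @param tendon_length Length of each tendon strap (mm).
#' @param tendon_radius Tendon strap radius (mm).
#' @param edge_length Target element edge length (mm); must be small enough
#'   to yield at least 200 elements.
#' @param muscle_angle Elevation of the muscle axis above the bone axis
#'   (degrees).
#' @param bridge_height Clearance between the distal tendon cap and the bone
#'   surface, spanned by the insertion bridge (mm).
#' @param insertion_frac Axial position of the insertion centre as a
#'   fraction of the bone length.
#' @param aponeurosis_frac Fraction of the maximal muscle radius below
#'   which the tapered ends of the fusiform belly are labelled tendon
#'   (aponeurosis): the narrow necks funnel the whole muscle force and are
#'   collagenous in real muscle, not contractile.
#' @param q Cross-section grid divisions per side (even).
#' @param jitter Interior-node jitter amplitude as a fraction of
#'   `edge_length` (0 disables).
#' @param seed Random seed for the meshing jitter.
#' @return An object of class `forearm_params`.
#' @export
forearm_params <- function(radius_length = 250, radius_radius = 8,
                           muscle_length = 200, muscle_max_radius = 32,
                           tendon_length = 15, tendon_radius = 8,
                           edge_length = 10, muscle_angle = 50,
                           bridge_height = 12, insertion_frac = 0.3,
                           aponeurosis_frac = 0.45,
                           q = 2, jitter = 0, seed = 1) {
  stopifnot(radius_length > 0, radius_radius > 0, muscle_length > 0,
            muscle_max_radius > 0, tendon_length > 0, tendon_radius > 0,
            edge_length > 0, bridge_height > 0,
            insertion_frac > 0, insertion_frac < 1,
            aponeurosis_frac >= 0, aponeurosis_frac < 1,
            jitter >= 0, jitter < 0.5)
  if (q %% 2 != 0 || q < 2) stop("q must be an even integer >= 2")
  if (muscle_length >= radius_length + 2 * tendon_length)
    stop("muscle_length must be below radius_length plus tendon allowance")
  structure(as.list(environment()), class = "forearm_params")
}

#' Synthetic forearm mesh
#'
#' Generates the conforming three-region forearm mesh described in
#' [forearm_params()], with the node sets the scenario runners need:
#' `tendon_proximal_fixed` (free end of the proximal tendon),
#' `radius_proximal_pin` (single node at the proximal bone end),
#' `radius_y_restrained` (bone nodes within 10% of either bone end),
#' `radius_load` (distal bone end cap), `muscle_proximal` / `muscle_distal`
#' (muscle-tendon attachment cross-sections, the Dirichlet sets of the
#' fiber-field Laplace problem), and `insertion` (bone nodes shared with the
#' tendon bridge). Deterministic for fixed parameters and seed.
#'
#' @param params A [forearm_params()] object.
#' @return A [fem_mesh()] with a `forearm` attribute carrying the generative
#'   parameters and derived marker information.
#' @export
make_synthetic_forearm <- function(params = forearm_params()) {
  p <- params
  tmpl <- cross_template(p$q)
  pool <- node_pool()
  theta <- p$muscle_angle * pi / 180

  ## --- bone: straight tube along +x -----------------------------------
  nb <- max(4L, as.integer(round(p$radius_length / p$edge_length)))
  xb <- seq(0, p$radius_length, length.out = nb + 1)
  ids_b <- array(NA_integer_, dim = c(p$q + 1, p$q + 1, nb + 1))
  ids_b <- fill_block_ids(ids_b, pool, function(i, j, k)
    c(xb[k], p$radius_radius * tmpl$u[i, j], p$radius_radius * tmpl$v[i, j]))

  ## --- inclined tube: proximal tendon | muscle | distal tendon --------
  x_ins <- p$insertion_frac * p$radius_length
  d_ax <- c(-cos(theta), 0, sin(theta))          # distal cap -> origin
  a1 <- c(0, 1, 0)                               # cross axis 1 (mediolateral)
  a2 <- c(sin(theta), 0, cos(theta))             # cross axis 2 (sagittal)
  # the insertion bridge continues the tube axis down to the bone surface,
  # so the tendon force path stays straight (a kinked bridge would bend the
  # very soft muscle belly and wrinkle it)
  Q1 <- c(x_ins, 0, p$radius_radius) + p$bridge_height * d_ax
  nt <- max(2L, as.integer(round(p$tendon_length / p$edge_length)))
  nm <- max(6L, as.integer(round(p$muscle_length / p$edge_length)))
  L_tube <- p$muscle_length + 2 * p$tendon_length
  s_st <- c(seq(0, p$tendon_length, length.out = nt + 1),
            seq(p$tendon_length, p$tendon_length + p$muscle_length,
                length.out = nm + 1)[-1],
            seq(p$tendon_length + p$muscle_length, L_tube,
                length.out = nt + 1)[-1])         # arclength from distal cap
  r_st <- vapply(s_st, function(s) {
    sm <- s - p$tendon_length
    if (sm <= 0 || sm >= p$muscle_length) p$tendon_radius
    else p$tendon_radius + (p$muscle_max_radius - p$tendon_radius) *
        sin(pi * sm / p$muscle_length)
  }, 1)
  K <- length(s_st) - 1L
  # muscle belly layers: the tapered necks of the fusiform profile below
  # aponeurosis_frac of the maximal radius stay tendon (aponeurosis), as
  # the narrow ends funnel the full muscle force
  r_mid <- (r_st[-1] + r_st[-length(r_st)]) / 2
  belly <- seq_len(K) > nt & seq_len(K) <= nt + nm &
    r_mid >= p$aponeurosis_frac * p$muscle_max_radius
  if (!any(belly))
    stop("aponeurosis_frac leaves no muscle belly; decrease it")
  k_mus_lo <- min(which(belly))          # distal-most muscle layer
  k_mus_hi <- max(which(belly))          # proximal-most muscle layer
  # station order along +k runs distal cap -> proximal free end
  ids_t <- array(NA_integer_, dim = c(p$q + 1, p$q + 1, K + 1))
  ids_t <- fill_block_ids(ids_t, pool, function(i, j, k) {
    ctr <- Q1 + s_st[k] * d_ax
    ctr + r_st[k] * (tmpl$u[i, j] * a1 + tmpl$v[i, j] * a2)
  })
  ## --- insertion bridge: bone surface patch -> distal tendon cap ------
  # patch: bone top arc (j = q+1 face), q+1 axial stations centred on x_ins
  ka <- as.integer(round(x_ins / (p$radius_length / nb))) - p$q %/% 2
  ka <- max(1L, min(ka, nb + 1L - p$q))
  patch <- ids_b[, p$q + 1, ka:(ka + p$q)]       # (q+1) x (q+1): i=y, j=x
  cap <- ids_t[, , 1]                            # (q+1) x (q+1): i=y, j=a2
  nL <- max(2L, as.integer(round(p$bridge_height / p$edge_length)))
  ids_br <- array(NA_integer_, dim = c(p$q + 1, p$q + 1, nL + 1))
  ids_br[, , 1] <- patch
  ids_br[, , nL + 1] <- cap
  all_known <- pool$all()
  ids_br <- fill_block_ids(ids_br, pool, function(i, j, k) {
    w <- (k - 1) / nL
    (1 - w) * all_known[patch[i, j], ] + w * all_known[cap[i, j], ]
  })

  nodes <- pool$all()

  ## --- optional interior jitter ---------------------------------------
  if (p$jitter > 0) {
    boundary <- unique(c(as.vector(ids_b[, , c(1, nb + 1)]),
                         as.vector(ids_b[, p$q + 1, ]),
                         as.vector(ids_t[, , c(1, K + 1)]),
                         as.vector(ids_t[, , c(k_mus_lo, k_mus_hi + 1)]),
                         as.vector(patch), as.vector(cap)))
    interior <- setdiff(seq_len(nrow(nodes)), boundary)
    set.seed(p$seed)
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::runif(3 * length(interior), -1, 1),
             ncol = 3) * p$jitter * p$edge_length
  }

  bt_b <- block_tets(ids_b)
  bt_t <- block_tets(ids_t)
  bt_br <- block_tets(ids_br)
  conn <- rbind(bt_b$conn, bt_t$conn, bt_br$conn)
  conn <- orient_tets(nodes, conn)
  # region per tube tet via its parent cell's axial layer (tendon |
  # muscle belly | tendon, counted from the distal cap)
  cell_layer <- ((bt_t$cell - 1L) %/% (p$q^2)) + 1L
  tube_cell_region <- rep("tendon", K)
  tube_cell_region[belly] <- "muscle"
  region <- c(rep("bone", nrow(bt_b$conn)),
              tube_cell_region[cell_layer],
              rep("tendon", nrow(bt_br$conn)))
  patch_id <- c(bt_b$cell,
                max(bt_b$cell) + bt_t$cell,
                max(bt_b$cell) + max(bt_t$cell) + bt_br$cell)

  ## --- node sets -------------------------------------------------------
  ctr <- p$q %/% 2 + 1L
  x_lo <- 0.1 * p$radius_length
  bone_ids <- as.vector(ids_b)
  sets <- list(
    tendon_proximal_fixed = as.vector(ids_t[, , K + 1]),
    radius_proximal_pin = ids_b[ctr, ctr, 1],
    radius_y_restrained = bone_ids[nodes[bone_ids, 1] < x_lo |
                                     nodes[bone_ids, 1] > p$radius_length - x_lo],
    radius_load = as.vector(ids_b[, , nb + 1]),
    muscle_proximal = as.vector(ids_t[, , k_mus_hi + 1]),
    muscle_distal = as.vector(ids_t[, , k_mus_lo]),
    insertion = as.vector(patch))

  mesh <- fem_mesh(nodes, conn, region, sets, elem_patch = patch_id)
  if (nrow(conn) < 200)
    stop("edge_length too coarse: fewer than 200 elements generated")
  # closed-form volume of the muscle belly: the fusiform solid of
  # revolution r(s) = r_t + (R - r_t) sin(pi s / L) truncated where
  # r >= aponeurosis_frac * R
  rt <- p$tendon_radius; R <- p$muscle_max_radius; L <- p$muscle_length
  c0 <- max(0, min(1, (p$aponeurosis_frac * R - rt) / (R - rt)))
  th0 <- asin(c0)
  v_belly <- L * (rt^2 * (pi - 2 * th0) +
                         4 * rt * (R - rt) * cos(th0) +
                         (R - rt)^2 * ((pi - 2 * th0) / 2 +
                                         sin(2 * th0) / 2))
  attr(mesh, "forearm") <- list(
    params = p,
    bridge_elems = nrow(bt_b$conn) + nrow(bt_t$conn) +
      seq_len(nrow(bt_br$conn)),
    pin_node = sets$radius_proximal_pin,
    load_nodes = sets$radius_load,
    muscle_axis = -d_ax,
    analytic_volumes = c(
      bone = pi * p$radius_radius^2 * p$radius_length,
      muscle = v_belly))
  mesh
}

#' Minimum dihedral angle of a mesh
#'
#' Mesh-quality diagnostic: the smallest dihedral angle over all element
#' edges, in degrees.
#'
#' @param mesh A [fem_mesh()].
#' @return Scalar angle in degrees.
#' @export
min_dihedral_angle <- function(mesh) {
  faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  nd <- mesh$nodes
  worst <- 180
  for (e in seq_len(nrow(mesh$elems))) {
    v <- mesh$elems[e, ]
    nrm <- lapply(faces, function(f) {
      a <- nd[v[f[2]], ] - nd[v[f[1]], ]
      b <- nd[v[f[3]], ] - nd[v[f[1]], ]
      n <- c(a[2] * b[3] - a[3] * b[2],
             a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
      n / sqrt(sum(n^2))
    })
    for (i in 1:3) for (j in (i + 1):4) {
      ang <- acos(pmin(1, pmax(-1, -sum(nrm[[i]] * nrm[[j]])))) * 180 / pi
      if (ang < worst) worst <- ang
    }
  }
  worst
}
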