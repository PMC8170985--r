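# Hex8 reference element: trilinear shape functions, 2x2x2 Gauss quadrature.
# Node ordering follows the usual solid-element convention:
# (-,-,-),(+,-,-),(+,+,-),(-,+,-),(-,-,+),(+,-,+),(+,+,+),(-,+,+).
HEX8_XI <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

HEX8_FACES <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                   c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))

# dN/dxi (8x3) at natural coordinates xi
hex8_dN <- function(xi) {
  g <- HEX8_XI
  cbind(
    0.125 * g[, 1] * (1 + g[, 2] * xi[2]) * (1 + g[, 3] * xi[3]),
    0.125 * g[, 2] * (1 + g[, 1] * xi[1]) * (1 + g[, 3] * xi[3]),
    0.125 * g[, 3] * (1 + g[, 1] * xi[1]) * (1 + g[, 2] * xi[2])
  )
}

# 2x2x2 Gauss points (weight 1 each) and their shape-gradient matrices
HEX8_GP <- local({
  a <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-a, a), eta = c(-a, a), zeta = c(-a, a)))
  lapply(seq_len(nrow(pts)), function(i) hex8_dN(pts[i, ]))
})

#' Hexahedral finite-element mesh
#'
#' @param nodes N x 3 matrix of node coordinates (m).
#' @param elements E x 8 integer matrix of node indices per 8-node solid
#'   element, consistently oriented (positive Jacobian).
#' @param part Integer part id per element (default all 1).
#' @return An object of class `fe_mesh` with precomputed reference
#'   shape-function gradients and element volumes.
#' @export
fe_mesh <- function(nodes, elements, part = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) ff_stop("foamfem_invalid_mesh", "nodes must be N x 3")
  if (ncol(elements) != 8L) ff_stop("foamfem_invalid_mesh", "elements must be E x 8")
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    ff_stop("foamfem_invalid_mesh", "element connectivity references missing nodes")
  }
  part <- as.integer(part %||% rep(1L, nrow(elements)))
  if (length(part) != nrow(elements)) {
    ff_stop("foamfem_invalid_mesh", "part must have one id per element")
  }
  E <- nrow(elements)
  dNdX <- vector("list", E)       # per element: list of 8 (8x3) gradients
  dV <- matrix(0, E, 8L)          # per element/gauss-point reference volume
  for (e in seq_len(E)) {
    Xe <- nodes[elements[e, ], , drop = FALSE]
    grads <- vector("list", 8L)
    for (g in 1:8) {
      dN <- HEX8_GP[[g]]
      Jm <- crossprod(dN, Xe)     # dx_k/dxi_l in [l, k]
      detJ <- det(Jm)
      if (detJ <= 0) {
        ff_stop("foamfem_invalid_mesh",
                "element %d has non-positive reference Jacobian", e,
                data = list(element = e))
      }
      grads[[g]] <- dN %*% t(solve(Jm))
      dV[e, g] <- detJ
    }
    dNdX[[e]] <- grads
  }
  structure(list(nodes = nodes, elements = elements, part = part,
                 dNdX = dNdX, dV = dV, volumes = rowSums(dV)),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d hex8 elements, total volume %.6g m^3\n",
              nrow(x$nodes), nrow(x$elements), sum(x$volumes)))
  invisible(x)
}

#' Deformation states of an element's integration points
#'
#' Computes the deformation gradient from the trilinear shape-function
#' gradients at each of the 2x2x2 Gauss points, with the full spectral
#' kinematics needed by the material.
#'
#' @param mesh An [fe_mesh()].
#' @param u N x 3 nodal displacement matrix (m).
#' @param element Element index.
#' @return List of 8 [deformation_state()] objects.
#' @export
element_deformation <- function(mesh, u, element) {
  e <- as.integer(element)
  if (e < 1L || e > nrow(mesh$elements)) {
    ff_stop("foamfem_invalid_argument", "element %d does not exist", e)
  }
  idx <- mesh$elements[e, ]
  xe <- mesh$nodes[idx, , drop = FALSE] + u[idx, , drop = FALSE]
  lapply(1:8, function(g) {
    F <- crossprod(xe, mesh$dNdX[[e]][[g]])
    if (det(F) <= 0) {
      ff_stop("foamfem_negative_volume",
              "negative volume in element %d (gauss point %d)", e, g,
              data = list(element = e))
    }
    deformation_state(F)
  })
}

# Quad face area via half cross product of the diagonals (exact for planar
# quads, the standard estimate otherwise).
quad_area <- function(p1, p2, p3, p4) {
  d1 <- p3 - p1; d2 <- p4 - p2
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  0.5 * sqrt(sum(cr^2))
}

# Characteristic length per element: volume / largest face area
# (conservative hex estimate). Coordinates are current if u is supplied.
element_char_length <- function(mesh, u = NULL) {
  x <- mesh$nodes
  if (!is.null(u)) x <- x + u
  E <- nrow(mesh$elements)
  L <- numeric(E)
  for (e in seq_len(E)) {
    xe <- x[mesh$elements[e, ], , drop = FALSE]
    amax <- 0
    for (f in HEX8_FACES) {
      a <- quad_area(xe[f[1], ], xe[f[2], ], xe[f[3], ], xe[f[4], ])
      if (a > amax) amax <- a
    }
    vol <- element_current_volume(mesh, e, x)
    L[e] <- vol / amax
  }
  L
}

# Current element volume from the Gauss quadrature of det(J)
element_current_volume <- function(mesh, e, x) {
  xe <- x[mesh$elements[e, ], , drop = FALSE]
  v <- 0
  for (g in 1:8) {
    v <- v + det(crossprod(HEX8_GP[[g]], xe))
  }
  v
}

#' Build a structured box mesh of hex8 elements
#'
#' @param lengths Box edge lengths c(Lx, Ly, Lz) in m.
#' @param divisions Element counts c(nx, ny, nz).
#' @param origin Coordinates of the (0,0,0) corner, default the origin.
#' @return An [fe_mesh()].
#' @export
box_mesh <- function(lengths, divisions = c(1L, 1L, 1L), origin = c(0, 0, 0)) {
  L <- as.numeric(lengths); nd <- as.integer(divisions)
  if (length(L) != 3L || any(L <= 0)) ff_stop("foamfem_invalid_mesh", "lengths must be 3 positive values")
  if (length(nd) != 3L || any(nd < 1L)) ff_stop("foamfem_invalid_mesh", "divisions must be 3 positive counts")
  xs <- seq(0, L[1], length.out = nd[1] + 1L) + origin[1]
  ys <- seq(0, L[2], length.out = nd[2] + 1L) + origin[2]
  zs <- seq(0, L[3], length.out = nd[3] + 1L) + origin[3]
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nd[1] + 1L) * ((j - 1L) + (nd[2] + 1L) * (k - 1L))
  conn <- matrix(0L, prod(nd), 8L)
  e <- 0L
  for (k in seq_len(nd[3])) for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                   nid(i, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                   nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  }
  fe_mesh(nodes, conn)
}
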