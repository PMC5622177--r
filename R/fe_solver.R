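#' @import Matrix
NULL

# 24 x 24 stiffness matrix of an 8-node trilinear brick with edge lengths h
# (mm), unit modulus (GPa) and Poisson ratio nu, by 2x2x2 Gauss quadrature.
# Local corner ordering matches buildVoxelMesh (1-4 CCW lower face, 5-8 top).
hexStiffness <- function(h, nu) {
  sg <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
              c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  detJ <- prod(h) / 8
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    dN <- cbind(sg[, 1] * (1 + sg[, 2] * gy) * (1 + sg[, 3] * gz),
                sg[, 2] * (1 + sg[, 1] * gx) * (1 + sg[, 3] * gz),
                sg[, 3] * (1 + sg[, 1] * gx) * (1 + sg[, 2] * gy)) / 8
    dNdx <- sweep(dN, 2, h / 2, "/")     # d/dx = d/dxi * 2/h
    B <- matrix(0, 6, 24)
    ix <- 3 * (1:8) - 2
    B[1, ix] <- dNdx[, 1]
    B[2, ix + 1] <- dNdx[, 2]
    B[3, ix + 2] <- dNdx[, 3]
    B[4, ix] <- dNdx[, 2]; B[4, ix + 1] <- dNdx[, 1]
    B[5, ix + 1] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 2]
    B[6, ix] <- dNdx[, 3]; B[6, ix + 2] <- dNdx[, 1]
    Ke <- Ke + t(B) %*% D %*% B * detJ
  }
  (Ke + t(Ke)) / 2
}

#' FESystem: assembled global stiffness system
#'
#' @slot K sparse symmetric global stiffness matrix (kN/mm per dof).
#' @slot mesh the [HexMesh-class] it was assembled from.
#' @slot materials the [MaterialField-class] used.
#' @export
setClass("FESystem",
  representation(K = "ANY", mesh = "HexMesh", materials = "MaterialField"))

setMethod("show", "FESystem", function(object) {
  cat(sprintf("FESystem: %d dof, %d elements\n", nrow(object@K),
              nrow(object@mesh@elements)))
})

#' Assemble the global linear-elastic stiffness system
#'
#' Standard small-strain isotropic Hooke elasticity on 8-node trilinear
#' bricks with 2x2x2 Gauss quadrature. Because every element is a voxel of
#' identical geometry, the unit-modulus element matrix is computed once and
#' scaled by each element's modulus. Units mm/GPa give forces in kN.
#'
#' @param mesh a [HexMesh-class].
#' @param materials a [MaterialField-class] with one modulus per element.
#' @return An [FESystem-class].
#' @export
assembleStiffness <- function(mesh, materials) {
  stopifnot(is(mesh, "HexMesh"), is(materials, "MaterialField"),
            length(materials@E) == nrow(mesh@elements))
  if (any(mesh@spacing <= 0)) stop("degenerate element geometry")
  nNode <- nrow(mesh@nodes)
  Ke <- hexStiffness(mesh@spacing, materials@nu)
  el <- mesh@elements
  edof <- matrix(0L, nrow(el), 24L)
  for (a in 1:8) {
    base <- 3L * el[, a]
    edof[, 3L * a - 2L] <- base - 2L
    edof[, 3L * a - 1L] <- base - 1L
    edof[, 3L * a] <- base
  }
  ii <- edof[, rep(1:24, times = 24), drop = FALSE]
  jj <- edof[, rep(1:24, each = 24), drop = FALSE]
  xx <- outer(materials@E, as.vector(Ke))
  K <- sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(xx),
                    dims = c(3L * nNode, 3L * nNode))
  new("FESystem", K = K, mesh = mesh, materials = materials)
}

# Solve K[free,free] u_free = -K[free,fixed] u_fixed by sparse Cholesky,
# falling back to conjugate gradients for very large systems.
solveReduced <- function(Kred, f) {
  n <- nrow(Kred)
  if (n <= 3e5) {
    ch <- tryCatch(suppressWarnings(Cholesky(forceSymmetric(Kred),
                                             LDL = FALSE)),
                   error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    as.numeric(solve(ch, f))
  } else {
    x <- numeric(n)
    r <- f - as.numeric(Kred %*% x)
    dPre <- Matrix::diag(Kred)
    z <- r / dPre
    p <- z
    rz <- sum(r * z)
    f2 <- sqrt(sum(f^2))
    for (it in seq_len(20000L)) {
      Kp <- as.numeric(Kred %*% p)
      a <- rz / sum(p * Kp)
      x <- x + a * p
      r <- r - a * Kp
      if (sqrt(sum(r^2)) <= 1e-9 * f2) break
      z <- r / dPre
      rzNew <- sum(r * z)
      p <- z + (rzNew / rz) * p
      rz <- rzNew
    }
    x
  }
}

# Count mesh components by node-sharing (union-find over elements); used to
# explain singular constrained systems.
diagnoseSingular <- function(mesh) {
  el <- mesh@elements
  parent <- seq_len(nrow(mesh@nodes))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(el))) {
    r <- find(el[e, 1])
    for (a in 2:8) { r2 <- find(el[e, a]); if (r2 != r) parent[r2] <- r }
  }
  roots <- unique(vapply(unique(as.vector(el)), find, 0L))
  length(roots)
}

#' Solve the axial compression load case
#'
#' In the default `"tied"` mode the bottom node set is clamped and the top
#' node set is coupled to a rigid plate through a linearised rigid-body
#' constraint `u = u_ref + theta x (x - x_ref)` with a 6-dof reference
#' point: the reference axial translation is prescribed, lateral
#' translations are fixed and all three rotations are left free, matching a
#' ball-loaded plate. In `"uniaxial-oracle"` mode only axial displacements
#' are prescribed on both faces, lateral motion is free and rigid-body modes
#' are pinned, so that uniform-strain states are represented exactly
#' (closed-form EA/L and series-spring answers hold to machine precision).
#'
#' @param system an [FESystem-class] from [assembleStiffness()].
#' @param loadcase a [LoadCase-class].
#' @return An [FEResult-class]. The apparent stiffness is the axial reaction
#'   at the loading surface divided by the prescribed displacement.
#' @export
solveCompression <- function(system, loadcase = loadCase()) {
  stopifnot(is(system, "FESystem"), is(loadcase, "LoadCase"))
  mesh <- system@mesh
  K <- system@K
  ndof <- nrow(K)
  bottom <- mesh@nodeSets[[loadcase@clampedSet]]
  top <- mesh@nodeSets[[loadcase@plateSet]]
  if (!length(bottom) || !length(top))
    stop("clamped and plate node sets must be non-empty")
  if (length(intersect(bottom, top)))
    stop("clamped and plate node sets must be disjoint")
  delta <- loadcase@displacement
  nodeDofs <- function(nodes, comp) 3L * (nodes - 1L) + comp

  if (loadcase@mode == "tied") {
    xref <- if (length(loadcase@referencePoint) == 3L) loadcase@referencePoint
            else c(colMeans(mesh@nodes[top, 1:2, drop = FALSE]),
                   max(mesh@nodes[top, 3]))
    fixedDofs <- c(nodeDofs(bottom, 1L), nodeDofs(bottom, 2L), nodeDofs(bottom, 3L))
    plateDofs <- c(nodeDofs(top, 1L), nodeDofs(top, 2L), nodeDofs(top, 3L))
    freeDofs <- setdiff(seq_len(ndof), c(fixedDofs, plateDofs))
    nf <- length(freeDofs)
    # transformation u = T q + g; q = [free dofs, theta_x, theta_y, theta_z]
    r <- sweep(mesh@nodes[top, , drop = FALSE], 2, xref)
    nTop <- length(top)
    Ti <- c(freeDofs,
            nodeDofs(top, 1L), nodeDofs(top, 1L),   # ux <- ry*.., rz*..
            nodeDofs(top, 2L), nodeDofs(top, 2L),
            nodeDofs(top, 3L), nodeDofs(top, 3L))
    Tj <- c(seq_len(nf),
            rep(nf + 2L, nTop), rep(nf + 3L, nTop),  # ux: theta_y, theta_z
            rep(nf + 3L, nTop), rep(nf + 1L, nTop),  # uy: theta_z, theta_x
            rep(nf + 1L, nTop), rep(nf + 2L, nTop))  # uz: theta_x, theta_y
    Tx <- c(rep(1, nf),
            r[, 3], -r[, 2],
            r[, 1], -r[, 3],
            r[, 2], -r[, 1])
    Tm <- sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(ndof, nf + 3L))
    g <- numeric(ndof)
    g[nodeDofs(top, 3L)] <- delta
    Kred <- forceSymmetric(crossprod(Tm, K %*% Tm))
    f <- -as.numeric(crossprod(Tm, K %*% g))
    q <- solveReduced(Kred, f)
    if (is.null(q)) {
      ncomp <- diagnoseSingular(mesh)
      stop("singular constrained system",
           if (ncomp > 1L) paste0(": mesh has ", ncomp,
                                  " disconnected components") else "")
    }
    u <- as.numeric(Tm %*% q) + g
    theta <- q[nf + 1:3]
    resid <- sqrt(sum((as.numeric(Kred %*% q) - f)^2)) / max(sqrt(sum(f^2)), 1e-300)
    intF <- as.numeric(K %*% u)
    reaction <- sum(intF[nodeDofs(top, 3L)])
    clampReaction <- sum(intF[nodeDofs(bottom, 3L)])
  } else if (loadcase@mode == "tied-locked") {
    # rigid plate with rotations locked: plate nodes fully prescribed
    fixed <- c(nodeDofs(bottom, 1L), nodeDofs(bottom, 2L), nodeDofs(bottom, 3L),
               nodeDofs(top, 1L), nodeDofs(top, 2L), nodeDofs(top, 3L))
    uFixed <- numeric(ndof)
    uFixed[nodeDofs(top, 3L)] <- delta
    freeDofs <- setdiff(seq_len(ndof), fixed)
    f <- -as.numeric(K[freeDofs, , drop = FALSE] %*% uFixed)
    Kred <- forceSymmetric(K[freeDofs, freeDofs, drop = FALSE])
    uf <- solveReduced(Kred, f)
    if (is.null(uf)) {
      ncomp <- diagnoseSingular(mesh)
      stop("singular constrained system",
           if (ncomp > 1L) paste0(": mesh has ", ncomp,
                                  " disconnected components") else "")
    }
    u <- uFixed
    u[freeDofs] <- uf
    theta <- c(0, 0, 0)
    resid <- sqrt(sum((as.numeric(Kred %*% uf) - f)^2)) / max(sqrt(sum(f^2)), 1e-300)
    intF <- as.numeric(K %*% u)
    reaction <- sum(intF[nodeDofs(top, 3L)])
    clampReaction <- sum(intF[nodeDofs(bottom, 3L)])
  } else {
    # uniaxial oracle: axial Dirichlet on both faces, lateral free, pins
    bxy <- mesh@nodes[bottom, 1:2, drop = FALSE]
    o <- order(bxy[, 2], bxy[, 1])
    pinA <- bottom[o[1]]                       # fix ux, uy
    sameRow <- bottom[abs(mesh@nodes[bottom, 2] - mesh@nodes[pinA, 2]) < 1e-9 &
                      bottom != pinA]
    pinB <- if (length(sameRow)) sameRow[1] else bottom[o[2]]  # fix uy
    fixed <- c(nodeDofs(bottom, 3L), nodeDofs(top, 3L),
               nodeDofs(pinA, 1L), nodeDofs(pinA, 2L), nodeDofs(pinB, 2L))
    vals <- c(rep(0, length(bottom)), rep(delta, length(top)), 0, 0, 0)
    freeDofs <- setdiff(seq_len(ndof), fixed)
    uFixed <- numeric(ndof)
    uFixed[fixed] <- vals
    f <- -as.numeric(K[freeDofs, , drop = FALSE] %*% uFixed)
    Kred <- forceSymmetric(K[freeDofs, freeDofs, drop = FALSE])
    uf <- solveReduced(Kred, f)
    if (is.null(uf)) {
      ncomp <- diagnoseSingular(mesh)
      stop("singular constrained system",
           if (ncomp > 1L) paste0(": mesh has ", ncomp,
                                  " disconnected components") else "")
    }
    u <- uFixed
    u[freeDofs] <- uf
    theta <- c(0, 0, 0)
    resid <- sqrt(sum((as.numeric(Kred %*% uf) - f)^2)) / max(sqrt(sum(f^2)), 1e-300)
    intF <- as.numeric(K %*% u)
    reaction <- sum(intF[nodeDofs(top, 3L)])
    clampReaction <- sum(intF[nodeDofs(bottom, 3L)])
  }
  new("FEResult",
      displacements = matrix(u, ncol = 3L, byrow = TRUE),
      reactionForce = reaction,
      stiffness = reaction / delta,
      diagnostics = list(ndof = ndof, residual = resid,
                         equilibriumImbalance = reaction + clampReaction,
                         plateRotation = theta,
                         solver = if (ndof <= 3e5) "cholesky" else "cg"))
}

#' Per-element Gauss-point stresses of a solved model
#'
#' Recovers the 6-component engineering stress (xx, yy, zz, xy, yz, zx; GPa)
#' at each of the 8 Gauss points of every element, from a displacement
#' solution. Mainly used for uniform-strain patch testing.
#'
#' @param system an [FESystem-class].
#' @param result an [FEResult-class] from [solveCompression()].
#' @return An array `elements x 8 x 6`.
#' @export
elementStresses <- function(system, result) {
  mesh <- system@mesh
  nu <- system@materials@nu
  h <- mesh@spacing
  sg <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
              c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  gp <- 1 / sqrt(3)
  gpts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  u <- t(result@displacements)                  # 3 x N
  nEl <- nrow(mesh@elements)
  out <- array(0, c(nEl, 8, 6))
  Bs <- lapply(seq_len(8), function(g) {
    dN <- cbind(sg[, 1] * (1 + sg[, 2] * gpts[g, 2]) * (1 + sg[, 3] * gpts[g, 3]),
                sg[, 2] * (1 + sg[, 1] * gpts[g, 1]) * (1 + sg[, 3] * gpts[g, 3]),
                sg[, 3] * (1 + sg[, 1] * gpts[g, 1]) * (1 + sg[, 2] * gpts[g, 2])) / 8
    dNdx <- sweep(dN, 2, h / 2, "/")
    B <- matrix(0, 6, 24)
    ix <- 3 * (1:8) - 2
    B[1, ix] <- dNdx[, 1]; B[2, ix + 1] <- dNdx[, 2]; B[3, ix + 2] <- dNdx[, 3]
    B[4, ix] <- dNdx[, 2]; B[4, ix + 1] <- dNdx[, 1]
    B[5, ix + 1] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 2]
    B[6, ix] <- dNdx[, 3]; B[6, ix + 2] <- dNdx[, 1]
    D %*% B
  })
  for (e in seq_len(nEl)) {
    ue <- as.vector(u[, mesh@elements[e, ]])
    Ee <- system@materials@E[e]
    for (g in 1:8) out[e, g, ] <- Ee * as.numeric(Bs[[g]] %*% ue)
  }
  out
}

#' Apparent stiffness of a model with the conversion factor set to one
#'
#' Convenience for calibration: builds materials at `alpha = 1` and solves
#' the compression load case. For all-bone models (and, to numerical
#' precision, rigid-cement models) apparent stiffness is proportional to
#' alpha, so `K(alpha) = alpha * unitAlphaStiffness(...)`; with
#' deformable fixed-modulus cement the bone and cement act in series and
#' stiffness is only affine in alpha, so calibration must re-solve per
#' alpha.
#'
#' @param mesh a [HexMesh-class].
#' @param gray aligned gray8 [ImageVolume-class].
#' @param loadcase a [LoadCase-class].
#' @param ... passed to [assignMaterials()] (`ECement`, `nu`, `EFloor`,
#'   `rigidCement`).
#' @return Apparent stiffness at alpha = 1, kN/mm.
#' @export
unitAlphaStiffness <- function(mesh, gray, loadcase = loadCase(), ...) {
  mats <- assignMaterials(mesh, gray, alpha = 1, ...)
  apparentStiffness(solveCompression(assembleStiffness(mesh, mats), loadcase))
}
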