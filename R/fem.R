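## Desk-scale 2D FEM forward modelling and linear inverse: P1 triangular
## elements with point electrodes, adjoint-field sensitivity matrix,
## zeroth-order Tikhonov inversion with cross-validated hyperparameter, and a
## noise-based z-score correction of the reconstructed image.

#' Triangle areas of a mesh (signed positive for CCW elements)
#' @param mesh a \linkS4class{Mesh2D}.
#' @export
triangleAreas <- function(mesh) {
  n <- mesh@nodes; t <- mesh@triangles
  x1 <- n[t[, 1], 1]; y1 <- n[t[, 1], 2]
  x2 <- n[t[, 2], 1]; y2 <- n[t[, 2], 2]
  x3 <- n[t[, 3], 1]; y3 <- n[t[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Structured triangular mesh of the unit disc with boundary electrodes
#'
#' Polar-grid triangulation: \code{nRings} concentric rings of
#' \code{nTheta} nodes plus the centre; electrodes are placed on equally spaced
#' boundary nodes (so \code{nTheta} must be a multiple of \code{nElectrodes}).
#'
#' @param nElectrodes electrodes on the boundary.
#' @param nRings radial subdivisions.
#' @param nTheta angular subdivisions (default: smallest multiple of
#'   \code{nElectrodes} that is at least 16).
#' @param radius disc radius, m.
#' @param conductivity background conductivity, S/m.
#' @return a \linkS4class{Mesh2D}.
#' @export
discMesh <- function(nElectrodes = 16, nRings = 5, nTheta = NULL, radius = 1,
                     conductivity = 1) {
  if (is.null(nTheta))
    nTheta <- nElectrodes * max(1L, ceiling(16 / nElectrodes))
  if (nTheta %% nElectrodes != 0L)
    stop("nTheta must be a multiple of nElectrodes")
  nTheta <- as.integer(nTheta); nRings <- as.integer(nRings)
  theta <- 2 * pi * (seq_len(nTheta) - 1L) / nTheta
  nodes <- rbind(c(0, 0))
  for (k in seq_len(nRings)) {
    r <- radius * k / nRings
    nodes <- rbind(nodes, cbind(r * cos(theta), r * sin(theta)))
  }
  id <- function(ring, j) {          # ring 0 = centre
    if (ring == 0L) 1L else 1L + (ring - 1L) * nTheta + ((j - 1L) %% nTheta) + 1L
  }
  tris <- list()
  for (j in seq_len(nTheta))          # centre fan
    tris[[length(tris) + 1L]] <- c(id(0, 1), id(1, j), id(1, j + 1))
  if (nRings > 1L) {
    for (k in seq_len(nRings - 1L)) for (j in seq_len(nTheta)) {
      a <- id(k, j); b <- id(k, j + 1); c <- id(k + 1, j); d <- id(k + 1, j + 1)
      tris[[length(tris) + 1L]] <- c(a, c, d)
      tris[[length(tris) + 1L]] <- c(a, d, b)
    }
  }
  tri <- do.call(rbind, tris)
  storage.mode(tri) <- "integer"
  mesh <- new("Mesh2D", nodes = nodes, triangles = tri,
              electrodeNodes = integer(), conductivity = rep(conductivity, nrow(tri)))
  a <- triangleAreas(mesh)
  if (any(a < 0)) {                   # enforce CCW
    tri[a < 0, ] <- tri[a < 0, c(1, 3, 2)]
    mesh@triangles <- tri
  }
  step <- as.integer(nTheta / nElectrodes)
  mesh@electrodeNodes <- vapply(seq_len(nElectrodes), function(e)
    id(nRings, 1L + (e - 1L) * step), integer(1))
  validObject(mesh)
  mesh
}

#' Read / write a mesh as plain-text node and element files
#'
#' Nodes: one \code{x y} pair per line. Elements: one \code{n1 n2 n3} triple
#' per line (1-based). Electrodes: one boundary node index per line.
#'
#' @param nodeFile,elemFile,electrodeFile text file paths.
#' @param conductivity per-element conductivity (recycled).
#' @export
readMeshText <- function(nodeFile, elemFile, electrodeFile, conductivity = 1) {
  nodes <- as.matrix(read.table(nodeFile))
  tri <- as.matrix(read.table(elemFile))
  storage.mode(tri) <- "integer"
  el <- as.integer(read.table(electrodeFile)[[1]])
  dimnames(nodes) <- NULL; dimnames(tri) <- NULL
  mesh <- new("Mesh2D", nodes = nodes, triangles = tri, electrodeNodes = el,
              conductivity = rep_len(conductivity, nrow(tri)))
  validObject(mesh)
  mesh
}

#' @rdname readMeshText
#' @param mesh a \linkS4class{Mesh2D}.
#' @export
writeMeshText <- function(mesh, nodeFile, elemFile, electrodeFile) {
  write.table(mesh@nodes, nodeFile, row.names = FALSE, col.names = FALSE)
  write.table(mesh@triangles, elemFile, row.names = FALSE, col.names = FALSE)
  writeLines(as.character(mesh@electrodeNodes), electrodeFile)
  invisible(NULL)
}

## Per-element shape-function gradients: list(b, c) with rows = elements.
shapeGradients <- function(mesh) {
  n <- mesh@nodes; t <- mesh@triangles
  x <- matrix(n[t, 1], ncol = 3); y <- matrix(n[t, 2], ncol = 3)
  A <- triangleAreas(mesh)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * A)
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * A)
  list(b = b, c = cc, area = A)
}

#' Assemble the FEM forward model
#'
#' Builds the P1 stiffness matrix for \code{div(sigma grad u) = 0} with point
#' electrodes, grounds one node for solvability and caches a Cholesky
#' factorisation of the reduced system.
#'
#' @param mesh a \linkS4class{Mesh2D}.
#' @return a \linkS4class{ForwardModel}.
#' @export
forwardModel <- function(mesh) {
  g <- shapeGradients(mesh)
  t <- mesh@triangles
  nn <- nrow(mesh@nodes)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, b]
    vv[[k]] <- mesh@conductivity * g$area *
      (g$b[, a] * g$b[, b] + g$c[, a] * g$c[, b])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(nn, nn))
  ground <- 1L
  free <- setdiff(seq_len(nn), ground)
  Kred <- K[free, free]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kred), LDL = FALSE)
  new("ForwardModel", mesh = mesh, stiffness = K, groundNode = ground,
      factor = fac)
}

## Nodal potential for unit current in at node src, out at node snk.
solvePotential <- function(fm, src, snk, currentA = 1) {
  nn <- nrow(fm@mesh@nodes)
  b <- numeric(nn)
  b[src] <- b[src] + currentA
  b[snk] <- b[snk] - currentA
  free <- setdiff(seq_len(nn), fm@groundNode)
  u <- numeric(nn)
  u[free] <- as.numeric(Matrix::solve(fm@factor, b[free]))
  u
}

#' Solve the forward problem for one injection pair
#'
#' @param fm a \linkS4class{ForwardModel} (or a \linkS4class{Mesh2D}, which is
#'   assembled first).
#' @param pair length-2 vector of (source, sink) electrode indices.
#' @param currentA injected current, amperes.
#' @return electrode voltages (volts), referenced to zero mean over electrodes.
#' @export
forwardSolve <- function(fm, pair, currentA = 1) {
  if (is(fm, "Mesh2D")) fm <- forwardModel(fm)
  el <- fm@mesh@electrodeNodes
  u <- solvePotential(fm, el[pair[1L]], el[pair[2L]], currentA)
  v <- u[el]
  v - mean(v)
}

#' Full transfer table / phantom model from a FEM mesh
#'
#' Solves the forward problem for every pair of a protocol and returns the
#' signed transfer impedances (ohms: volts per ampere) as a
#' \linkS4class{PhantomModel}, optionally dispersive.
#'
#' @param mesh a \linkS4class{Mesh2D}.
#' @param protocol an \linkS4class{InjectionProtocol} (electrode count must
#'   match the mesh).
#' @param dispersion gain function of frequency.
#' @param scale scalar multiplier on the transfer impedances (e.g. to convert
#'   a unit-conductivity solution to a physical load).
#' @export
femPhantom <- function(mesh, protocol, dispersion = function(f) rep(1, length(f)),
                       scale = 1) {
  if (length(mesh@electrodeNodes) != nElectrodes(protocol))
    stop("mesh and protocol electrode counts differ")
  fm <- forwardModel(mesh)
  p <- protocolPairs(protocol)
  tr <- t(vapply(seq_len(nrow(p)), function(i) forwardSolve(fm, p[i, ], 1),
                 numeric(length(mesh@electrodeNodes))))
  phantomModel(tr * scale, dispersion)
}

#' Adjoint-field sensitivity (Jacobian) matrix
#'
#' \code{J[m, e] = -area_e * grad(u_drive) . grad(u_meas)} on element e for
#' measurement m, per unit conductivity change; the measurement field is the
#' adjoint solution for a unit current at the measurement electrode balanced
#' against the mean-reference over all electrodes. Rows are ordered as the
#' protocol's measurements (pair-major, electrode-minor), restricted to
#' \code{retained} when given.
#'
#' @param mesh a \linkS4class{Mesh2D}.
#' @param protocol an \linkS4class{InjectionProtocol}.
#' @param retained optional logical matrix pairs x electrodes (TRUE = keep) or
#'   two-column index matrix; default: all pairs x electrodes.
#' @return list with \code{J} (measurements x elements), \code{rows}
#'   (data.frame pair, electrode) and \code{fm} (the forward model).
#' @export
jacobianMatrix <- function(mesh, protocol, retained = NULL) {
  fm <- forwardModel(mesh)
  el <- fm@mesh@electrodeNodes
  ne <- length(el)
  np <- nPairs(protocol)
  p <- protocolPairs(protocol)
  g <- shapeGradients(mesh)
  tri <- mesh@triangles

  gradOf <- function(u) {
    ux <- g$b[, 1] * u[tri[, 1]] + g$b[, 2] * u[tri[, 2]] + g$b[, 3] * u[tri[, 3]]
    uy <- g$c[, 1] * u[tri[, 1]] + g$c[, 2] * u[tri[, 2]] + g$c[, 3] * u[tri[, 3]]
    cbind(ux, uy)
  }
  drive <- lapply(seq_len(np), function(i)
    gradOf(solvePotential(fm, el[p[i, 1]], el[p[i, 2]], 1)))
  # adjoint measurement fields: unit current at electrode k, balanced -1/ne at all
  meas <- lapply(seq_len(ne), function(k) {
    nn <- nrow(mesh@nodes)
    b <- numeric(nn)
    b[el] <- b[el] - 1 / ne
    b[el[k]] <- b[el[k]] + 1
    free <- setdiff(seq_len(nn), fm@groundNode)
    u <- numeric(nn)
    u[free] <- as.numeric(Matrix::solve(fm@factor, b[free]))
    gradOf(u)
  })

  if (is.null(retained)) {
    rows <- expand.grid(electrode = seq_len(ne), pair = seq_len(np))[, 2:1]
  } else if (is.matrix(retained) && is.logical(retained)) {
    idx <- which(t(retained), arr.ind = TRUE)   # pair-major ordering
    rows <- data.frame(pair = idx[, 2], electrode = idx[, 1])
  } else {
    rows <- as.data.frame(retained)
    names(rows) <- c("pair", "electrode")
  }
  J <- matrix(0, nrow(rows), nrow(tri))
  for (m in seq_len(nrow(rows))) {
    gd <- drive[[rows$pair[m]]]
    gm <- meas[[rows$electrode[m]]]
    J[m, ] <- -g$area * (gd[, 1] * gm[, 1] + gd[, 2] * gm[, 2])
  }
  list(J = J, rows = rows, fm = fm)
}

#' Zeroth-order Tikhonov inverse
#'
#' \code{deltaSigma = argmin ||J x - dv||^2 + lambda ||x||^2}, solved through
#' the normal equations. Deterministic.
#'
#' @param J sensitivity matrix (measurements x elements).
#' @param dv boundary-voltage change vector.
#' @param lambda regularisation hyperparameter (> 0).
#' @return per-element conductivity change.
#' @export
tikhonovInverse <- function(J, dv, lambda) {
  stopifnot(lambda > 0, length(dv) == nrow(J))
  A <- crossprod(J) + diag(lambda, ncol(J))
  as.numeric(solve(A, crossprod(J, dv)))
}

#' Default log-spaced lambda grid scaled to the problem
#' @param J sensitivity matrix.
#' @param n grid points.
#' @export
lambdaGrid <- function(J, n = 20) {
  s <- sum(J^2) / ncol(J)     # trace(J'J)/n_elements
  s * 10^seq(-8, 0, length.out = n)
}

#' Cross-validated choice of the Tikhonov hyperparameter
#'
#' k-fold cross-validation over measurement rows: for each lambda, each fold is
#' held out, the image reconstructed from the remainder, and the held-out
#' residual \code{||J_test x - dv_test||^2} accumulated; the lambda with the
#' smallest mean held-out residual wins, ties broken toward larger lambda.
#'
#' @param J sensitivity matrix.
#' @param dv boundary-voltage change vector.
#' @param grid candidate lambdas (default \code{\link{lambdaGrid}}).
#' @param kFolds folds (>= 2).
#' @param seed fold-assignment seed.
#' @return list with \code{lambda}, \code{cvCurve} (data.frame lambda,
#'   cv_error).
#' @export
selectLambdaCV <- function(J, dv, grid = lambdaGrid(J), kFolds = 10,
                           seed = NULL) {
  stopifnot(length(grid) >= 1L, kFolds >= 2L)
  n <- nrow(J)
  if (n < kFolds) stop("fewer measurements than folds")
  if (length(grid) == 1L)
    return(list(lambda = grid,
                cvCurve = data.frame(lambda = grid, cv_error = NA_real_)))
  fold <- withSeed(seed, sample(rep_len(seq_len(kFolds), n)))
  err <- vapply(grid, function(l) {
    tot <- 0
    for (k in seq_len(kFolds)) {
      tr <- fold != k
      x <- tikhonovInverse(J[tr, , drop = FALSE], dv[tr], l)
      r <- J[!tr, , drop = FALSE] %*% x - dv[!tr]
      tot <- tot + sum(r^2)
    }
    tot / n
  }, numeric(1))
  best <- max(which(err <= min(err) + 0))   # ties -> larger lambda
  list(lambda = grid[best], cvCurve = data.frame(lambda = grid, cv_error = err))
}

#' Noise-based correction of a reconstructed image
#'
#' Projects the per-measurement noise covariance through the linear inverse
#' operator \code{R = (J'J + lambda I)^-1 J'} to get the SD of each element
#' under pure noise, converts the image to z-scores and zeroes elements with
#' \code{|z| < threshold}.
#'
#' @param deltaSigma reconstructed image (from \code{\link{tikhonovInverse}}
#'   with the same J and lambda).
#' @param J sensitivity matrix.
#' @param noiseSd per-measurement noise SD (scalar or vector), volts.
#' @param lambda the lambda used for the reconstruction.
#' @param threshold z-score threshold (default 3).
#' @return list with \code{corrected}, \code{zscores}, \code{elementSd}.
#' @export
noiseCorrection <- function(deltaSigma, J, noiseSd, lambda, threshold = 3) {
  noiseSd <- rep_len(noiseSd, nrow(J))
  if (all(noiseSd == 0))
    stop("all measurement noise SDs are zero; z-scores undefined")
  A <- crossprod(J) + diag(lambda, ncol(J))
  R <- solve(A, t(J))                       # elements x measurements
  elementVar <- (R^2) %*% noiseSd^2
  elementSd <- sqrt(as.numeric(elementVar))
  z <- deltaSigma / elementSd
  corrected <- ifelse(abs(z) >= threshold, deltaSigma, 0)
  list(corrected = corrected, zscores = z, elementSd = elementSd)
}

#' Reconstruct a conductivity-change image from a voltage difference
#'
#' Convenience wrapper: sensitivity matrix on the mesh, cross-validated (or
#' fixed) lambda, Tikhonov inversion, optional noise-based correction.
#'
#' @param mesh a \linkS4class{Mesh2D}.
#' @param protocol an \linkS4class{InjectionProtocol}.
#' @param dv voltage-change vector over the retained measurements.
#' @param retained logical pairs x electrodes keep-matrix matching \code{dv}
#'   (see \code{\link{jacobianMatrix}}); NULL = all.
#' @param lambda fixed lambda, or NULL for cross-validation.
#' @param noiseSd optional per-measurement noise SD for the correction.
#' @param kFolds,seed cross-validation controls.
#' @param threshold z-score threshold of the correction.
#' @return a \linkS4class{ReconResult}.
#' @export
reconstructImage <- function(mesh, protocol, dv, retained = NULL, lambda = NULL,
                             noiseSd = NULL, kFolds = 10, seed = NULL,
                             threshold = 3) {
  jac <- jacobianMatrix(mesh, protocol, retained)
  if (length(dv) != nrow(jac$J)) stop("dv length does not match retained measurements")
  cv <- data.frame(lambda = numeric(), cv_error = numeric())
  if (is.null(lambda)) {
    sel <- selectLambdaCV(jac$J, dv, kFolds = kFolds, seed = seed)
    lambda <- sel$lambda
    cv <- sel$cvCurve
  }
  ds <- tikhonovInverse(jac$J, dv, lambda)
  z <- rep(NA_real_, length(ds)); corr <- ds
  if (!is.null(noiseSd)) {
    nc <- noiseCorrection(ds, jac$J, noiseSd, lambda, threshold)
    z <- nc$zscores; corr <- nc$corrected
  }
  new("ReconResult", deltaSigma = ds, lambda = lambda, cvCurve = cv,
      zscores = z, corrected = corr)
}

#' Element centroids of a mesh
#' @param mesh a \linkS4class{Mesh2D}.
#' @export
elementCentroids <- function(mesh) {
  t <- mesh@triangles; n <- mesh@nodes
  cbind((n[t[, 1], 1] + n[t[, 2], 1] + n[t[, 3], 1]) / 3,
        (n[t[, 1], 2] + n[t[, 2], 2] + n[t[, 3], 2]) / 3)
}

#' Export an element-valued image as CSV and legacy VTK
#'
#' @param mesh a \linkS4class{Mesh2D}.
#' @param values per-element values.
#' @param pathBase path without extension; writes <base>.csv and <base>.vtk.
#' @export
writeImage <- function(mesh, values, pathBase) {
  cen <- elementCentroids(mesh)
  write.csv(data.frame(element = seq_along(values), x = cen[, 1], y = cen[, 2],
                       value = values),
            paste0(pathBase, ".csv"), row.names = FALSE)
  con <- file(paste0(pathBase, ".vtk"), "w")
  on.exit(close(con))
  nn <- nrow(mesh@nodes); nt <- nrow(mesh@triangles)
  writeLines(c("# vtk DataFile Version 3.0", "conductivity change image",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nn)), con)
  write.table(cbind(mesh@nodes, 0), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nt, 4 * nt), con)
  write.table(cbind(3L, mesh@triangles - 1L), con, row.names = FALSE,
              col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  writeLines(c(sprintf("CELL_DATA %d", nt), "SCALARS delta_sigma float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(values, scientific = TRUE), con)
  invisible(pathBase)
}
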