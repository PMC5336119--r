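# Standard small-mesh setup shared by the inverse tests.
femSetup <- function() {
  mesh <- discMesh(nElectrodes = 16, nRings = 5, nTheta = 16)
  prot <- injectionProtocol(rbind(cbind(1:16, c(2:16, 1)), cbind(1:8, 9:16)),
                            nElectrodes = 16, currentAmplitude = 1e-4)
  keep <- matrix(TRUE, nPairs(prot), 16)
  pp <- protocolPairs(prot)
  for (i in seq_len(nrow(pp))) keep[i, pp[i, ]] <- FALSE
  list(mesh = mesh, prot = prot, keep = keep)
}

test_that("forward solutions respect symmetry, reciprocity and scaling", {
  mesh <- discMesh(nElectrodes = 8, nRings = 4, nTheta = 16)
  fm <- forwardModel(mesh)
  # injection through the horizontal diameter (1 -> 5): reflecting across the
  # vertical axis swaps source and sink, so potentials are antisymmetric under
  # that mirror; reflecting across the injection axis leaves them symmetric
  v <- forwardSolve(fm, c(1, 5))
  mirrorV <- c(5, 4, 3, 2, 1, 8, 7, 6)   # x -> -x electrode map
  mirrorH <- c(1, 8, 7, 6, 5, 4, 3, 2)   # y -> -y electrode map
  expect_lt(max(abs(v + v[mirrorV])), 1e-10 * max(abs(v)))
  expect_lt(max(abs(v - v[mirrorH])), 1e-10 * max(abs(v)))
  # reciprocity to 1e-12 relative
  pairs <- list(c(1, 3), c(2, 6), c(4, 7))
  for (a in pairs) for (b in pairs) {
    va <- forwardSolve(fm, a)
    vb <- forwardSolve(fm, b)
    expect_lt(abs((va[b[1]] - va[b[2]]) - (vb[a[1]] - vb[a[2]])),
              1e-12 * max(abs(va)))
  }
  # doubling sigma halves every transfer voltage exactly
  mesh2 <- mesh
  mesh2@conductivity <- mesh@conductivity * 2
  v2 <- forwardSolve(forwardModel(mesh2), c(1, 5))
  expect_equal(v2, v / 2, tolerance = 1e-12)
})

test_that("mesh text files round-trip and validity catches bad meshes", {
  mesh <- discMesh(nElectrodes = 4, nRings = 3, nTheta = 12)
  nf <- withr::local_tempfile(); ef <- withr::local_tempfile()
  lf <- withr::local_tempfile()
  writeMeshText(mesh, nf, ef, lf)
  m2 <- readMeshText(nf, ef, lf)
  expect_equal(m2@nodes, mesh@nodes, tolerance = 1e-12)
  expect_identical(m2@triangles, mesh@triangles)
  expect_identical(m2@electrodeNodes, mesh@electrodeNodes)
  bad <- mesh
  expect_error({ bad@conductivity[1] <- -1; validObject(bad) }, "positive")
})

test_that("adjoint Jacobian matches finite differences and Geselowitz", {
  mesh <- discMesh(nElectrodes = 8, nRings = 4, nTheta = 16)   # 112 elements
  prot <- injectionProtocol(rbind(c(1, 5), c(2, 7), c(3, 8), c(4, 6)),
                            nElectrodes = 8)
  jac <- jacobianMatrix(mesh, prot)     # all pairs x electrodes
  nel <- nrow(mesh@triangles)
  # finite-difference oracle, central differences over every element
  h <- 1e-6
  Jfd <- matrix(0, nrow(jac$J), nel)
  pp <- protocolPairs(prot)
  for (e in seq_len(nel)) {
    mp <- mesh; mp@conductivity[e] <- mesh@conductivity[e] + h
    mm <- mesh; mm@conductivity[e] <- mesh@conductivity[e] - h
    fp <- forwardModel(mp); fmn <- forwardModel(mm)
    col <- unlist(lapply(seq_len(nrow(pp)), function(i)
      (forwardSolve(fp, pp[i, ]) - forwardSolve(fmn, pp[i, ])) / (2 * h)))
    Jfd[, e] <- col
  }
  expect_lt(max(abs(jac$J - Jfd)) / max(abs(jac$J)), 1e-4)
  # Geselowitz: sum_e J[m,e] sigma_e = -V_m for the homogeneous background
  V <- unlist(lapply(seq_len(nrow(pp)), function(i)
    forwardSolve(jac$fm, pp[i, ])))
  expect_lt(max(abs(jac$J %*% mesh@conductivity + V)), 1e-12 * max(abs(V)))
  # an element far from all electrodes is less sensitive than one at an
  # electrode (qualitative monotonicity, first measurement row)
  cen <- elementCentroids(mesh)
  rfar <- which.min(rowSums(cen^2))         # central element
  el1 <- mesh@nodes[mesh@electrodeNodes[1], ]
  rnear <- which.min((cen[, 1] - el1[1])^2 + (cen[, 2] - el1[2])^2)
  expect_lt(abs(jac$J[1, rfar]), abs(jac$J[1, rnear]))
})

test_that("Tikhonov inverse: zero data, shrinkage limit, linearity, crime", {
  s <- femSetup()
  jac <- jacobianMatrix(s$mesh, s$prot, s$keep)
  expect_equal(tikhonovInverse(jac$J, numeric(nrow(jac$J)), 1e-3),
               numeric(ncol(jac$J)))
  set.seed(2)
  dv <- as.numeric(jac$J %*% rnorm(ncol(jac$J), 0, 0.01))
  lams <- lambdaGrid(jac$J, 8)
  norms <- vapply(lams, function(l) sqrt(sum(tikhonovInverse(jac$J, dv, l)^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))            # monotone shrinkage
  huge <- sqrt(sum(tikhonovInverse(jac$J, dv, 1e12 * sum(jac$J^2))^2))
  expect_lt(huge / norms[1], 1e-9)             # lambda >> ||J'J|| -> ~0
  # linearity at fixed lambda
  dv2 <- as.numeric(jac$J %*% rnorm(ncol(jac$J), 0, 0.01))
  l <- lams[4]
  expect_equal(tikhonovInverse(jac$J, dv + dv2, l),
               tikhonovInverse(jac$J, dv, l) + tikhonovInverse(jac$J, dv2, l),
               tolerance = 1e-10)
  # inverse crime: single-element perturbation localises to itself
  ds <- numeric(ncol(jac$J)); ds[37] <- 0.05
  rec <- tikhonovInverse(jac$J, as.numeric(jac$J %*% ds), lambdaGrid(jac$J)[3])
  expect_equal(which.max(abs(rec)), 37L)
})

test_that("cross-validated lambda: noise-free small, noisy larger, single-point", {
  s <- femSetup()
  jac <- jacobianMatrix(s$mesh, s$prot, s$keep)
  set.seed(5)
  dv <- as.numeric(jac$J %*% rnorm(ncol(jac$J), 0, 0.01))
  grid <- lambdaGrid(jac$J)
  sel <- selectLambdaCV(jac$J, dv, grid, kFolds = 10, seed = 1)
  expect_lte(which(grid == sel$lambda), 2L)    # at or next to the grid minimum
  expect_equal(nrow(sel$cvCurve), length(grid))
  # SNR 0 dB noise: lambda* >= noise-free lambda* (median over 10 seeds)
  idxNoisy <- vapply(1:10, function(sd0) {
    set.seed(sd0)
    dvn <- dv + rnorm(length(dv), 0, sd(dv))
    which(grid == selectLambdaCV(jac$J, dvn, grid, kFolds = 10,
                                 seed = sd0)$lambda)
  }, numeric(1))
  expect_gte(median(idxNoisy), which(grid == sel$lambda))
  expect_equal(selectLambdaCV(jac$J, dv, grid = 0.5)$lambda, 0.5)
  expect_error(selectLambdaCV(jac$J[1:5, ], dv[1:5], grid, kFolds = 10),
               "folds")
})

test_that("noise-based correction: null rate, degenerate input, precision", {
  s <- femSetup()
  jac <- jacobianMatrix(s$mesh, s$prot, s$keep)
  grid <- lambdaGrid(jac$J)
  lam <- grid[8]
  expect_error(noiseCorrection(numeric(ncol(jac$J)), jac$J, 0, lam), "zero")
  # pure-noise images: fraction of |z| >= 3 near the Gaussian 0.27%
  hits <- 0; tot <- 0
  for (sd0 in 1:50) {
    set.seed(sd0)
    nv <- rnorm(nrow(jac$J), 0, 1e-6)
    ds <- tikhonovInverse(jac$J, nv, lam)
    nc <- noiseCorrection(ds, jac$J, 1e-6, lam)
    hits <- hits + sum(abs(nc$zscores) >= 3)
    tot <- tot + length(nc$zscores)
  }
  expect_gt(hits / tot, 0.0002)
  expect_lt(hits / tot, 0.009)
  # injected perturbation at SNR 20 dB survives; background suppressed
  cen <- elementCentroids(s$mesh)
  d2 <- sqrt((cen[, 1] - 0.45)^2 + (cen[, 2] - 0.25)^2)
  region <- which(d2 < 0.25)
  dsTrue <- numeric(ncol(jac$J)); dsTrue[region] <- 0.1
  dv <- as.numeric(jac$J %*% dsTrue)
  prec <- vapply(1:5, function(sd0) {
    set.seed(sd0)
    sdm <- sqrt(mean(dv^2)) / 10
    dvn <- dv + rnorm(length(dv), 0, sdm)
    sel <- selectLambdaCV(jac$J, dvn, kFolds = 10, seed = sd0)
    nc <- noiseCorrection(tikhonovInverse(jac$J, dvn, sel$lambda), jac$J,
                          sdm, sel$lambda)
    surv <- which(nc$corrected != 0)
    expect_gt(length(surv), 0)
    mean(surv %in% which(d2 < 0.45))   # region plus edge-sharing ring
  }, numeric(1))
  expect_true(all(prec >= 0.8))
})

test_that("full pipeline localises a conductivity change on a 16-electrode disc", {
  s <- femSetup()
  mesh <- s$mesh; prot <- s$prot; keep <- s$keep
  plan <- frequencyPlan(2000, periods = 100)   # 50 ms injections
  cen <- elementCentroids(mesh)
  d2 <- sqrt((cen[, 1] - 0.45)^2 + (cen[, 2] - 0.25)^2)
  region <- which(d2 < 0.25)
  mesh2 <- mesh
  mesh2@conductivity[region] <- mesh@conductivity[region] * 1.3
  scale <- 50
  phBase <- femPhantom(mesh, prot, scale = scale)
  phPert <- femPhantom(mesh2, prot, scale = scale)
  runMeans <- function(ph, seed) {
    sim <- simulateRecording(prot, plan, timingPlan(), ph,
                             noiseModel(whiteSd = 2e-6), amplifierModel(),
                             nFrames = 2, seed = seed)
    segs <- segmentRecording(sim$recording,
                             decodeTriggerChannel(sim$recording@triggers),
                             prot, plan)
    fs1 <- assembleFrameSet(measureSegments(sim$recording, segs), prot)
    m <- apply(fs1@amplitudes * sign(cos(fs1@phases)), c(2, 3), mean)
    t(m)[t(keep)]                       # signed, pair-major retained vector
  }
  limit <- 2 * sqrt(mean(triangleAreas(mesh)) * 4 / sqrt(3))  # 2 element diams
  truth <- colMeans(cen[region, ])
  demodSd <- 2e-6 * sqrt(2 / (0.8 * 0.05 * 16000))
  for (seed in 1:5) {
    dv <- (runMeans(phPert, seed + 100) - runMeans(phBase, seed)) / scale
    res <- reconstructImage(mesh, prot, dv, retained = keep, seed = seed,
                            noiseSd = demodSd / scale)
    w <- abs(res@corrected)
    if (sum(w) == 0) w <- abs(res@deltaSigma)
    com <- c(sum(cen[, 1] * w), sum(cen[, 2] * w)) / sum(w)
    expect_lt(sqrt(sum((com - truth)^2)), limit)
    # the recovered change at the target is positive (a conductivity increase)
    expect_gt(mean(res@deltaSigma[region]), 0)
  }
})

test_that("a seven-fold focal conductivity increase reconstructs positively", {
  s <- femSetup()
  cen <- elementCentroids(s$mesh)
  d2 <- sqrt((cen[, 1] + 0.4)^2 + (cen[, 2] - 0.3)^2)
  region <- which(d2 < 0.25)
  mesh7 <- s$mesh
  mesh7@conductivity[region] <- s$mesh@conductivity[region] * 7
  trBase <- femPhantom(s$mesh, s$prot)@transfer
  trPert <- femPhantom(mesh7, s$prot)@transfer
  dv <- t(trPert - trBase)[t(s$keep)]
  res <- reconstructImage(s$mesh, s$prot, dv, retained = s$keep, seed = 1)
  expect_gt(mean(res@deltaSigma[region]), 0)
  expect_true(all(order(-abs(res@deltaSigma))[1:3] %in% which(d2 < 0.45)))
})

test_that("image export writes CSV and legacy VTK", {
  mesh <- discMesh(nElectrodes = 4, nRings = 3, nTheta = 12)
  vals <- seq_len(nrow(mesh@triangles)) * 1e-3
  base <- withr::local_tempfile()
  writeImage(mesh, vals, base)
  tab <- read.csv(paste0(base, ".csv"))
  expect_equal(nrow(tab), nrow(mesh@triangles))
  vtk <- readLines(paste0(base, ".vtk"))
  expect_true(any(grepl("UNSTRUCTURED_GRID", vtk)))
  expect_true(any(grepl("CELL_DATA", vtk)))
})
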