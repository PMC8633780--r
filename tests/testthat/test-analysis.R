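test_that("Kabsch RMSD is zero under rigid transforms and matches bio3d", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- X %*% R + 5
  expect_equal(kabschRMSD(X, X), 0, tolerance = 1e-12)
  expect_equal(kabschRMSD(X, Y), 0, tolerance = 1e-12)
  # symmetry and cross-check against the independent bio3d implementation
  Y2 <- Y + matrix(rnorm(60, 0, 0.3), 20, 3)
  r1 <- kabschRMSD(X, Y2)
  expect_equal(kabschRMSD(Y2, X), r1, tolerance = 1e-9)
  r2 <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y2)), fit = TRUE)
  expect_equal(r1, r2, tolerance = 1e-3)
})

test_that("structure selections pair by residue number and atom name", {
  d <- twoHelixDimer(1)
  r <- kabschRMSD(d, d, chainA = "A", chainB = "B")
  expect_lt(r, 0.5)  # near-identical subunits by construction
  expect_gt(r, 0)
  expect_error(kabschRMSD(d, d, chainA = "A", chainB = "Z"), "pairing|mismatch")
})

test_that("RMSF matches closed forms on synthetic ensembles", {
  h <- idealHelix(16)
  # identical frames: RMSF zero
  e0 <- noisyEnsemble(h, 0, 4, seed = 1)
  expect_lt(max(rmsf(e0)$rmsf), 1e-12)
  expect_error(rmsf(new("Ensemble", frames = e0@frames[1], atoms = e0@atoms,
                        stepsCompleted = 0L, haltReason = "none",
                        frameSteps = 0L, maxViolations = 0)), "2 frames")

  # two frames, one Calpha displaced by 2d: that residue d, others 0
  xyz <- coords(h)
  ca <- which(atoms(h)$name == "CA")[8]
  xyz2 <- xyz; xyz2[ca, 1] <- xyz2[ca, 1] + 2 * 0.7
  e2 <- new("Ensemble", frames = list(xyz, xyz2), atoms = atoms(h),
            stepsCompleted = 0L, haltReason = "none", frameSteps = 0:1,
            maxViolations = c(0, 0))
  r2 <- rmsf(e2, superpose = FALSE)
  expect_equal(r2$rmsf[8], 0.7, tolerance = 1e-12)
  expect_lt(max(r2$rmsf[-8]), 1e-12)

  # isotropic noise: mean RMSF -> sigma*sqrt(3)*sqrt((n-1)/n) within 5%
  en <- noisyEnsemble(h, 0.5, 1000, seed = 7)
  rn <- rmsf(en, superpose = FALSE)
  expect_equal(mean(rn$rmsf), 0.5 * sqrt(3) * sqrt(999 / 1000), tolerance = 0.05)

  # invariance under one global rigid transform of every frame
  th <- 0.9
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  eR <- e2
  eR@frames <- lapply(e2@frames, function(f) f %*% R + 3)
  expect_equal(rmsf(eR)$rmsf, rmsf(e2)$rmsf, tolerance = 1e-9)
})

test_that("B-factor profile normalizes the region by the overall mean", {
  h <- idealHelix(12)             # uniform B = 10 by construction
  bp <- bfactorProfile(h, regionSelection("A", 3, 6))
  expect_equal(bp$normalizedFold, 1.0)
  expect_equal(bp$overallMean, 10)
  # whole structure as its own region: fold exactly 1
  whole <- bfactorProfile(h, regionSelection("A", 1, 12))
  expect_identical(whole$normalizedFold, 1)
  # non-uniform case
  a <- atoms(h); a$b[a$resNo <= 6] <- 30
  s <- structureFromAtoms(a)
  bp2 <- bfactorProfile(s, regionSelection("A", 1, 6))
  expect_equal(bp2$regionMean, 30)
  expect_equal(bp2$normalizedFold, 30 / mean(c(rep(30, 6), rep(10, 6))))
  expect_error(bfactorProfile(h, regionSelection("A", 50, 60)), "no Calpha")
})

test_that("Shrake-Rupley SASA reproduces sphere areas and burial", {
  s1 <- pointStructure(matrix(0, 1, 3))
  expect_equal(attr(sasa(s1), "total"), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # far-separated atoms are additive
  s2 <- pointStructure(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(attr(sasa(s2), "total"), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  # fully enclosed atom has zero area
  grid <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2)))
  a3 <- sasa(pointStructure(grid))
  expect_equal(unname(a3[14]), 0)
  # sampling convergence: halving the point count changes the total < 0.5%
  h <- idealHelix(12)
  t1 <- attr(sasa(h, nPoints = 960), "total")
  t2 <- attr(sasa(h, nPoints = 480), "total")
  expect_lt(abs(t1 - t2) / t1, 0.005)
  expect_error(sasa(pointStructure(matrix(0, 1, 3), element = "Q")), "unknown element")
})

test_that("interface area is symmetric and vanishes without contact", {
  d <- twoHelixDimer(1)
  ia <- interfaceArea(d, "A", "B")
  expect_gt(ia, 50)
  expect_equal(interfaceArea(d, "B", "A"), ia, tolerance = 1e-9)
  at <- atoms(d); at$x[at$chainId == "B"] <- at$x[at$chainId == "B"] + 100
  expect_lt(abs(interfaceArea(structureFromAtoms(at), "A", "B")), 1)
  expect_error(interfaceArea(d, "A", "Z"), "missing")
})

test_that("composition census counts classes from SEQRES or coordinates", {
  h <- idealHelix(20)              # poly-Ala
  cc <- compositionCensus(h)
  expect_equal(unname(cc$counts["ALA"]), 20L)
  expect_equal(cc$fractionCharged, 0)
  d <- twoHelixDimer(1)
  ca <- compositionCensus(d, "A")
  expect_equal(ca$basic, 1L)       # the designed lysine
  expect_equal(ca$source, "seqres")
  cb <- compositionCensus(d, "B")
  expect_equal(cb$acidic, 1L)      # the designed aspartate
  # observed census never exceeds SEQRES per residue type
  obs <- compositionCensus(d, "A", source = "observed")
  for (nm in names(obs$counts))
    expect_lte(obs$counts[[nm]], ca$counts[[nm]])
})
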