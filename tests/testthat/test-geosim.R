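test_that("constraint targets encode bonds, angles and locked dihedrals", {
  di <- structureFromAtoms(flexrig:::.buildPeptide(c("ALA", "ALA")))
  net <- buildNetwork(di, -4, "ambient")
  cfg <- geoSimConfig()
  tg <- constraintTargets(di, net, cfg)
  a <- atoms(di)
  iC <- which(a$name == "C" & a$resNo == 1)
  iN <- which(a$name == "N" & a$resNo == 2)
  hit <- which((tg$eq[, 1] == min(iC, iN)) & (tg$eq[, 2] == max(iC, iN)))
  expect_length(hit, 1L)
  dCN <- sqrt(sum((coords(di)[iC, ] - coords(di)[iN, ])^2))
  expect_equal(tg$eqTargets[hit], dCN, tolerance = 1e-12)
  # constrained pairs are excluded from the steric list
  st <- flexrig:::.stericPairs(coords(di), tg, cfg)
  if (nrow(st$lb))
    expect_false(any(paste(st$lb[, 1], st$lb[, 2]) %in%
                     paste(tg$eq[, 1], tg$eq[, 2])))
})

test_that("relaxation projects a stretched bond in one sweep, moving both atoms", {
  xyz <- rbind(c(0, 0, 0), c(1.8, 0, 0))   # target 1.5, stretched by 0.3
  tg <- list(eq = matrix(c(1L, 2L), 1, 2), eqTargets = 1.5,
             ub = matrix(integer(), 0, 2), ubTargets = numeric(),
             excluded = character(), radii = c(1.7, 1.7), stericFloorMax = 0)
  cfg <- geoSimConfig()
  out <- flexrig:::.relax_cpp(xyz, tg$eq, tg$eqTargets,
                              tg$ub, tg$ubTargets,
                              matrix(integer(), 0, 2), numeric(),
                              cfg@tolerance, cfg@maxRelaxSweeps)
  expect_equal(out$sweeps, 1L)
  expect_equal(out$coords[1, 1], 0.15, tolerance = 1e-12)
  expect_equal(out$coords[2, 1], 1.65, tolerance = 1e-12)
})

test_that("already-satisfied coordinates are returned unchanged in zero sweeps", {
  h <- fixHelix()
  net <- buildNetwork(h, -4, "ambient")
  cfg <- geoSimConfig()
  tg <- constraintTargets(h, net, cfg)
  out <- relaxGeometry(coords(h), tg, cfg)
  expect_equal(out$sweeps, 0L)
  expect_identical(out$coords, coords(h))
})

test_that("infeasible targets are flagged, not an error", {
  # triangle-inequality-violating equality set: cannot be restored
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0))
  eq <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- flexrig:::.relax_cpp(xyz, eq, c(1, 1, 3),
                              matrix(integer(), 0, 2), numeric(),
                              matrix(integer(), 0, 2), numeric(), 0.1, 50L)
  expect_gt(out$maxViolation, 0.1)
})

test_that("mode projection replicates node displacements and normalizes", {
  h <- fixHelix()
  enm <- buildENM(h)
  tm <- trivialModes(enm)
  cfg <- geoSimConfig()
  bias <- projectMode(tm, 1, enm, h, cfg)
  expect_equal(sqrt(sum(bias^2)), cfg@stepScale, tolerance = 1e-12)
  # pure translation: identical displacement for every atom
  expect_lt(max(apply(bias, 2, function(cl) diff(range(cl)))), 1e-12)
  cfgA <- geoSimConfig(direction = "antiparallel")
  expect_equal(projectMode(tm, 1, enm, h, cfgA), -bias, tolerance = 1e-15)
})

test_that("translation-mode run conserves internal geometry exactly", {
  h <- fixHelix()
  enm <- buildENM(h)
  tm <- trivialModes(enm)
  cfg <- geoSimConfig(maxSteps = 200L, frameInterval = 50L)
  e <- runGeoSim(h, tm, 1, cfg)
  expect_equal(e@stepsCompleted, 200L)
  expect_equal(e@haltReason, "max_steps")
  expect_equal(length(e@frames), 200L / 50L + 1L)
  disp <- e@frames[[length(e@frames)]] - e@frames[[1]]
  expect_equal(sqrt(sum(disp^2)), 200 * cfg@stepScale, tolerance = 1e-9)
  d0 <- dist(e@frames[[1]]); d1 <- dist(e@frames[[length(e@frames)]])
  expect_lt(max(abs(d1 - d0)), 1e-9)
})

test_that("mode-biased runs keep every saved frame within tolerance", {
  h <- fixHelix()
  enm <- buildENM(h)
  lm <- lowestModes(enm, 2)
  cfg <- geoSimConfig(maxSteps = 150L, frameInterval = 50L)
  net <- buildNetwork(h, cfg@networkCutoff, "ambient")
  tg <- constraintTargets(h, net, cfg)
  e <- runGeoSim(h, lm, 7, cfg, net2 = net, enmNet = enm)
  expect_lte(e@stepsCompleted, cfg@maxSteps)
  expect_equal(length(e@frames),
               floor(e@stepsCompleted / cfg@frameInterval) + 1L)
  for (fr in e@frames) {
    chk <- relaxGeometry(fr, tg, cfg)
    expect_lte(chk$maxViolation, cfg@tolerance + 1e-12)
    expect_equal(chk$sweeps, 0L)  # frame already satisfies everything
  }
  # deterministic: identical inputs give bit-identical ensembles
  e2 <- runGeoSim(h, lm, 7, cfg, net2 = net, enmNet = enm)
  expect_identical(e@frames, e2@frames)
  # run log is serializable
  f <- withr::local_tempfile(fileext = ".json")
  log <- geoSimLog(e, 7, "parallel", f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})

test_that("helix ends explore larger amplitudes than the core under bending", {
  h <- fixHelix()
  enm <- buildENM(h)
  lm <- lowestModes(enm, 2)
  e <- runGeoSim(h, lm, 7, geoSimConfig(maxSteps = 300L, frameInterval = 100L))
  d <- sqrt(rowSums((e@frames[[length(e@frames)]] - e@frames[[1]])^2))
  a <- atoms(h)
  ends <- mean(d[a$resNo %in% c(1:4, 17:20)])
  core <- mean(d[a$resNo %in% 9:12])
  expect_gt(ends, core)
})
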