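test_that("spring assignment uses a strict distance cutoff", {
  s <- pointStructure(rbind(c(0, 0, 0), c(5, 0, 0)), element = "CA")
  s@atoms$name <- "CA"; s@atoms$element <- "C"
  net <- buildENM(s, cutoff = 10)
  expect_equal(nrow(net@pairs), 1L)
  s2 <- pointStructure(rbind(c(0, 0, 0), c(12, 0, 0)))
  s2@atoms$name <- "CA"; s2@atoms$element <- "C"
  net2 <- buildENM(s2, cutoff = 10)
  expect_equal(nrow(net2@pairs), 0L)
  ev <- eigen(flexrig:::.enmHessian(net2), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(abs(ev) < 1e-12))
})

test_that("one node per residue; residues lacking a Calpha are an error", {
  d <- fixDimer()
  net <- buildENM(d)
  expect_equal(nrow(net@nodes), 36L)
  broken <- atoms(d)[atoms(d)$name != "CA" | atoms(d)$resNo != 5, ]
  expect_error(buildENM(structureFromAtoms(broken)), "Calpha")
})

test_that("trivial modes are an orthonormal basis of the Hessian null space", {
  net <- buildENM(idealHelix(12))
  tm <- trivialModes(net)
  V <- modeVectors(tm)
  expect_equal(ncol(V), 6L)
  expect_equal(crossprod(V), diag(6), tolerance = 1e-10)
  H <- flexrig:::.enmHessian(net)
  expect_lt(max(abs(H %*% V)), 1e-8 * max(abs(H)))
  # uniform x-translation has 1/sqrt(N) in every x slot
  N <- nrow(net@nodes)
  tx <- V[, 1]
  expect_equal(tx[seq(1, 3 * N, by = 3)], rep(1 / sqrt(N), N), tolerance = 1e-10)
  expect_equal(tx[-seq(1, 3 * N, by = 3)], rep(0, 2 * N), tolerance = 1e-10)
})

test_that("dumbbell has a single internal mode with eigenvalue 2k", {
  s <- pointStructure(rbind(c(0, 0, 0), c(5, 0, 0)))
  s@atoms$name <- "CA"; s@atoms$element <- "C"
  net <- buildENM(s, cutoff = 10, k = 1)
  lm <- lowestModes(net, 1)
  expect_equal(modeValues(lm), 2, tolerance = 1e-9)
  # relative motion along the bond axis
  v <- matrix(modeVectors(lm)[, 1], ncol = 3, byrow = TRUE)
  expect_equal(abs(v[1, 1] - v[2, 1]), sqrt(2), tolerance = 1e-6)
})

test_that("inverse iteration reproduces the dense eigensolution", {
  for (s in list(idealHelix(20), fixDimer())) {
    net <- buildENM(s)
    H <- flexrig:::.enmHessian(net)
    dense <- eigen(H, symmetric = TRUE)
    nzero <- sum(abs(dense$values) < 1e-8 * max(dense$values))
    expect_equal(nzero, 6L)
    lm <- lowestModes(net, 10)
    ref <- sort(dense$values)[7:16]
    expect_equal(modeValues(lm), ref, tolerance = 1e-6)
    # each mode lies in the span of dense eigenvectors of matching eigenvalue
    lamMax <- max(dense$values)
    for (cl in 1:10) {
      v <- modeVectors(lm)[, cl]
      resid <- sqrt(sum((H %*% v - modeValues(lm)[cl] * v)^2))
      expect_lt(resid, 1e-6 * lamMax)
    }
    # orthonormality of the returned set
    expect_equal(crossprod(modeVectors(lm)), diag(10), tolerance = 1e-8)
    # eigenvalues non-decreasing with mode index
    expect_true(all(diff(modeValues(lm)) >= -1e-12))
  }
})

test_that("eigenvalues are invariant under rigid rotation of the input", {
  h <- idealHelix(14)
  net1 <- buildENM(h)
  lm1 <- lowestModes(net1, 4)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  h2 <- setCoords(h, coords(h) %*% R)
  lm2 <- lowestModes(buildENM(h2), 4)
  expect_equal(modeValues(lm2), modeValues(lm1), tolerance = 1e-8)
})

test_that("mode participation is a normalized fraction over regions", {
  net <- buildENM(idealHelix(12))
  lm <- lowestModes(net, 2)
  whole <- modeParticipation(lm, net, regionSelection("A", 1, 12))
  expect_equal(unname(whole), c(1, 1), tolerance = 1e-10)
  tm <- trivialModes(net)
  part <- modeParticipation(tm, net, regionSelection("A", 1, 6), which = 1)
  expect_equal(unname(part), 6 / 12, tolerance = 1e-10)
  expect_error(modeParticipation(lm, net, regionSelection("B", 1, 3)), "no network nodes")
})

test_that("mode writers emit eigenvalue tables, vectors and animations", {
  net <- buildENM(idealHelix(10))
  lm <- lowestModes(net, 2)
  d <- withr::local_tempdir()
  writeModes(lm, net, d)
  ev <- utils::read.table(file.path(d, "eigenvalues.txt"), header = TRUE, sep = "\t")
  expect_equal(ev$mode, c(7L, 8L))
  tab <- utils::read.table(file.path(d, "modes.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 30L)
  f <- file.path(d, "anim.pdb")
  writeModeAnimation(lm, net, 7, f, nFrames = 5)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 5L)
})
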