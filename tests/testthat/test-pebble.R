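test_that("pebble game counts degrees of freedom on elementary graphs", {
  # one free body: no internal degrees of freedom
  g1 <- bodyBarGraph(1, data.frame(i = integer(), j = integer(), bars = integer()))
  expect_equal(pebbleGame(g1)$floppyModes, 0L)

  # welded pair: 6 bars, all independent
  g2 <- bodyBarGraph(2, data.frame(i = 1, j = 2, bars = 6))
  r2 <- pebbleGame(g2)
  expect_equal(r2$independentBars, 6L)
  expect_equal(r2$floppyModes, 0L)

  # 7 parallel bars: one redundant (aggregation caps at 6; feed raw bars)
  r7 <- pebbleGame(bodyBarGraph(2, data.frame(i = rep(1, 7), j = rep(2, 7),
                                              bars = rep(1, 7))))
  expect_equal(r7$independentBars, 6L)

  # bar counting on a pair: k = 0..7 single bars
  floppy <- vapply(0:7, function(k) {
    e <- if (k) data.frame(i = rep(1, k), j = rep(2, k), bars = rep(1, k))
         else data.frame(i = integer(), j = integer(), bars = integer())
    pebbleGame(bodyBarGraph(2, e))$floppyModes
  }, integer(1))
  expect_equal(floppy, c(6L, 5L, 4L, 3L, 2L, 1L, 0L, 0L))
})

test_that("floppy modes match the numeric generic-rank oracle", {
  for (seed in 1:40) {
    n <- sample(1:8, 1)
    nb <- if (n >= 2) sample(0:40, 1) else 0
    g <- randomBodyBar(n, nb, seed = seed)
    expect_equal(pebbleGame(g)$floppyModes, oracleFloppy(g),
                 info = sprintf("seed %d (n=%d, bars=%d)", seed, n, nb))
  }
})

test_that("accepted-bar count is invariant under insertion order", {
  g <- randomBodyBar(8, 30, seed = 5)
  tot <- sum(g@edges$bars)
  base <- pebbleGame(g)$independentBars
  set.seed(11)
  for (k in 1:20)
    expect_equal(pebbleGame(g, order = sample(tot))$independentBars, base)
})

test_that("adding a bar never increases floppy modes", {
  set.seed(42)
  for (trial in 1:20) {
    g <- randomBodyBar(6, sample(5:25, 1), seed = trial + 100)
    f0 <- pebbleGame(g)$floppyModes
    i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
    g2 <- bodyBarGraph(6, rbind(g@edges, data.frame(i = i, j = j, bars = 1)))
    expect_lte(pebbleGame(g2)$floppyModes, f0)
  }
})

test_that("rigid clusters are maximal mutually rigid sets", {
  # welded pair plus isolated third body
  g <- bodyBarGraph(3, data.frame(i = 1, j = 2, bars = 6))
  d <- rigidClusters(g)
  expect_equal(unname(clusterSizes(d)), c(2L, 1L))

  # 3-body ring with 3 bars per edge: 9 bars, floppy 6*3-6-9 = 3, no
  # multi-body cluster (no pair is rigid though the ring is connected)
  ring <- bodyBarGraph(3, data.frame(i = c(1, 2, 3), j = c(2, 3, 1),
                                     bars = c(3, 3, 3)))
  dr <- rigidClusters(ring)
  expect_equal(dr@floppyModes, 3L)
  expect_true(all(clusterSizes(dr) == 1L))

  # cluster relation agrees with the pairwise rank oracle on random graphs
  for (seed in c(2, 7, 13)) {
    g <- randomBodyBar(6, 24, seed = seed)
    d <- rigidClusters(g)
    rk <- bodyBarRank(6, g@edges)
    for (i in 1:5) for (j in (i + 1):6) {
      extra <- rbind(g@edges, data.frame(i = i, j = j, bars = 1))
      pairRigid <- bodyBarRank(6, extra) == rk  # extra bar redundant
      expect_equal(d@clusterOf[i] == d@clusterOf[j], pairRigid,
                   info = sprintf("seed %d pair (%d,%d)", seed, i, j))
    }
  }
})

test_that("cluster labels are deterministic: size then smallest member", {
  g <- bodyBarGraph(5, data.frame(i = c(3, 1), j = c(4, 2), bars = c(6, 6)))
  d <- rigidClusters(g)
  expect_equal(unname(clusterSizes(d)), c(2L, 2L, 1L))
  expect_equal(d@clusters[[1]], c(1L, 2L))  # tie broken by smallest member
  expect_equal(d@clusters[[2]], c(3L, 4L))
})

test_that("dilution series is monotone and cold never out-rigidifies ambient", {
  amb <- fixDimerDilution("ambient")
  cold <- fixDimerDilution("cold")
  largestA <- vapply(amb@decompositions, function(d) max(clusterSizes(d)), integer(1))
  largestC <- vapply(cold@decompositions, function(d) max(clusterSizes(d)), integer(1))
  expect_true(all(diff(largestA) <= 0))
  expect_true(all(diff(largestC) <= 0))
  expect_true(all(largestC <= largestA))
  # floppy modes grow (or stay) as constraints are removed
  floppyA <- vapply(amb@decompositions, floppyModes, integer(1))
  expect_true(all(diff(floppyA) >= 0))
})

test_that("decomposition exports map atoms to clusters", {
  d <- fixDimer()
  dec <- fixDimerDilution("ambient")@decompositions[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDecomposition(dec, d, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), sum(!atoms(d)$isHetero))
  expect_true(all(tab$cluster >= 1))
  fp <- withr::local_tempfile(fileext = ".pml")
  clusterViewerScript(dec, d, fp)
  expect_true(any(grepl("^color clust1", readLines(fp))))
  sm <- decompositionSummary(dec, -1, "ambient")
  expect_equal(sm$largest_size, unname(max(clusterSizes(dec))))
})
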