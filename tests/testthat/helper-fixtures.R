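# Shared fixtures (built once per test run) and the independent numeric
# rank oracle for body-bar frameworks.

.cache <- new.env()

fixHelix <- function() {
  if (is.null(.cache$helix))
    .cache$helix <- suppressWarnings(addPolarHydrogens(idealHelix(20)))
  .cache$helix
}

fixDimer <- function() {
  if (is.null(.cache$dimer))
    .cache$dimer <- suppressWarnings(addPolarHydrogens(twoHelixDimer(1)))
  .cache$dimer
}

fixDimerDilution <- function(regime) {
  key <- paste0("dil_", regime)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- rigidityDilution(fixDimer(), c(-1, -2, -3, -4), regime)
  .cache[[key]]
}

# generic rank of a body-bar framework from a random realization: each bar
# is a line between random points fixed to its two bodies; row of the
# rigidity matrix = (d, a x d) for one body and -(d, b x d) for the other
bodyBarRank <- function(nBodies, edges, seed = 1234) {
  if (!nrow(edges)) return(0L)
  set.seed(seed)
  P <- matrix(runif(3 * nBodies, -10, 10), ncol = 3)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  rows <- list()
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    for (b in seq_len(edges$bars[r])) {
      pa <- P[i, ] + runif(3, -2, 2)
      pb <- P[j, ] + runif(3, -2, 2)
      d <- pb - pa; d <- d / sqrt(sum(d * d))
      row <- numeric(6 * nBodies)
      row[(6 * i - 5):(6 * i)] <- c(d, cross3(pa, d))
      row[(6 * j - 5):(6 * j)] <- -c(d, cross3(pb, d))
      rows[[length(rows) + 1]] <- row
    }
  }
  qr(do.call(rbind, rows))$rank
}

# floppy modes predicted by the oracle (6 global motions subtracted once)
oracleFloppy <- function(g) 6L * g@nBodies - 6L - bodyBarRank(g@nBodies, g@edges)

# minimal single-atom-per-row structure for geometric tests
pointStructure <- function(xyz, element = "C", chain = "A") {
  structureFromAtoms(data.frame(
    serial = seq_len(nrow(xyz)), name = element, element = element,
    altLoc = "", resName = "ALA", chainId = chain, resNo = seq_len(nrow(xyz)),
    insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b = 10, isHetero = FALSE, stringsAsFactors = FALSE))
}
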