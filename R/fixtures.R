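# Deterministic synthetic inputs: ideal peptides built from internal
# coordinates, a packed two-helix dimer with designed inter-chain contacts,
# random body-bar multigraphs, and noisy coordinate ensembles.

.runSeeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# peptide backbone + template side chains at fixed dihedrals
.buildPeptide <- function(seq3, phi = -57, psi = -47, chainId = "A",
                          startRes = 1L, bFactor = 10) {
    n <- length(seq3)
    bad <- setdiff(seq3, .buildableResidues)
    if (length(bad))
      stop("no building template for: ", paste(unique(bad), collapse = ", "),
           " (supported: ", paste(.buildableResidues, collapse = ", "), ")")
    rows <- list()
    addAtom <- function(resIdx, nm, p) {
      rows[[length(rows) + 1]] <<- data.frame(
        serial = 0L, name = nm, element = .elementFromName(nm), altLoc = "",
        resName = seq3[resIdx], chainId = chainId,
        resNo = startRes + resIdx - 1L, insert = "",
        x = p[1], y = p[2], z = p[3], occupancy = 1, b = bFactor,
        isHetero = FALSE, stringsAsFactors = FALSE)
    }
    flush <- function(resIdx, atoms) {
      order <- c("N", "CA", "C", "O", "CB",
                 setdiff(names(atoms), c("N", "CA", "C", "O", "CB")))
      for (nm in order) if (!is.null(atoms[[nm]])) addAtom(resIdx, nm, atoms[[nm]])
    }
    N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
    th <- 111.2 * pi / 180
    C <- CA + 1.525 * c(-cos(th), sin(th), 0)
    prev <- NULL
    for (i in seq_len(n)) {
      if (i > 1) {
        N <- .nerf(prev$N, prev$CA, prev$C, 1.329, 116.2, psi)
        CA <- .nerf(prev$CA, prev$C, N, 1.458, 121.7, 180)
        C <- .nerf(prev$C, N, CA, 1.525, 111.2, phi)
        prev$atoms$O <- .nerf(N, prev$CA, prev$C, 1.231, 120.8, 180)
        flush(i - 1, prev$atoms)
      }
      atoms <- list(N = N, CA = CA, C = C)
      if (seq3[i] != "GLY") {
        atoms$CB <- .nerf(N, C, CA, 1.530, 110.1, 122.6)
        for (row in .sideChainICTemplates[[seq3[i]]])
          atoms[[row[1]]] <- .nerf(atoms[[row[2]]], atoms[[row[3]]],
                                   atoms[[row[4]]], as.numeric(row[5]),
                                   as.numeric(row[6]), as.numeric(row[7]))
      }
      prev <- list(N = N, CA = CA, C = C, atoms = atoms)
      if (i == n) {
        prev$atoms$O <- .nerf(N, CA, C, 1.231, 120.8, psi + 180)
        flush(i, prev$atoms)
      }
    }
    out <- do.call(rbind, rows)
    out$serial <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Ideal alpha-helix fixture
#'
#' Backbone (N, CA, C, O, CB where applicable) built at ideal alpha-helical
#' dihedrals (phi = -57, psi = -47 degrees) and standard bond geometry, so
#' the i -> i+4 backbone hydrogen-bond ladder falls inside the polar
#' detection gates by construction.
#'
#' @param nResidues number of residues (>= 4).
#' @param sequence optional vector of 3-letter codes (recycled); default
#'   poly-Ala. Supported residues: those with internal-coordinate
#'   templates (Gly, Ala, Ser, Cys, Thr, Leu, Lys, Glu, Asp, Arg, Phe).
#' @return A \code{PDBStructure} (single chain A, SEQRES populated).
#' @export
idealHelix <- function(nResidues, sequence = NULL) {
  if (nResidues < 4) stop("need at least 4 residues for a helix")
  seq3 <- if (is.null(sequence)) rep("ALA", nResidues)
          else rep(toupper(sequence), length.out = nResidues)
  atoms <- .buildPeptide(seq3)
  structureFromAtoms(atoms, title = sprintf("ideal helix (%d residues)", nResidues),
                     seqres = list(A = seq3))
}

# canonicalize a single-chain helix: Calpha principal axis -> z, centroid
# at the origin, N-to-C direction along +z
.canonicalize <- function(atoms) {
  xyz <- .coordMatrix(atoms)
  ca <- xyz[atoms$name == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  pc <- prcomp(ca)
  ax <- pc$rotation[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  zax <- ax
  xax <- .unit(.cross(c(0, 1, 0), zax))
  if (!is.finite(sum(xax))) xax <- .unit(.cross(c(1, 0, 0), zax))
  yax <- .cross(zax, xax)
  R <- rbind(xax, yax, zax)
  out <- t(R %*% t(sweep(xyz, 2, ctr)))
  atoms$x <- out[, 1]; atoms$y <- out[, 2]; atoms$z <- out[, 3]
  atoms
}

.rotateZ <- function(atoms, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz <- t(R %*% t(.coordMatrix(atoms)))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

.flipX <- function(atoms) {      # 180 degrees about the x axis
  atoms$y <- -atoms$y; atoms$z <- -atoms$z
  atoms
}

# mean azimuth (degrees) of the selected atoms around the z axis
.faceAzimuth <- function(atoms, names) {
  sel <- atoms[atoms$name %in% names, , drop = FALSE]
  u <- cbind(sel$x, sel$y)
  u <- u / sqrt(rowSums(u^2))
  m <- colMeans(u)
  atan2(m[2], m[1]) * 180 / pi
}

#' Two-helix dimer fixture
#'
#' A miniature dimer: two 18-residue helices packed antiparallel. The
#' contact faces carry threonines whose methyl groups form inter-chain
#' hydrophobic tethers and whose hydroxyls can hydrogen-bond across the
#' interface, and a facing Lys/Asp pair forms at least one inter-chain salt
#' bridge. Under the default packing the ambient-regime constraint network
#' at a -1 kcal/mol cut-off welds both helix cores into one rigid cluster
#' spanning the chains, while the cold regime (single-bar tethers) leaves
#' the two helices as separate clusters. A small seeded coordinate jitter
#' (sigma 0.005 A) makes the fixture reproducibly non-degenerate.
#'
#' @param seed integer seed.
#' @param separation inter-axis distance, Angstrom.
#' @return A \code{PDBStructure} with chains A and B.
#' @export
twoHelixDimer <- function(seed = 1L, separation = 10.0) {
  faceA <- c(2, 5, 9, 12, 16)
  faceB <- 19 - faceA                      # z-matched under the antiparallel flip
  seqA <- rep("ALA", 18); seqA[c(2, 5, 12, 16)] <- "THR"; seqA[9] <- "LYS"
  seqB <- rep("ALA", 18); seqB[19 - c(2, 5, 12, 16)] <- "THR"; seqB[11] <- "ASP"
  a <- .canonicalize(.buildPeptide(seqA, chainId = "A"))
  b <- .canonicalize(.buildPeptide(seqB, chainId = "B"))
  # point each chain's contact stripe at the partner, with spins and an
  # axial shift that interdigitate the threonine tips
  azA <- .faceAzimuth(a[a$resNo %in% faceA, , drop = FALSE], "CB")
  azB <- .faceAzimuth(b[b$resNo %in% faceB, , drop = FALSE], "CB")
  a <- .rotateZ(a, -azA - 18)
  b <- .rotateZ(b, 180 - azB - 24)
  b <- .flipX(b)
  b$x <- b$x + separation
  b$z <- b$z - 3.2
  atoms <- rbind(a, b)
  atoms$serial <- seq_len(nrow(atoms))
  jit <- .runSeeded(seed, matrix(stats::rnorm(3 * nrow(atoms), 0, 0.005),
                                 ncol = 3))
  atoms$x <- atoms$x + jit[, 1]; atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  rownames(atoms) <- NULL
  structureFromAtoms(atoms, title = "two-helix dimer fixture",
                     seqres = list(A = seqA, B = seqB))
}

#' Random body-bar multigraph fixture
#'
#' Uniform random endpoints with bar multiplicities drawn from the given
#' set; parallel bars aggregate (sum, cap 6). Used as the substrate for the
#' pebble-game rank oracle.
#'
#' @param nBodies number of bodies (>= 1).
#' @param nBars number of bars drawn.
#' @param multiplicities multiplicity set to draw from.
#' @param seed integer seed.
#' @return A \code{\linkS4class{BodyBarGraph}} with attribute
#'   \code{"rawBars"} (the unaggregated draw).
#' @export
randomBodyBar <- function(nBodies, nBars, multiplicities = c(1, 2, 5, 6),
                          seed = 1L) {
  stopifnot(nBodies >= 1)
  if (nBodies < 2 && nBars > 0) stop("bars need at least 2 bodies")
  raw <- .runSeeded(seed, {
    if (nBars > 0) {
      i <- sample.int(nBodies, nBars, replace = TRUE)
      off <- sample.int(nBodies - 1, nBars, replace = TRUE)
      j <- ((i - 1 + off) %% nBodies) + 1
      m <- sample(multiplicities, nBars, replace = TRUE)
      cbind(i = pmin(i, j), j = pmax(i, j), bars = as.integer(m))
    } else matrix(integer(), 0, 3, dimnames = list(NULL, c("i", "j", "bars")))
  })
  g <- bodyBarGraph(nBodies, raw)
  attr(g, "rawBars") <- raw
  g
}

#' Noisy coordinate ensemble fixture
#'
#' Independent isotropic Gaussian displacement per atom per frame, for RMSF
#' calibration against the closed form sigma * sqrt(3) * sqrt((n-1)/n).
#'
#' @param s a \code{PDBStructure}.
#' @param sigma per-coordinate noise, Angstrom (>= 0).
#' @param nFrames number of frames.
#' @param seed integer seed.
#' @return An \code{\linkS4class{Ensemble}}.
#' @export
noisyEnsemble <- function(s, sigma, nFrames, seed = 1L) {
  stopifnot(sigma >= 0, nFrames >= 1)
  base <- .coordMatrix(s@atoms)
  frames <- .runSeeded(seed, lapply(seq_len(nFrames), function(f)
    base + matrix(stats::rnorm(length(base), 0, sigma), ncol = 3)))
  new("Ensemble", frames = frames, atoms = s@atoms, stepsCompleted = 0L,
      haltReason = "none", frameSteps = seq_len(nFrames) - 1L,
      maxViolations = rep(0, nFrames))
}
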