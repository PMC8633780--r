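#' Build a one-node-per-residue elastic network
#'
#' One node per residue at the Calpha position; springs of uniform strength
#' join all node pairs strictly closer than the distance cutoff. The model
#' is built over every protein residue of the structure (both chains of a
#' dimer form one network).
#'
#' @param s a \code{PDBStructure}.
#' @param cutoff spring distance cutoff in Angstrom (default 10, open
#'   interval).
#' @param k uniform spring constant (default 1; only mode shapes matter
#'   downstream).
#' @return An \code{\linkS4class{ElasticNetwork}}.
#' @export
buildENM <- function(s, cutoff = 10.0, k = 1.0) {
  a <- s@atoms
  std <- a$resName %in% .standardResidues & !a$isHetero
  resTab <- .residueTable(a[std, , drop = FALSE])
  caRows <- .calphaRows(a)
  caKey <- paste(a$chainId[caRows], a$resNo[caRows], a$insert[caRows], sep = "\r")
  missing <- setdiff(resTab$key, caKey)
  if (length(missing))
    stop("residues lacking a Calpha: ",
         paste(gsub("\r", " ", missing), collapse = ", "))
  nodes <- .coordMatrix(a)[caRows, , drop = FALSE]
  info <- data.frame(chainId = a$chainId[caRows], resNo = a$resNo[caRows],
                     resName = a$resName[caRows], stringsAsFactors = FALSE)
  n <- nrow(nodes)
  pairs <- matrix(integer(), 0, 2)
  if (n > 1) {
    d2 <- .cdist2(nodes, nodes)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    pairs <- matrix(as.integer(hit), ncol = 2)
  }
  new("ElasticNetwork", nodes = nodes, nodeInfo = info, pairs = pairs,
      k = k, cutoff = cutoff)
}

# anisotropic network Hessian: per spring the 3x3 block -k r^ r^T
# off-diagonal, accumulated on the diagonal
.enmHessian <- function(net) {
  n <- nrow(net@nodes)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(net@pairs))) {
    i <- net@pairs[r, 1]; j <- net@pairs[r, 2]
    rij <- net@nodes[j, ] - net@nodes[i, ]
    u <- rij / sqrt(sum(rij^2))
    blk <- net@k * (u %o% u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

# orthonormal rigid-body motions (3 translations + up to 3 rotations about
# the centroid); near-null rotation axes (collinear geometry) are dropped
# when drop = TRUE
.rigidModes <- function(nodes, drop = FALSE) {
  n <- nrow(nodes)
  ctr <- colMeans(nodes)
  rel <- sweep(nodes, 2, ctr)
  vecs <- matrix(0, 3 * n, 6)
  for (ax in 1:3) vecs[seq(ax, 3 * n, by = 3), ax] <- 1
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    rot <- t(apply(rel, 1, function(r) .cross(e, r)))
    vecs[, 3 + ax] <- as.vector(t(rot))
  }
  norms <- sqrt(colSums(vecs^2))
  keep <- norms > 1e-8 * max(norms)
  if (!all(keep)) {
    if (!drop) stop("degenerate (collinear) node geometry")
    vecs <- vecs[, keep, drop = FALSE]
  }
  Q <- qr.Q(qr(vecs))[, seq_len(sum(keep)), drop = FALSE]
  # deterministic sign: first component of visible magnitude positive
  for (cl in seq_len(ncol(Q))) {
    nz <- which(abs(Q[, cl]) > 1e-8)[1]
    if (!is.na(nz) && Q[nz, cl] < 0) Q[, cl] <- -Q[, cl]
  }
  Q
}

#' Analytic rigid-body (trivial) modes
#'
#' The six zero-frequency motions of the whole network: three uniform
#' translations and three rotations about the centroid, orthonormalized.
#' Each is an exact null vector of the Hessian.
#'
#' @param net an \code{\linkS4class{ElasticNetwork}} with at least three
#'   non-collinear nodes.
#' @return A \code{\linkS4class{NormalModes}} with indices 1-6 and
#'   eigenvalue 0.
#' @export
trivialModes <- function(net) {
  if (nrow(net@nodes) < 3) stop("degenerate geometry: need >= 3 nodes")
  V <- .rigidModes(net@nodes, drop = FALSE)
  new("NormalModes", vectors = V, values = rep(0, 6), indices = 1:6,
      nNodes = nrow(net@nodes))
}

#' Lowest non-trivial normal modes by inverse iteration
#'
#' Extracts the \code{n} lowest-frequency internal modes without fully
#' diagonalizing the Hessian: shifted inverse iteration on the Hessian with
#' the rigid-body motions and previously found modes deflated by a spectral
#' shift. Modes are numbered from 7 upwards (the ten lowest internal
#' motions are modes 7-16), have unit norm, eigenvalues in non-decreasing
#' order, and a deterministic sign convention (first component of magnitude
#' above 1e-8 is positive).
#'
#' @param net an \code{\linkS4class{ElasticNetwork}}.
#' @param n number of non-trivial modes (default 10).
#' @param tol residual tolerance relative to a Gershgorin bound on the
#'   largest eigenvalue (default 1e-8): each mode satisfies
#'   \code{||Hv - lambda v|| <= tol * lambda_max}.
#' @param maxIter inverse-iteration sweep budget.
#' @return A \code{\linkS4class{NormalModes}} with indices 7..6+n.
#' @export
lowestModes <- function(net, n = 10, tol = 1e-8, maxIter = 500) {
  H <- .enmHessian(net)
  N3 <- nrow(H)
  V0 <- .rigidModes(net@nodes, drop = TRUE)
  nTrivial <- ncol(V0)
  if (n > N3 - nTrivial) stop("requested more modes than internal DOF")
  lamMax <- max(rowSums(abs(H)))          # Gershgorin upper bound
  if (lamMax <= 0) stop("network has no springs")
  # block inverse iteration on the trivial-deflated operator with
  # Rayleigh-Ritz extraction: robust to (near-)degenerate eigenvalues
  B <- H + 2 * lamMax * (V0 %*% t(V0))
  ch <- chol(B + 1e-12 * lamMax * diag(N3))
  m0 <- min(n + 4L, N3 - nTrivial)
  X <- outer(seq_len(N3), seq_len(m0), function(i, m) sin(i * (m + 0.37)))
  X <- X - V0 %*% crossprod(V0, X)
  X <- qr.Q(qr(X))
  res <- Inf
  for (it in seq_len(maxIter)) {
    X <- backsolve(ch, forwardsolve(t(ch), X))
    X <- X - V0 %*% crossprod(V0, X)
    X <- qr.Q(qr(X))
    ritz <- eigen(crossprod(X, H %*% X), symmetric = TRUE)
    ord <- order(ritz$values)
    X <- X %*% ritz$vectors[, ord, drop = FALSE]
    vals <- ritz$values[ord]
    R <- H %*% X[, seq_len(n), drop = FALSE] -
      X[, seq_len(n), drop = FALSE] %*% diag(vals[seq_len(n)], n)
    res <- max(sqrt(colSums(R^2)))
    if (res <= tol * lamMax) break
  }
  if (res > tol * lamMax)
    stop(sprintf("inverse iteration did not converge (residual %.3g after %d sweeps)",
                 res, maxIter))
  vectors <- X[, seq_len(n), drop = FALSE]
  values <- vals[seq_len(n)]
  # deterministic sign convention: first component above 1e-8 positive
  for (cl in seq_len(n)) {
    nz <- which(abs(vectors[, cl]) > 1e-8)[1]
    if (!is.na(nz) && vectors[nz, cl] < 0) vectors[, cl] <- -vectors[, cl]
  }
  new("NormalModes", vectors = vectors, values = values,
      indices = as.integer(6 + seq_len(n)), nNodes = nrow(net@nodes))
}

#' Mode participation of a region
#'
#' Sum of squared eigenvector components over the nodes of a region; a
#' whole-structure region gives exactly 1 for a unit-norm mode. Used to
#' quantify localization, e.g. of cap/lid modes.
#'
#' @param modes a \code{\linkS4class{NormalModes}}.
#' @param net the \code{\linkS4class{ElasticNetwork}} the modes belong to.
#' @param region a \code{\link{regionSelection}}.
#' @param which mode indices (as in \code{modeIndices}); default all.
#' @return named numeric vector of fractions in [0, 1].
#' @export
modeParticipation <- function(modes, net, region, which = modeIndices(modes)) {
  nodeIn <- net@nodeInfo$chainId == region@chainId &
            net@nodeInfo$resNo >= region@firstResidue &
            net@nodeInfo$resNo <= region@lastResidue
  if (!any(nodeIn)) stop("region selects no network nodes")
  comp <- rep(nodeIn, each = 3)
  cols <- match(which, modes@indices)
  if (anyNA(cols)) stop("mode index not present")
  out <- vapply(cols, function(cl) sum(modes@vectors[comp, cl]^2), numeric(1))
  names(out) <- sprintf("mode%02d", which)
  out
}

#' Write normal modes to text files
#'
#' Writes a plain-text eigenvalue table and a per-mode TSV of 3N vector
#' components; optionally a mode-animation multi-model PDB sweeping
#' plus/minus an amplitude along one mode.
#'
#' @param modes a \code{\linkS4class{NormalModes}}.
#' @param net the corresponding \code{\linkS4class{ElasticNetwork}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeModes <- function(modes, net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(
    data.frame(mode = modes@indices, eigenvalue = modes@values),
    file.path(dir, "eigenvalues.txt"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tab <- data.frame(chain = rep(net@nodeInfo$chainId, each = 3),
                    resNo = rep(net@nodeInfo$resNo, each = 3),
                    axis = rep(c("x", "y", "z"), nrow(net@nodes)))
  for (cl in seq_along(modes@indices))
    tab[[sprintf("mode%02d", modes@indices[cl])]] <- modes@vectors[, cl]
  utils::write.table(tab, file.path(dir, "modes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Mode animation as a multi-model PDB of Calpha traces
#'
#' @param modes,net as in \code{\link{writeModes}}.
#' @param index mode index to animate.
#' @param amplitude sweep amplitude in Angstrom.
#' @param nFrames frames over one full sweep.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModeAnimation <- function(modes, net, index, path, amplitude = 3,
                               nFrames = 7) {
  cl <- match(index, modes@indices)
  if (is.na(cl)) stop("mode index not present")
  v <- matrix(modes@vectors[, cl], ncol = 3, byrow = TRUE)
  info <- net@nodeInfo
  base <- data.frame(serial = seq_len(nrow(info)), name = "CA", element = "C",
                     altLoc = "", resName = info$resName, chainId = info$chainId,
                     resNo = info$resNo, insert = "", x = 0, y = 0, z = 0,
                     occupancy = 1, b = 0, isHetero = FALSE,
                     stringsAsFactors = FALSE)
  amps <- amplitude * sin(seq(0, 2 * pi, length.out = nFrames))
  frames <- lapply(amps, function(am)
    setCoords(structureFromAtoms(base), net@nodes + am * v))
  writeEnsemble(frames, path)
}
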