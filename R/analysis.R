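# Kabsch superposition: optimal proper rotation of Y onto X (both centred)
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Yc, Xc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, cx = cx, cy = cy,
       fit = sweep(Yc %*% t(R), 2, cx, `+`))
}

#' Least-squares superposition RMSD (Kabsch)
#'
#' Optimal proper-rotation superposition of two equal-length atom
#' selections followed by the root-mean-square deviation. Structures are
#' paired by residue number and atom name; a pairing with fewer than three
#' common atoms is an error.
#'
#' @param a,b \code{PDBStructure}s or n x 3 coordinate matrices.
#' @param chainA,chainB chains to select when \code{a}/\code{b} are
#'   structures (default: all).
#' @param atomNames atom names used for pairing (default \code{"CA"}).
#' @return RMSD in Angstrom.
#' @export
kabschRMSD <- function(a, b, chainA = NULL, chainB = NULL, atomNames = "CA") {
  sel <- function(s, chain) {
    if (is.matrix(s)) return(s)
    at <- s@atoms
    keep <- !at$isHetero & at$name %in% atomNames & at$element != "H"
    if (!is.null(chain)) keep <- keep & at$chainId %in% chain
    at <- at[keep, , drop = FALSE]
    key <- paste(at$resNo, at$insert, at$name)
    at <- at[!duplicated(key), , drop = FALSE]
    m <- .coordMatrix(at)
    rownames(m) <- paste(at$resNo, at$insert, at$name)
    m
  }
  X <- sel(a, chainA); Y <- sel(b, chainB)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    common <- intersect(rownames(X), rownames(Y))
    if (length(common) < 3)
      stop(sprintf("pairing failed: %d common atoms (%d vs %d selected)",
                   length(common), nrow(X), nrow(Y)))
    X <- X[common, , drop = FALSE]; Y <- Y[common, , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop(sprintf("length mismatch: %d vs %d atoms", nrow(X), nrow(Y)))
  }
  fit <- .kabsch(X, Y)$fit
  sqrt(mean(rowSums((X - fit)^2)))
}

#' Per-residue RMSF of an ensemble
#'
#' Frames are superposed onto the ensemble mean (one reiteration of the
#' mean after fitting) and the root-mean-square displacement of each
#' residue's Calpha from its mean position is reported.
#'
#' @param e an \code{\linkS4class{Ensemble}} (>= 2 frames).
#' @param superpose superpose frames first? Default \code{TRUE}; disable
#'   when frames are already aligned (e.g. anchored fixtures).
#' @return data.frame with \code{chainId}, \code{resNo}, \code{resName},
#'   \code{rmsf} (Angstrom; attribute \code{unit}).
#' @export
rmsf <- function(e, superpose = TRUE) {
  if (length(e@frames) < 2) stop("RMSF needs at least 2 frames")
  ca <- .calphaRows(e@atoms)
  if (!length(ca)) stop("no Calpha atoms in ensemble")
  mats <- lapply(e@frames, function(f) f[ca, , drop = FALSE])
  if (superpose) {
    ref <- Reduce(`+`, mats) / length(mats)
    mats <- lapply(mats, function(m) .kabsch(ref, m)$fit)
    ref <- Reduce(`+`, mats) / length(mats)
    mats <- lapply(mats, function(m) .kabsch(ref, m)$fit)
  }
  mean <- Reduce(`+`, mats) / length(mats)
  msd <- Reduce(`+`, lapply(mats, function(m) rowSums((m - mean)^2))) /
    length(mats)
  out <- data.frame(chainId = e@atoms$chainId[ca], resNo = e@atoms$resNo[ca],
                    resName = e@atoms$resName[ca], rmsf = sqrt(msd),
                    stringsAsFactors = FALSE)
  attr(out, "unit") <- "Angstrom"
  out
}

#' Calpha B-factor profile with region normalization
#'
#' Mean Calpha B-factor over the whole structure and over a region, and
#' their ratio (the normalized fold change used to compare cap/lid mobility
#' across structures).
#'
#' @param s a \code{PDBStructure} whose Calpha atoms carry B-factors.
#' @param region a \code{\link{regionSelection}}.
#' @return list with \code{perResidue} (chain, resNo, resName, b),
#'   \code{overallMean}, \code{regionMean}, \code{normalizedFold}.
#' @export
bfactorProfile <- function(s, region) {
  a <- s@atoms
  ca <- .calphaRows(a)
  if (!length(ca)) stop("no Calpha atoms")
  per <- data.frame(chainId = a$chainId[ca], resNo = a$resNo[ca],
                    resName = a$resName[ca], b = a$b[ca],
                    stringsAsFactors = FALSE)
  inRegion <- per$chainId == region@chainId &
    per$resNo >= region@firstResidue & per$resNo <= region@lastResidue
  if (!any(inRegion)) stop("region contains no Calpha atoms")
  overall <- mean(per$b)
  regionMean <- mean(per$b[inRegion])
  list(perResidue = per, overallMean = overall, regionMean = regionMean,
       normalizedFold = regionMean / overall)
}

# deterministic Fibonacci-lattice points on the unit sphere
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a rolled probe: each atom's solvent sphere (vdW
#' radius + probe) is sampled on a deterministic Fibonacci lattice and
#' points inside any neighbour's solvent sphere are discarded.
#'
#' @param s a \code{PDBStructure}.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param nPoints sample points per atom (default 960).
#' @param includeHydrogens include H atoms as spheres? Default \code{FALSE}.
#' @param radii named vdW radius set, element -> Angstrom.
#' @param chains optional chain subset.
#' @return per-atom areas (Angstrom^2) named by atom serial, with
#'   attribute \code{total}.
#' @export
sasa <- function(s, probe = 1.4, nPoints = 960, includeHydrogens = FALSE,
                 radii = interactionParams()$vdwRadii, chains = NULL) {
  a <- s@atoms
  keep <- rep(TRUE, nrow(a))
  if (!includeHydrogens) keep <- a$element != "H"
  if (!is.null(chains)) keep <- keep & a$chainId %in% chains
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("no atoms selected")
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  xyz <- .coordMatrix(a)
  r <- unname(radii[a$element]) + probe
  pts <- .spherePoints(nPoints)
  n <- nrow(a)
  d2 <- .cdist2(xyz, xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    if (length(nbr)) {
      free <- rep(TRUE, nPoints)
      for (j in nbr) {
        if (!any(free)) break
        dj2 <- colSums((t(p[free, , drop = FALSE]) - xyz[j, ])^2)
        free[free] <- dj2 >= r[j]^2
      }
      frac <- mean(free)
    } else frac <- 1
    areas[i] <- 4 * pi * r[i]^2 * frac
  }
  names(areas) <- a$serial
  attr(areas, "total") <- sum(areas)
  areas
}

#' Buried interface area between two chains
#'
#' Half the SASA buried on complex formation:
#' (SASA(A) + SASA(B) - SASA(AB)) / 2.
#'
#' @param s a \code{PDBStructure} containing both chains.
#' @param chainA,chainB chain identifiers.
#' @param ... passed to \code{\link{sasa}}.
#' @return interface area, Angstrom^2.
#' @export
interfaceArea <- function(s, chainA, chainB, ...) {
  present <- chainIds(s)
  if (!chainA %in% present || !chainB %in% present)
    stop("chain(s) missing: ", paste(setdiff(c(chainA, chainB), present),
                                     collapse = ", "))
  sA <- attr(sasa(s, chains = chainA, ...), "total")
  sB <- attr(sasa(s, chains = chainB, ...), "total")
  sAB <- attr(sasa(s, chains = c(chainA, chainB), ...), "total")
  (sA + sB - sAB) / 2
}

#' Residue composition census
#'
#' Counts per 3-letter residue code plus derived classes: acidic (Asp+Glu),
#' basic (Lys+Arg), charged (Asp, Glu, Lys, Arg) and the charged fraction.
#' SEQRES is preferred when available so the census does not depend on
#' disordered residues missing from the coordinates; the source used is
#' recorded.
#'
#' @param s a \code{PDBStructure}.
#' @param chain chain identifier(s); default all chains.
#' @param source \code{"auto"} (SEQRES when present), \code{"seqres"}, or
#'   \code{"observed"}.
#' @return list with \code{counts} (named integer vector), \code{acidic},
#'   \code{basic}, \code{charged}, \code{fractionCharged}, \code{total},
#'   \code{source}.
#' @export
compositionCensus <- function(s, chain = NULL,
                              source = c("auto", "seqres", "observed")) {
  source <- match.arg(source)
  useSeqres <- length(s@seqres) > 0 && source != "observed"
  if (source == "seqres" && !length(s@seqres)) stop("no SEQRES records")
  if (useSeqres) {
    sq <- s@seqres
    if (!is.null(chain)) sq <- sq[names(sq) %in% chain]
    codes <- toupper(unlist(sq, use.names = FALSE))
    src <- "seqres"
  } else {
    a <- s@atoms[!s@atoms$isHetero, , drop = FALSE]
    if (!is.null(chain)) a <- a[a$chainId %in% chain, , drop = FALSE]
    rt <- .residueTable(a)
    codes <- rt$resName
    src <- "observed"
  }
  counts <- table(factor(codes))
  counts <- stats::setNames(as.integer(counts), names(counts))
  get <- function(x) sum(counts[intersect(x, names(counts))])
  total <- sum(counts)
  list(counts = counts,
       acidic = get(c("ASP", "GLU")),
       basic = get(c("LYS", "ARG")),
       charged = get(c("ASP", "GLU", "LYS", "ARG")),
       fractionCharged = if (total) get(c("ASP", "GLU", "LYS", "ARG")) / total else 0,
       total = total, source = src)
}
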