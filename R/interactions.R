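#' Detect covalent bonds
#'
#' Intra-residue bonds come from residue topology templates; peptide C-N
#' bonds join consecutive residues of a chain (a C-N distance above 2.0 A
#' is treated as a chain break and skipped with a warning); disulfides are
#' assigned for SG-SG pairs under 2.3 A. Peptide bonds and double/partial
#' double bonds (carbonyl, carboxylate, amide, guanidinium, rings) are
#' \code{covalent_locked}; other single bonds are \code{covalent_rotatable};
#' hydrogens are locked to their parent heavy atom. Non-standard (hetero)
#' residues fall back to distance-based single bonds.
#'
#' @param s a \code{PDBStructure}.
#' @return data.frame of constraints with columns \code{kind}, \code{i},
#'   \code{j} (atom row indices), \code{distance}, \code{energy} (0),
#'   \code{salt} (FALSE).
#' @export
detectCovalent <- function(s) {
  a <- s@atoms
  xyz <- .coordMatrix(a)
  resRows <- .residueRowIndex(a)
  resTab <- .residueTable(a)
  ii <- integer(); jj <- integer(); locked <- logical()
  push <- function(i, j, l) {
    ii <<- c(ii, i); jj <<- c(jj, j); locked <<- c(locked, l)
  }
  findAtom <- function(rows, nm) {
    r <- rows[a$name[rows] == nm]
    if (length(r)) r[1] else NA_integer_
  }

  for (k in seq_along(resRows)) {
    rows <- resRows[[k]]
    rn <- resTab$resName[k]
    if (rn %in% .standardResidues) {
      tmpl <- c(.backboneBonds, .sideChainBonds[[rn]])
      for (b in tmpl) {
        i <- findAtom(rows, b[1]); j <- findAtom(rows, b[2])
        if (is.na(i) || is.na(j)) next
        l <- b[3] == "l" || (rn == "PRO" && paste(b[1], b[2]) %in% .prolineLockedBackbone)
        push(i, j, l)
      }
    } else {
      # unknown residue: distance-based heavy-atom bonds within the residue
      hv <- rows[a$element[rows] != "H"]
      if (length(hv) > 1) {
        d2 <- .cdist2(xyz[hv, , drop = FALSE], xyz[hv, , drop = FALSE])
        for (p in seq_along(hv)) for (q in seq_along(hv)) {
          if (p < q && d2[p, q] < 1.8^2) push(hv[p], hv[q], FALSE)
        }
      }
    }
    # hydrogens lock to the nearest heavy atom of the residue
    hs <- rows[a$element[rows] == "H"]
    hv <- rows[a$element[rows] != "H"]
    if (length(hs) && length(hv)) {
      d2 <- .cdist2(xyz[hs, , drop = FALSE], xyz[hv, , drop = FALSE])
      for (p in seq_along(hs)) {
        q <- which.min(d2[p, ])
        if (d2[p, q] < 1.6^2) push(hs[p], hv[q], TRUE)
      }
    }
  }

  # peptide bonds between consecutive residues of the same chain
  for (k in seq_len(length(resRows) - 1)) {
    if (resTab$chainId[k] != resTab$chainId[k + 1]) next
    if (!resTab$resName[k] %in% .standardResidues ||
        !resTab$resName[k + 1] %in% .standardResidues) next
    i <- findAtom(resRows[[k]], "C"); j <- findAtom(resRows[[k + 1]], "N")
    if (is.na(i) || is.na(j)) next
    d <- .vnorm(xyz[i, ] - xyz[j, ])
    if (d > 2.0) {
      warning(sprintf("chain break between %s%d and %s%d (C-N %.2f A)",
                      resTab$chainId[k], resTab$resNo[k],
                      resTab$chainId[k + 1], resTab$resNo[k + 1], d))
      next
    }
    push(i, j, TRUE)
  }

  # disulfides
  sg <- which(a$name == "SG" & a$resName == "CYS")
  if (length(sg) > 1) {
    d2 <- .cdist2(xyz[sg, , drop = FALSE], xyz[sg, , drop = FALSE])
    for (p in seq_along(sg)) for (q in seq_along(sg))
      if (p < q && d2[p, q] < 2.3^2) push(sg[p], sg[q], FALSE)
  }

  if (!length(ii))
    return(data.frame(kind = character(), i = integer(), j = integer(),
                      distance = numeric(), energy = numeric(), salt = logical(),
                      stringsAsFactors = FALSE))
  # terminal single-bond pendants (O-H, methyl C, ...) lock to their parent
  # body: a pendant's only degree of freedom would be a spin about its bond
  deg <- tabulate(c(ii, jj), nbins = nrow(a))
  locked <- locked | deg[ii] == 1 | deg[jj] == 1
  d <- sqrt(rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2))
  out <- data.frame(kind = ifelse(locked, "covalent_locked", "covalent_rotatable"),
                    i = pmin(ii, jj), j = pmax(ii, jj), distance = d,
                    energy = 0, salt = FALSE, stringsAsFactors = FALSE)
  out[!duplicated(paste(out$i, out$j)), , drop = FALSE]
}

#' Detect hydrophobic tethers
#'
#' One tether per pair of carbon/sulfur atoms from residues more than two
#' apart in sequence (or on different chains) whose distance is below the
#' sum of van der Waals radii plus \code{tetherVdwSlop}; only the single
#' shortest qualifying contact per residue pair is retained.
#'
#' @param s a \code{PDBStructure}.
#' @param p an \code{\link{interactionParams}} object.
#' @return constraint data.frame (\code{kind = "tether"}).
#' @export
detectTethers <- function(s, p = interactionParams()) {
  a <- s@atoms
  cand <- which(a$element %in% c("C", "S") & !a$isHetero)
  empty <- data.frame(kind = character(), i = integer(), j = integer(),
                      distance = numeric(), energy = numeric(), salt = logical(),
                      stringsAsFactors = FALSE)
  if (length(cand) < 2) return(empty)
  xyz <- .coordMatrix(a)[cand, , drop = FALSE]
  rad <- p$vdwRadii[a$element[cand]]
  maxR <- max(rad) * 2 + p$tetherVdwSlop
  d2 <- .cdist2(xyz, xyz)
  hit <- which(d2 < maxR^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (!nrow(hit)) return(empty)
  i <- cand[hit[, 1]]; j <- cand[hit[, 2]]
  d <- sqrt(d2[hit])
  ok <- d < (rad[hit[, 1]] + rad[hit[, 2]] + p$tetherVdwSlop) &
        (a$chainId[i] != a$chainId[j] | abs(a$resNo[i] - a$resNo[j]) > 2)
  i <- i[ok]; j <- j[ok]; d <- d[ok]
  if (!length(i)) return(empty)
  respair <- paste(a$chainId[i], a$resNo[i], a$insert[i], "|",
                   a$chainId[j], a$resNo[j], a$insert[j])
  keep <- unlist(lapply(split(seq_along(d), respair),
                        function(idx) idx[which.min(d[idx])]), use.names = FALSE)
  data.frame(kind = "tether", i = i[keep], j = j[keep], distance = d[keep],
             energy = 0, salt = FALSE, stringsAsFactors = FALSE)
}

# Mayo-form hydrogen-bond well: V0 * (5 (d0/d)^12 - 6 (d0/d)^10) * cos^2(theta),
# d the donor-acceptor distance, theta the D-H...A angle; clamped to [-10, 0].
.mayoEnergy <- function(d, thetaDeg, p) {
  r <- p$mayoEquilibrium / d
  e <- p$mayoWellDepth * (5 * r^12 - 6 * r^10) * cos(thetaDeg * pi / 180)^2
  pmin(0, pmax(-10, e))
}

#' Detect polar interactions (hydrogen bonds and salt bridges)
#'
#' Donor-H...acceptor triples must pass three geometric gates (donor-
#' acceptor and hydrogen-acceptor distance maxima, minimum D-H-A angle) and
#' are scored with a Mayo-form well clamped to [-10, 0] kcal/mol. Pairs of
#' charged side-chain groups (Asp/Glu carboxylate O against Lys NZ, Arg
#' guanidinium N or His ring N) within the salt-bridge cutoff are classed
#' salt bridges instead and pinned at the salt-bridge energy, which keeps
#' them through every dilution cut-off; a donor without an attached H only
#' contributes via the salt-bridge route.
#'
#' @param s a \code{PDBStructure}, normally after
#'   \code{\link{addPolarHydrogens}}.
#' @param p an \code{\link{interactionParams}} object.
#' @return constraint data.frame (\code{kind = "polar"}, donor-acceptor atom
#'   indices, energies in kcal/mol, \code{salt} flag).
#' @export
detectPolar <- function(s, p = interactionParams()) {
  a <- s@atoms
  xyz <- .coordMatrix(a)
  empty <- data.frame(kind = character(), i = integer(), j = integer(),
                      distance = numeric(), energy = numeric(), salt = logical(),
                      stringsAsFactors = FALSE)

  std <- a$resName %in% .standardResidues & !a$isHetero
  # donors: heavy N/O/S with at least one attached H
  heavyDonorOk <- std & a$element %in% c("N", "O", "S")
  hIdx <- which(a$element == "H")
  donH <- list()
  if (length(hIdx)) {
    heavy <- which(a$element != "H")
    d2 <- .cdist2(xyz[hIdx, , drop = FALSE], xyz[heavy, , drop = FALSE])
    parent <- heavy[apply(d2, 1, which.min)]
    near <- sqrt(d2[cbind(seq_along(hIdx), apply(d2, 1, which.min))]) < 1.6
    for (q in which(near & heavyDonorOk[parent]))
      donH[[as.character(parent[q])]] <- c(donH[[as.character(parent[q])]], hIdx[q])
  }
  donors <- as.integer(names(donH))

  # acceptors: backbone O/OXT plus side-chain acceptor atoms
  accept <- which(std & (a$name %in% c("O", "OXT") |
    mapply(function(rn, nm) nm %in% (.acceptorAtoms[[rn]] %||% character()),
           a$resName, a$name)))

  # covalent graph distances <= 2 are excluded from donor-acceptor pairing
  cov <- detectCovalent(s)
  nbr <- .neighborSets(cov, nrow(a), depth = 2)

  out <- list()
  if (length(donors) && length(accept)) {
    d2 <- .cdist2(xyz[donors, , drop = FALSE], xyz[accept, , drop = FALSE])
    cand <- which(d2 <= p$hbDonorAcceptorMax^2, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      D <- donors[cand[r, 1]]; A <- accept[cand[r, 2]]
      if (D == A) next
      sameRes <- a$chainId[D] == a$chainId[A] && a$resNo[D] == a$resNo[A] &&
                 a$insert[D] == a$insert[A]
      if (sameRes) next
      if (A %in% nbr[[D]]) next
      dDA <- sqrt(d2[cand[r, 1], cand[r, 2]])
      best <- NULL
      for (H in donH[[as.character(D)]]) {
        dHA <- .vnorm(xyz[H, ] - xyz[A, ])
        if (dHA > p$hbHydrogenAcceptorMax) next
        th <- .angle(xyz[D, ], xyz[H, ], xyz[A, ])
        if (th < p$hbDHAMinAngle) next
        if (is.null(best) || th > best) best <- th
      }
      if (is.null(best)) next
      out[[length(out) + 1]] <- data.frame(
        kind = "polar", i = min(D, A), j = max(D, A), distance = dDA,
        energy = .mayoEnergy(dDA, best, p), salt = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  hb <- if (length(out)) do.call(rbind, out) else empty
  # one polar constraint per atom pair: keep the strongest
  if (nrow(hb)) {
    hb <- hb[order(hb$energy), , drop = FALSE]
    hb <- hb[!duplicated(paste(hb$i, hb$j)), , drop = FALSE]
  }

  sb <- .saltBridgePairs(a, xyz, p$saltBridgeCutoff)
  if (nrow(sb)) {
    sb$kind <- "polar"; sb$energy <- p$saltBridgeEnergy; sb$salt <- TRUE
    # salt-bridge classification wins over the hydrogen-bond route for the
    # same charged residue pair
    rpair <- function(df) {
      r1 <- paste(a$chainId[df$i], a$resNo[df$i], a$insert[df$i])
      r2 <- paste(a$chainId[df$j], a$resNo[df$j], a$insert[df$j])
      paste(pmin(r1, r2), pmax(r1, r2), sep = "|")
    }
    if (nrow(hb)) {
      chargedAtom <- function(i)
        mapply(function(rn, nm) nm %in% c(.acidicAtoms[[rn]], .basicAtoms[[rn]]),
               a$resName[i], a$name[i])
      drop <- rpair(hb) %in% rpair(sb) & chargedAtom(hb$i) & chargedAtom(hb$j)
      hb <- hb[!drop, , drop = FALSE]
    }
    sb <- sb[, c("kind", "i", "j", "distance", "energy", "salt")]
  }
  res <- rbind(hb, sb)
  rownames(res) <- NULL
  res[order(res$i, res$j), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closest acidic-O / basic-N atom pair per oppositely charged residue pair
# within cutoff
.saltBridgePairs <- function(a, xyz, cutoff) {
  std <- a$resName %in% .standardResidues & !a$isHetero
  acid <- which(std & mapply(function(rn, nm)
    nm %in% (.acidicAtoms[[rn]] %||% character()), a$resName, a$name))
  base <- which(std & mapply(function(rn, nm)
    nm %in% (.basicAtoms[[rn]] %||% character()), a$resName, a$name))
  empty <- data.frame(i = integer(), j = integer(), distance = numeric(),
                      kind = character(), energy = numeric(), salt = logical(),
                      stringsAsFactors = FALSE)
  if (!length(acid) || !length(base)) return(empty)
  d2 <- .cdist2(xyz[acid, , drop = FALSE], xyz[base, , drop = FALSE])
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- acid[hit[, 1]]; j <- base[hit[, 2]]
  d <- sqrt(d2[hit])
  rp <- paste(a$chainId[i], a$resNo[i], a$insert[i], "|",
              a$chainId[j], a$resNo[j], a$insert[j])
  keep <- unlist(lapply(split(seq_along(d), rp),
                        function(idx) idx[which.min(d[idx])]), use.names = FALSE)
  data.frame(i = pmin(i, j)[keep], j = pmax(i, j)[keep], distance = d[keep],
             kind = "polar", energy = 0, salt = TRUE, stringsAsFactors = FALSE)
}

# adjacency sets up to a bond-graph depth
.neighborSets <- function(cov, n, depth = 2) {
  adj <- vector("list", n)
  if (nrow(cov)) {
    for (r in seq_len(nrow(cov))) {
      adj[[cov$i[r]]] <- c(adj[[cov$i[r]]], cov$j[r])
      adj[[cov$j[r]]] <- c(adj[[cov$j[r]]], cov$i[r])
    }
  }
  out <- adj
  if (depth >= 2) {
    for (v in seq_len(n)) {
      n1 <- adj[[v]]
      if (length(n1)) out[[v]] <- unique(c(n1, unlist(adj[n1])))
    }
  }
  out
}

#' Count salt bridges
#'
#' Number of unique oppositely charged side-chain residue pairs (Asp/Glu
#' carboxylate O against Arg/Lys/His side-chain N) with any inter-atom
#' distance under the cutoff; each residue pair counts once. Hydrogens are
#' not required. This mirrors the convention of ESBRI-style censuses
#' (His counted as charged).
#'
#' @param s a \code{PDBStructure}.
#' @param selection \code{NULL} (whole structure), a chain id, or a
#'   \code{\link{regionSelection}}; both residues of a pair must fall in
#'   the selection.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return integer count.
#' @export
countSaltBridges <- function(s, selection = NULL, cutoff = 4.0) {
  a <- s@atoms
  keep <- rep(TRUE, nrow(a))
  if (is.character(selection)) keep <- a$chainId %in% selection
  else if (is(selection, "RegionSelection"))
    keep <- seq_len(nrow(a)) %in% .regionRows(a, selection)
  sub <- a[keep, , drop = FALSE]
  if (!nrow(sub)) return(0L)
  sb <- .saltBridgePairs(sub, .coordMatrix(sub), cutoff)
  nrow(sb)
}

#' Build the constraint network
#'
#' Union of covalent bonds, hydrophobic tethers and the polar interactions
#' at or below the energy cut-off, with bar multiplicities assigned per
#' temperature regime: locked covalent 6, rotatable covalent 5, polar 5,
#' tether 2 under \code{"ambient"} or 1 under \code{"cold"} (modelling the
#' weakened hydrophobic effect at low temperature). Hetero atoms (waters,
#' additives) are excluded.
#'
#' @param s a \code{PDBStructure} (polar hydrogens recommended).
#' @param cutoff polar energy cut-off, kcal/mol (<= 0).
#' @param regime \code{"ambient"} or \code{"cold"}.
#' @param p an \code{\link{interactionParams}} object.
#' @param covalent,tethers,polar optional precomputed constraint tables, to
#'   avoid re-detection across a dilution series.
#' @return A \code{\linkS4class{ConstraintNetwork}}.
#' @export
buildNetwork <- function(s, cutoff = -1.0, regime = c("ambient", "cold"),
                         p = interactionParams(), covalent = NULL,
                         tethers = NULL, polar = NULL) {
  regime <- match.arg(regime)
  stopifnot(cutoff <= 0)
  if (is.null(covalent)) covalent <- detectCovalent(s)
  if (is.null(tethers)) tethers <- detectTethers(s, p)
  if (is.null(polar)) polar <- detectPolar(s, p)
  polar <- polar[polar$energy <= cutoff + 1e-12, , drop = FALSE]
  k <- rbind(covalent, tethers, polar)
  if (nrow(k)) {
    het <- s@atoms$isHetero
    k <- k[!het[k$i] & !het[k$j], , drop = FALSE]
    tb <- if (regime == "cold") 1L else 2L
    k$bars <- ifelse(k$kind == "covalent_locked", 6L,
              ifelse(k$kind == "covalent_rotatable", 5L,
              ifelse(k$kind == "polar", 5L, tb)))
    rownames(k) <- NULL
  } else k$bars <- integer()
  new("ConstraintNetwork", structure = s, constraints = k, cutoff = cutoff,
      regime = regime)
}

#' Write / read a constraint table
#'
#' Tabular dump (TSV) of a network's constraints with atom annotations, for
#' reproducibility and parameter sweeps.
#'
#' @param net a \code{\linkS4class{ConstraintNetwork}}.
#' @param path output path.
#' @return \code{writeConstraints}: \code{path}, invisibly.
#' @export
writeConstraints <- function(net, path) {
  a <- net@structure@atoms
  k <- net@constraints
  tab <- data.frame(kind = k$kind,
                    chain_i = a$chainId[k$i], res_i = a$resNo[k$i],
                    atom_i = a$name[k$i],
                    chain_j = a$chainId[k$j], res_j = a$resNo[k$j],
                    atom_j = a$name[k$j],
                    distance = round(k$distance, 3), energy = round(k$energy, 3),
                    bars = k$bars, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConstraints
#' @param path path to a TSV written by \code{writeConstraints}.
#' @return \code{readConstraints}: the constraint annotation data.frame.
#' @export
readConstraints <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
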