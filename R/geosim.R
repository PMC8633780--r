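#' Distance-constraint targets for geometric simulation
#'
#' Encodes the bonding and steric geometry of the input structure as pure
#' distance constraints: equality constraints on covalent bond lengths,
#' 1-3 distances (angle surrogates) and 1-4 distances across locked bonds
#' (peptide/aromatic dihedral surrogates), all at their crystal-structure
#' values; upper bounds on the network's polar and tether contacts at their
#' crystal distances (they may shorten but not lengthen beyond tolerance);
#' and steric lower bounds at \code{stericFactor} times the van der Waals
#' sum for non-bonded pairs (1-2, 1-3, 1-4 neighbours and constrained
#' contacts excluded), assembled lazily against the current coordinates
#' during relaxation.
#'
#' @param s a \code{PDBStructure}.
#' @param net a \code{\linkS4class{ConstraintNetwork}} built at the
#'   simulation cut-off.
#' @param cfg a \code{\link{geoSimConfig}}.
#' @param p an \code{\link{interactionParams}} (for van der Waals radii).
#' @return list with components \code{eq} (matrix i,j + \code{eqTargets}),
#'   \code{ub}/\code{ubTargets}, \code{excluded} (pair keys exempt from
#'   sterics), \code{radii} (per-atom vdW radii), \code{stericFloorMax}.
#' @export
constraintTargets <- function(s, net, cfg = geoSimConfig(),
                              p = interactionParams()) {
  a <- s@atoms
  xyz <- .coordMatrix(a)
  k <- net@constraints
  cov <- k[k$kind %in% c("covalent_locked", "covalent_rotatable"), , drop = FALSE]
  nAt <- nrow(a)

  adj <- vector("list", nAt)
  lockedKey <- character()
  if (nrow(cov)) {
    for (r in seq_len(nrow(cov))) {
      adj[[cov$i[r]]] <- c(adj[[cov$i[r]]], cov$j[r])
      adj[[cov$j[r]]] <- c(adj[[cov$j[r]]], cov$i[r])
    }
    lockedKey <- paste(pmin(cov$i, cov$j), pmax(cov$i, cov$j))[
      cov$kind == "covalent_locked"]
  }

  ei <- cov$i; ej <- cov$j
  # 1-3 pairs through every bonded centre
  for (b in seq_len(nAt)) {
    nb <- adj[[b]]
    if (length(nb) > 1) {
      cmb <- utils::combn(sort(nb), 2)
      ei <- c(ei, cmb[1, ]); ej <- c(ej, cmb[2, ])
    }
  }
  # 1-4 pairs across locked middle bonds
  if (nrow(cov)) {
    lk <- cov[cov$kind == "covalent_locked", , drop = FALSE]
    for (r in seq_len(nrow(lk))) {
      b <- lk$i[r]; c <- lk$j[r]
      for (aa in setdiff(adj[[b]], c)) for (dd in setdiff(adj[[c]], b)) {
        if (aa != dd) { ei <- c(ei, min(aa, dd)); ej <- c(ej, max(aa, dd)) }
      }
    }
  }
  eq <- unique(data.frame(i = pmin(ei, ej), j = pmax(ei, ej)))
  eq <- eq[eq$i != eq$j, , drop = FALSE]
  eqT <- sqrt(rowSums((xyz[eq$i, , drop = FALSE] - xyz[eq$j, , drop = FALSE])^2))

  nc <- k[k$kind %in% c("polar", "tether"), , drop = FALSE]
  ub <- data.frame(i = pmin(nc$i, nc$j), j = pmax(nc$i, nc$j))
  ubT <- sqrt(rowSums((xyz[ub$i, , drop = FALSE] - xyz[ub$j, , drop = FALSE])^2))

  # steric exclusions: 1-2/1-3/1-4 neighbourhood plus constrained contacts
  # (including the atoms bonded to a contact's endpoints, so e.g. the H of a
  # hydrogen bond is not pushed off its acceptor by the steric floor)
  n3 <- .neighborSets(cov, nAt, depth = 2)
  exKeys <- c(paste(eq$i, eq$j), paste(ub$i, ub$j))
  if (nrow(ub)) {
    for (r in seq_len(nrow(ub))) {
      i <- ub[r, 1]; j <- ub[r, 2]
      ni <- adj[[i]]; nj <- adj[[j]]
      if (length(ni)) exKeys <- c(exKeys, paste(pmin(ni, j), pmax(ni, j)))
      if (length(nj)) exKeys <- c(exKeys, paste(pmin(nj, i), pmax(nj, i)))
    }
  }
  for (v in seq_len(nAt)) {
    n1 <- n3[[v]]
    if (length(n1)) {
      n4 <- unique(c(n1, unlist(adj[n1])))
      n4 <- n4[n4 != v]
      exKeys <- c(exKeys, paste(pmin(v, n4), pmax(v, n4)))
    }
  }
  radii <- unname(p$vdwRadii[a$element])
  radii[is.na(radii)] <- 1.5
  list(eq = as.matrix(eq), eqTargets = eqT, ub = as.matrix(ub), ubTargets = ubT,
       excluded = unique(exKeys), radii = radii,
       stericFloorMax = cfg@stericFactor * 2 * max(radii))
}

# current steric lower-bound pairs: all non-excluded pairs within floor +
# margin of each other
.stericPairs <- function(xyz, targets, cfg, margin = 0.3) {
  d2 <- .cdist2(xyz, xyz)
  lim <- targets$stericFloorMax + margin
  hit <- which(d2 < lim^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (!nrow(hit)) return(list(lb = matrix(integer(), 0, 2), lbT = numeric()))
  keys <- paste(hit[, 1], hit[, 2])
  keep <- !(keys %in% targets$excluded)
  hit <- hit[keep, , drop = FALSE]
  floor <- cfg@stericFactor * (targets$radii[hit[, 1]] + targets$radii[hit[, 2]])
  near <- d2[hit] < (floor + margin)^2
  list(lb = matrix(as.integer(hit[near, , drop = FALSE]), ncol = 2),
       lbT = floor[near])
}

#' Relax coordinates onto the constraint targets
#'
#' Iterative sequential projection: each sweep visits every constraint and
#' moves both atoms equally and oppositely along the pair axis to satisfy
#' it, until the maximum violation is within tolerance or the sweep budget
#' is exhausted. Coordinates already within tolerance are returned
#' unchanged (zero sweeps). Non-restorable geometry is signalled by a
#' returned violation above tolerance, not an error.
#'
#' @param coords n x 3 coordinate matrix.
#' @param targets from \code{\link{constraintTargets}}.
#' @param cfg a \code{\link{geoSimConfig}}.
#' @return list with \code{coords}, \code{sweeps}, \code{maxViolation}.
#' @export
relaxGeometry <- function(coords, targets, cfg = geoSimConfig()) {
  st <- .stericPairs(coords, targets, cfg)
  out <- .relax_cpp(coords, targets$eq, targets$eqTargets,
                    targets$ub, targets$ubTargets, st$lb, st$lbT,
                    cfg@tolerance, cfg@maxRelaxSweeps)
  list(coords = out$coords, sweeps = out$sweeps,
       maxViolation = out$maxViolation)
}

#' Project a Calpha normal mode onto all atoms
#'
#' Every atom inherits the displacement of its residue's network node; the
#' resulting all-atom vector is normalized to unit norm and scaled by the
#' per-step bias amplitude, negated for antiparallel runs.
#'
#' @param modes a \code{\linkS4class{NormalModes}}.
#' @param index mode index to project.
#' @param net the \code{\linkS4class{ElasticNetwork}} defining the nodes.
#' @param s the all-atom \code{PDBStructure}.
#' @param cfg a \code{\link{geoSimConfig}} (step scale and direction).
#' @return n x 3 matrix of per-atom bias displacements, Frobenius norm
#'   equal to \code{stepScale}.
#' @export
projectMode <- function(modes, index, net, s, cfg = geoSimConfig()) {
  cl <- match(index, modes@indices)
  if (is.na(cl)) stop("mode index not present")
  v <- matrix(modes@vectors[, cl], ncol = 3, byrow = TRUE)
  a <- s@atoms
  nodeKey <- paste(net@nodeInfo$chainId, net@nodeInfo$resNo)
  atomNode <- match(paste(a$chainId, a$resNo), nodeKey)
  if (anyNA(atomNode[!a$isHetero]))
    stop("residue without a network node: ",
         paste(unique(paste(a$chainId, a$resNo)[is.na(atomNode) & !a$isHetero]),
               collapse = ", "))
  atomNode[is.na(atomNode)] <- 1L  # hetero atoms ride along with node 1
  bias <- v[atomNode, , drop = FALSE]
  bias <- bias / sqrt(sum(bias^2)) * cfg@stepScale
  if (cfg@direction == "antiparallel") bias <- -bias
  bias
}

#' Run a geometric simulation of flexible motion
#'
#' Repeatedly biases the all-atom structure along a normal-mode direction
#' (per-step amplitude \code{stepScale}) and restores bonding and steric
#' geometry by constraint projection, halting after \code{maxSteps} or at
#' the first step whose geometry cannot be restored to within tolerance.
#' Every \code{frameInterval}-th step is saved as a frame, frame 0 (the
#' input structure) included. The run is fully deterministic.
#'
#' @param s a \code{PDBStructure} (with polar hydrogens if the network was
#'   built with them).
#' @param modes a \code{\linkS4class{NormalModes}} over the Calpha network.
#' @param index mode index to follow (e.g. 7).
#' @param net2 optional precomputed \code{\linkS4class{ConstraintNetwork}};
#'   by default the network is rebuilt at \code{cfg@networkCutoff}.
#' @param enmNet the \code{\linkS4class{ElasticNetwork}} of \code{modes}
#'   (rebuilt from \code{s} when omitted).
#' @param cfg a \code{\link{geoSimConfig}}.
#' @param p an \code{\link{interactionParams}}.
#' @return An \code{\linkS4class{Ensemble}}.
#' @export
runGeoSim <- function(s, modes, index, cfg = geoSimConfig(), net2 = NULL,
                      enmNet = NULL, p = interactionParams()) {
  if (is.null(enmNet)) enmNet <- buildENM(s)
  if (is.null(net2))
    net2 <- buildNetwork(s, cfg@networkCutoff, "ambient", p)
  targets <- constraintTargets(s, net2, cfg, p)
  bias <- projectMode(modes, index, enmNet, s, cfg)
  xyz <- .coordMatrix(s@atoms)

  frames <- list(xyz)
  frameSteps <- 0L
  maxViol <- relaxGeometry(xyz, targets, cfg)$maxViolation
  violations <- maxViol
  steps <- 0L
  halt <- "max_steps"
  while (steps < cfg@maxSteps) {
    trial <- relaxGeometry(xyz + bias, targets, cfg)
    if (trial$maxViolation > cfg@tolerance) {
      halt <- "geometry_unrestorable"
      break
    }
    xyz <- trial$coords
    steps <- steps + 1L
    if (steps %% cfg@frameInterval == 0L) {
      frames[[length(frames) + 1]] <- xyz
      frameSteps <- c(frameSteps, steps)
      violations <- c(violations, trial$maxViolation)
    }
  }
  new("Ensemble", frames = frames, atoms = s@atoms,
      stepsCompleted = steps, haltReason = halt,
      frameSteps = as.integer(frameSteps), maxViolations = violations)
}

#' JSON run log for a geometric simulation
#'
#' @param e an \code{\linkS4class{Ensemble}} from \code{\link{runGeoSim}}.
#' @param index,direction annotations recorded in the log.
#' @param path optional path to write JSON to.
#' @return the log as a list (invisibly when written).
#' @export
geoSimLog <- function(e, index = NA_integer_, direction = NA_character_,
                      path = NULL) {
  log <- list(mode = index, direction = direction,
              steps_completed = e@stepsCompleted, halt_reason = e@haltReason,
              frame_steps = e@frameSteps,
              frame_max_violation = round(e@maxViolations, 6))
  if (!is.null(path)) {
    jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
    return(invisible(log))
  }
  log
}
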