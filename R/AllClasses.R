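#' @import methods
NULL

#' Atomic structure container
#'
#' Holds an ordered atom table parsed from a PDB/mmCIF file (or built by the
#' fixture generators), plus the SEQRES sequence per chain when present.
#' The atom table has one row per atom with columns \code{serial},
#' \code{name}, \code{element}, \code{altLoc}, \code{resName}, \code{chainId},
#' \code{resNo}, \code{insert}, \code{x}, \code{y}, \code{z},
#' \code{occupancy}, \code{b}, \code{isHetero}.
#'
#' @slot title character title string.
#' @slot atoms data.frame, one row per atom (columns above).
#' @slot seqres named list of 3-letter residue code vectors, one per chain;
#'   may be empty when the source file carried no SEQRES records.
#' @exportClass PDBStructure
setClass("PDBStructure",
  representation(title = "character", atoms = "data.frame", seqres = "list"))

.atomCols <- c("serial", "name", "element", "altLoc", "resName", "chainId",
               "resNo", "insert", "x", "y", "z", "occupancy", "b", "isHetero")

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  miss <- setdiff(.atomCols, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("non-finite coordinates")
    if (any(a$occupancy < 0 | a$occupancy > 1, na.rm = TRUE))
      return("occupancy outside [0,1]")
    if (any(a$b < 0, na.rm = TRUE)) return("negative B-factor")
    key <- paste(a$chainId, a$resNo, a$insert, a$name, a$altLoc)
    if (anyDuplicated(key))
      return("duplicate (chain, residue, insertion, name, altLoc) atom key")
  }
  TRUE
})

#' Region selection on author residue numbering
#'
#' An inclusive residue range on one chain, in author (PDB) numbering.
#' The canonical cap/lid selection of the HSL-family esterase analyses is
#' residues 7-42.
#'
#' @slot chainId single chain identifier.
#' @slot firstResidue,lastResidue inclusive residue-number bounds.
#' @exportClass RegionSelection
setClass("RegionSelection",
  representation(chainId = "character", firstResidue = "integer",
                 lastResidue = "integer"))

setValidity("RegionSelection", function(object) {
  if (object@firstResidue > object@lastResidue)
    return("firstResidue must be <= lastResidue")
  TRUE
})

#' @rdname RegionSelection-class
#' @param chainId chain identifier.
#' @param firstResidue,lastResidue inclusive author residue numbers.
#' @return A \code{RegionSelection}.
#' @export
regionSelection <- function(chainId, firstResidue, lastResidue) {
  new("RegionSelection", chainId = as.character(chainId),
      firstResidue = as.integer(firstResidue),
      lastResidue = as.integer(lastResidue))
}

#' Interaction detection parameters
#'
#' Geometric gates and energy constants for hydrogen-bond/salt-bridge and
#' hydrophobic-tether detection. Defaults follow the FIRST lineage: a
#' Mayo-form well with depth 8 kcal/mol at a 2.8 A donor-acceptor distance,
#' donor-acceptor gate 3.6 A, hydrogen-acceptor gate 2.5 A, minimum D-H...A
#' angle 110 degrees; salt bridges pinned at -10 kcal/mol within 4.0 A;
#' tethers between carbon/sulfur atoms within the van der Waals sum plus
#' 0.25 A.
#'
#' @slot hbDonorAcceptorMax,hbHydrogenAcceptorMax distance gates, Angstrom.
#' @slot hbDHAMinAngle minimum donor-hydrogen-acceptor angle, degrees.
#' @slot mayoWellDepth well depth V0, kcal/mol (positive).
#' @slot mayoEquilibrium equilibrium donor-acceptor distance d0, Angstrom.
#' @slot saltBridgeEnergy energy assigned to salt bridges, kcal/mol.
#' @slot saltBridgeCutoff distance cutoff for the salt-bridge census, Angstrom.
#' @slot tetherVdwSlop tether slop beyond the vdW sum, Angstrom.
#' @slot vdwRadii named numeric, element -> vdW radius, Angstrom.
#' @exportClass InteractionParams
setClass("InteractionParams",
  representation(hbDonorAcceptorMax = "numeric", hbHydrogenAcceptorMax = "numeric",
                 hbDHAMinAngle = "numeric", mayoWellDepth = "numeric",
                 mayoEquilibrium = "numeric", saltBridgeEnergy = "numeric",
                 saltBridgeCutoff = "numeric", tetherVdwSlop = "numeric",
                 vdwRadii = "numeric"))

setValidity("InteractionParams", function(object) {
  if (object$hbDonorAcceptorMax <= 0 || object$hbHydrogenAcceptorMax <= 0 ||
      object$mayoEquilibrium <= 0 || object$saltBridgeCutoff <= 0)
    return("distance gates must be positive")
  if (object$mayoWellDepth <= 0) return("mayoWellDepth must be positive")
  TRUE
})

#' @param x object.
#' @param name slot name.
#' @rdname InteractionParams-class
#' @export
setMethod("$", "InteractionParams", function(x, name) slot(x, name))

#' @rdname InteractionParams-class
#' @param hbDonorAcceptorMax,hbHydrogenAcceptorMax,hbDHAMinAngle,mayoWellDepth,mayoEquilibrium,saltBridgeEnergy,saltBridgeCutoff,tetherVdwSlop,vdwRadii see slot docs.
#' @return An \code{InteractionParams}.
#' @export
interactionParams <- function(hbDonorAcceptorMax = 3.6, hbHydrogenAcceptorMax = 2.5,
                              hbDHAMinAngle = 110, mayoWellDepth = 8.0,
                              mayoEquilibrium = 2.8, saltBridgeEnergy = -10.0,
                              saltBridgeCutoff = 4.0, tetherVdwSlop = 0.25,
                              vdwRadii = c(C = 1.70, N = 1.55, O = 1.52,
                                           S = 1.80, H = 1.20, P = 1.80)) {
  new("InteractionParams", hbDonorAcceptorMax = hbDonorAcceptorMax,
      hbHydrogenAcceptorMax = hbHydrogenAcceptorMax, hbDHAMinAngle = hbDHAMinAngle,
      mayoWellDepth = mayoWellDepth, mayoEquilibrium = mayoEquilibrium,
      saltBridgeEnergy = saltBridgeEnergy, saltBridgeCutoff = saltBridgeCutoff,
      tetherVdwSlop = tetherVdwSlop, vdwRadii = vdwRadii)
}

#' Constraint network over a structure
#'
#' Typed, energy-labelled constraints (covalent bonds, polar interactions,
#' hydrophobic tethers) between atoms of a \code{PDBStructure}, with bar
#' multiplicities assigned per temperature regime: locked covalent bonds 6,
#' rotatable covalent bonds 5, polar interactions 5, tethers 2 (ambient) or
#' 1 (cold).
#'
#' @slot structure the underlying \code{PDBStructure}.
#' @slot constraints data.frame with columns \code{kind}, \code{i}, \code{j}
#'   (atom row indices), \code{distance}, \code{energy}, \code{bars},
#'   \code{salt}.
#' @slot cutoff polar energy cut-off, kcal/mol (<= 0).
#' @slot regime \code{"ambient"} or \code{"cold"}.
#' @exportClass ConstraintNetwork
setClass("ConstraintNetwork",
  representation(structure = "PDBStructure", constraints = "data.frame",
                 cutoff = "numeric", regime = "character"))

setValidity("ConstraintNetwork", function(object) {
  if (!object@regime %in% c("ambient", "cold")) return("regime must be ambient/cold")
  k <- object@constraints
  if (nrow(k)) {
    pol <- k$kind == "polar"
    if (any(k$energy[pol] > object@cutoff + 1e-9))
      return("polar constraint above cutoff")
    tb <- if (object@regime == "cold") 1L else 2L
    want <- ifelse(k$kind == "covalent_locked", 6L,
            ifelse(k$kind == "covalent_rotatable", 5L,
            ifelse(k$kind == "polar", 5L, tb)))
    if (any(k$bars != want)) return("bar multiplicities inconsistent with regime")
    if (any(k$i == k$j)) return("self-constraint")
  }
  TRUE
})

#' Body-bar multigraph
#'
#' Bodies (one per atom, or abstract for synthetic graphs) joined by bars
#' with multiplicities 1..6; parallel bars between a body pair are summed
#' and capped at 6 during aggregation.
#'
#' @slot nBodies number of bodies.
#' @slot edges data.frame with columns \code{i}, \code{j}, \code{bars}
#'   (aggregated, 1..6).
#' @slot labels optional body labels (e.g. atom serials).
#' @exportClass BodyBarGraph
setClass("BodyBarGraph",
  representation(nBodies = "integer", edges = "data.frame", labels = "character"))

setValidity("BodyBarGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$bars < 1 | e$bars > 6)) return("bar multiplicity outside 1..6")
    if (any(e$i == e$j)) return("self-loop bar")
    if (any(e$i < 1 | e$j < 1 | e$i > object@nBodies | e$j > object@nBodies))
      return("bar endpoint out of range")
    if (anyDuplicated(paste(pmin(e$i, e$j), pmax(e$i, e$j))))
      return("unaggregated parallel bars")
  }
  TRUE
})

#' Rigid cluster decomposition
#'
#' Partition of bodies into maximal mutually rigid clusters, with the count
#' of internal (floppy) degrees of freedom after removing the six global
#' rigid-body motions. Cluster labels 1..K are assigned by decreasing size,
#' ties broken by smallest member id.
#'
#' @slot clusterOf integer vector, body -> cluster label.
#' @slot clusters list of integer vectors (bodies per cluster), in label order.
#' @slot floppyModes internal degrees of freedom.
#' @slot independentBars accepted (independent) bar count.
#' @exportClass RigidClusterDecomposition
setClass("RigidClusterDecomposition",
  representation(clusterOf = "integer", clusters = "list",
                 floppyModes = "integer", independentBars = "integer"))

setValidity("RigidClusterDecomposition", function(object) {
  if (object@floppyModes < 0) return("negative floppy modes")
  if (length(object@clusterOf) &&
      !identical(sort(unlist(object@clusters)), seq_along(object@clusterOf)))
    return("clusters do not partition the bodies")
  TRUE
})

#' Rigidity dilution series
#'
#' One rigid cluster decomposition per energy cut-off, cut-offs strictly
#' decreasing (toward stronger interactions only).
#'
#' @slot regime \code{"ambient"} or \code{"cold"}.
#' @slot cutoffs numeric vector, strictly decreasing.
#' @slot decompositions list of \code{RigidClusterDecomposition}.
#' @exportClass DilutionSeries
setClass("DilutionSeries",
  representation(regime = "character", cutoffs = "numeric",
                 decompositions = "list"))

setValidity("DilutionSeries", function(object) {
  if (length(object@cutoffs) > 1 && any(diff(object@cutoffs) >= 0))
    return("cutoffs must be strictly decreasing")
  if (length(object@cutoffs) != length(object@decompositions))
    return("one decomposition per cutoff required")
  TRUE
})

#' One-node-per-residue elastic network
#'
#' Calpha nodes with uniform springs between all node pairs closer than the
#' distance cutoff (strictly less than; default 10 A).
#'
#' @slot nodes N x 3 matrix of Calpha coordinates, Angstrom.
#' @slot nodeInfo data.frame with \code{chainId}, \code{resNo}, \code{resName}.
#' @slot pairs m x 2 matrix of spring pairs (i < j).
#' @slot k uniform spring constant (arbitrary units).
#' @slot cutoff spring distance cutoff, Angstrom.
#' @exportClass ElasticNetwork
setClass("ElasticNetwork",
  representation(nodes = "matrix", nodeInfo = "data.frame", pairs = "matrix",
                 k = "numeric", cutoff = "numeric"))

setValidity("ElasticNetwork", function(object) {
  if (ncol(object@nodes) != 3) return("nodes must be N x 3")
  p <- object@pairs
  if (nrow(p)) {
    if (any(p[, 1] == p[, 2])) return("self-spring")
    d <- sqrt(rowSums((object@nodes[p[, 1], , drop = FALSE] -
                       object@nodes[p[, 2], , drop = FALSE])^2))
    if (any(d >= object@cutoff)) return("spring pair at or beyond cutoff")
  }
  TRUE
})

#' Normal mode set
#'
#' Orthonormal modes of the elastic network Hessian. Modes 1-6 are the
#' analytically constructed rigid-body (trivial) motions with eigenvalue
#' zero; non-trivial modes are numbered from 7 upwards (so the ten
#' lowest-frequency internal motions are modes 7-16).
#'
#' @slot vectors 3N x m matrix, one unit-norm mode per column.
#' @slot values eigenvalues (spring-constant units), one per column.
#' @slot indices mode indices (1-6 trivial, 7+ non-trivial).
#' @slot nNodes number of network nodes N.
#' @exportClass NormalModes
setClass("NormalModes",
  representation(vectors = "matrix", values = "numeric", indices = "integer",
                 nNodes = "integer"))

setValidity("NormalModes", function(object) {
  if (ncol(object@vectors) != length(object@values)) return("values/vectors mismatch")
  if (nrow(object@vectors) != 3L * object@nNodes) return("vector length != 3N")
  if (length(object@values) && any(object@values < -1e-8 * max(abs(object@values), 1)))
    return("negative eigenvalue")
  TRUE
})

#' Geometric simulation configuration
#'
#' Parameters of the mode-biased geometric simulation: per-step bias of
#' 0.1 A along the normalized mode direction, up to 500 steps with every
#' 50th frame saved, geometry restored to within a 0.1 A tolerance using the
#' non-covalent network at a -4 kcal/mol cut-off, steric floors at 0.85 of
#' the van der Waals sum.
#'
#' @slot stepScale per-step bias amplitude, Angstrom.
#' @slot tolerance restoration tolerance, Angstrom.
#' @slot maxSteps maximum bias steps.
#' @slot frameInterval save every this many steps (frame 0 always saved).
#' @slot networkCutoff polar cut-off for the retained network, kcal/mol.
#' @slot direction \code{"parallel"} or \code{"antiparallel"}.
#' @slot maxRelaxSweeps relaxation sweep budget per step.
#' @slot stericFactor steric floor as a fraction of the vdW sum.
#' @exportClass GeoSimConfig
setClass("GeoSimConfig",
  representation(stepScale = "numeric", tolerance = "numeric",
                 maxSteps = "integer", frameInterval = "integer",
                 networkCutoff = "numeric", direction = "character",
                 maxRelaxSweeps = "integer", stericFactor = "numeric"))

setValidity("GeoSimConfig", function(object) {
  if (object@stepScale <= 0) return("stepScale must be positive")
  if (object@tolerance <= 0) return("tolerance must be positive")
  if (object@frameInterval > object@maxSteps)
    return("frameInterval must be <= maxSteps")
  if (!object@direction %in% c("parallel", "antiparallel"))
    return("direction must be parallel/antiparallel")
  TRUE
})

#' @rdname GeoSimConfig-class
#' @param stepScale,tolerance,maxSteps,frameInterval,networkCutoff,direction,maxRelaxSweeps,stericFactor see slot docs.
#' @return A \code{GeoSimConfig}.
#' @export
geoSimConfig <- function(stepScale = 0.1, tolerance = 0.1, maxSteps = 500L,
                         frameInterval = 50L, networkCutoff = -4.0,
                         direction = c("parallel", "antiparallel"),
                         maxRelaxSweeps = 200L, stericFactor = 0.85) {
  new("GeoSimConfig", stepScale = stepScale, tolerance = tolerance,
      maxSteps = as.integer(maxSteps), frameInterval = as.integer(frameInterval),
      networkCutoff = networkCutoff, direction = match.arg(direction),
      maxRelaxSweeps = as.integer(maxRelaxSweeps), stericFactor = stericFactor)
}

#' Coordinate ensemble
#'
#' Ordered all-atom coordinate frames from a geometric simulation (or a
#' synthetic generator), with the step count reached and why the run halted.
#'
#' @slot frames list of n x 3 coordinate matrices (frame 0 first).
#' @slot atoms the atom table the frames refer to.
#' @slot stepsCompleted bias steps completed.
#' @slot haltReason \code{"max_steps"} or \code{"geometry_unrestorable"}.
#' @slot frameSteps step index of each saved frame.
#' @slot maxViolations per-frame maximum constraint violation, Angstrom.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(frames = "list", atoms = "data.frame",
                 stepsCompleted = "integer", haltReason = "character",
                 frameSteps = "integer", maxViolations = "numeric"))

setValidity("Ensemble", function(object) {
  if (!length(object@frames)) return("empty ensemble")
  if (!object@haltReason %in% c("max_steps", "geometry_unrestorable", "none"))
    return("unknown haltReason")
  TRUE
})

## ---- show methods ----

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat("PDBStructure:", if (nzchar(object@title)) object@title else "<untitled>", "\n")
  cat(sprintf("  %d atoms, %d chains (%s), %d residues\n", nrow(a),
              length(unique(a$chainId)), paste(unique(a$chainId), collapse = ","),
              length(unique(paste(a$chainId, a$resNo, a$insert)))))
})

setMethod("show", "ConstraintNetwork", function(object) {
  k <- object@constraints
  cat(sprintf("ConstraintNetwork (%s regime, cutoff %.1f kcal/mol)\n",
              object@regime, object@cutoff))
  if (nrow(k)) print(table(k$kind)) else cat("  no constraints\n")
})

setMethod("show", "BodyBarGraph", function(object) {
  cat(sprintf("BodyBarGraph: %d bodies, %d edges, %d bars total\n",
              object@nBodies, nrow(object@edges), sum(object@edges$bars)))
})

setMethod("show", "RigidClusterDecomposition", function(object) {
  sz <- lengths(object@clusters)
  cat(sprintf("RigidClusterDecomposition: %d clusters (largest %d), %d floppy modes\n",
              length(sz), if (length(sz)) max(sz) else 0L, object@floppyModes))
})

setMethod("show", "DilutionSeries", function(object) {
  cat(sprintf("DilutionSeries (%s): %d cutoffs\n", object@regime,
              length(object@cutoffs)))
  for (i in seq_along(object@cutoffs)) {
    d <- object@decompositions[[i]]
    cat(sprintf("  %6.2f kcal/mol: largest cluster %d, floppy %d\n",
                object@cutoffs[i], max(lengths(d@clusters)), d@floppyModes))
  }
})

setMethod("show", "ElasticNetwork", function(object) {
  cat(sprintf("ElasticNetwork: %d nodes, %d springs (cutoff %.1f A, k = %g)\n",
              nrow(object@nodes), nrow(object@pairs), object@cutoff, object@k))
})

setMethod("show", "NormalModes", function(object) {
  cat(sprintf("NormalModes: %d modes over %d nodes (indices %s)\n",
              ncol(object@vectors), object@nNodes,
              paste(range(object@indices), collapse = "-")))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d frames, %d steps completed, halted at %s\n",
              length(object@frames), object@stepsCompleted, object@haltReason))
})

## ---- accessors ----

#' Accessors for structures, networks and decompositions
#'
#' @param x object.
#' @return \code{atoms} the atom table; \code{nAtoms} atom count;
#'   \code{chainIds} chain identifiers; \code{constraints} the constraint
#'   table; \code{clusterSizes} rigid-cluster sizes (label order);
#'   \code{floppyModes} internal degree-of-freedom count;
#'   \code{modeVectors}/\code{modeValues}/\code{modeIndices} mode matrix,
#'   eigenvalues and indices; \code{ensembleFrames} the coordinate frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "PDBStructure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setMethod("chainIds", "PDBStructure", function(x) unique(x@atoms$chainId))
#' @rdname accessors
#' @export
setGeneric("constraints", function(x) standardGeneric("constraints"))
#' @rdname accessors
#' @export
setMethod("constraints", "ConstraintNetwork", function(x) x@constraints)
#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setMethod("clusterSizes", "RigidClusterDecomposition",
          function(x) lengths(x@clusters))
#' @rdname accessors
#' @export
setGeneric("floppyModes", function(x) standardGeneric("floppyModes"))
#' @rdname accessors
#' @export
setMethod("floppyModes", "RigidClusterDecomposition", function(x) x@floppyModes)
#' @rdname accessors
#' @export
setGeneric("modeVectors", function(x) standardGeneric("modeVectors"))
#' @rdname accessors
#' @export
setMethod("modeVectors", "NormalModes", function(x) x@vectors)
#' @rdname accessors
#' @export
setGeneric("modeValues", function(x) standardGeneric("modeValues"))
#' @rdname accessors
#' @export
setMethod("modeValues", "NormalModes", function(x) x@values)
#' @rdname accessors
#' @export
setGeneric("modeIndices", function(x) standardGeneric("modeIndices"))
#' @rdname accessors
#' @export
setMethod("modeIndices", "NormalModes", function(x) x@indices)
#' @rdname accessors
#' @export
setGeneric("ensembleFrames", function(x) standardGeneric("ensembleFrames"))
#' @rdname accessors
#' @export
setMethod("ensembleFrames", "Ensemble", function(x) x@frames)
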