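#' Construct a body-bar multigraph
#'
#' Bars between the same body pair are summed and capped at 6 (a pair of
#' 6-DOF rigid bodies has only six relative degrees of freedom, so further
#' parallel bars are necessarily redundant).
#'
#' @param nBodies number of bodies.
#' @param edges data.frame or matrix with columns \code{i}, \code{j},
#'   \code{bars} (multiplicity 1..6 before aggregation).
#' @param labels optional body labels.
#' @return A \code{\linkS4class{BodyBarGraph}}.
#' @export
bodyBarGraph <- function(nBodies, edges, labels = character()) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) {
    edges <- data.frame(i = integer(), j = integer(), bars = integer())
  } else {
    names(edges)[1:3] <- c("i", "j", "bars")
    i <- pmin(edges$i, edges$j); j <- pmax(edges$i, edges$j)
    agg <- stats::aggregate(list(bars = edges$bars),
                            by = list(i = i, j = j), FUN = sum)
    agg$bars <- pmin(agg$bars, 6L)
    edges <- agg[order(agg$i, agg$j), , drop = FALSE]
    rownames(edges) <- NULL
    edges$i <- as.integer(edges$i); edges$j <- as.integer(edges$j)
    edges$bars <- as.integer(edges$bars)
  }
  new("BodyBarGraph", nBodies = as.integer(nBodies), edges = edges,
      labels = labels)
}

#' Body-bar graph of a constraint network
#'
#' One body per (non-hetero) atom; constraint bars aggregated per atom pair
#' (summed, capped at 6). The returned graph carries the atom row indices of
#' the underlying structure as an attribute so cluster decompositions can be
#' mapped back onto atoms.
#'
#' @param net a \code{\linkS4class{ConstraintNetwork}}.
#' @return A \code{\linkS4class{BodyBarGraph}} with attribute
#'   \code{"atomRows"}.
#' @export
networkGraph <- function(net) {
  a <- net@structure@atoms
  rows <- which(!a$isHetero)
  bodyOf <- integer(nrow(a))
  bodyOf[rows] <- seq_along(rows)
  k <- net@constraints
  g <- bodyBarGraph(length(rows),
                    data.frame(i = bodyOf[k$i], j = bodyOf[k$j], bars = k$bars),
                    labels = as.character(a$serial[rows]))
  attr(g, "atomRows") <- rows
  g
}

.expandBars <- function(g) {
  e <- g@edges
  if (!nrow(e)) return(matrix(integer(), 0, 3))
  cbind(rep(e$i, e$bars), rep(e$j, e$bars), rep(1L, sum(e$bars)))
}

#' Run the (6,6) body-bar pebble game
#'
#' Each body starts with six pebbles; a bar is accepted (independent) iff
#' seven pebbles can be gathered on its endpoints. The accepted-bar count
#' equals the generic rank of the body-bar framework, and the floppy-mode
#' count is the number of free pebbles minus the six global rigid-body
#' motions. The result is independent of bar insertion order.
#'
#' @param g a \code{\linkS4class{BodyBarGraph}}.
#' @param order optional permutation of the expanded unit-bar list giving
#'   the insertion order (used to exercise order invariance).
#' @return list with \code{independentBars}, \code{redundantBars},
#'   \code{floppyModes}, \code{freePebbles}.
#' @export
pebbleGame <- function(g, order = NULL) {
  bars <- .expandBars(g)
  if (!is.null(order)) {
    stopifnot(length(order) == nrow(bars))
    bars <- bars[order, , drop = FALSE]
  }
  res <- .pebble_run_cpp(g@nBodies, bars, clusters = FALSE)
  list(independentBars = res$accepted,
       redundantBars = nrow(bars) - res$accepted,
       floppyModes = res$floppyModes,
       freePebbles = res$freePebbles)
}

#' Rigid cluster decomposition
#'
#' Partitions the bodies into maximal mutually rigid clusters (pairwise
#' relative degrees of freedom zero, determined by pebble gathering after
#' the game completes; singletons allowed). Cluster labels are assigned by
#' decreasing size, ties broken by smallest member id, so outputs are
#' deterministic.
#'
#' @param g a \code{\linkS4class{BodyBarGraph}}.
#' @return A \code{\linkS4class{RigidClusterDecomposition}} (the
#'   \code{"atomRows"} attribute of \code{g}, if any, is propagated).
#' @export
rigidClusters <- function(g) {
  res <- .pebble_run_cpp(g@nBodies, .expandBars(g), clusters = TRUE)
  raw <- res$clusterOf
  groups <- split(seq_len(g@nBodies), raw)
  ord <- order(-lengths(groups), vapply(groups, min, integer(1)))
  groups <- unname(groups[ord])
  clusterOf <- integer(g@nBodies)
  for (lab in seq_along(groups)) clusterOf[groups[[lab]]] <- lab
  d <- new("RigidClusterDecomposition", clusterOf = clusterOf,
           clusters = groups, floppyModes = as.integer(max(0L, res$floppyModes)),
           independentBars = as.integer(res$accepted))
  attr(d, "atomRows") <- attr(g, "atomRows")
  d
}

#' Rigidity dilution
#'
#' Rebuilds the constraint network at each energy cut-off (progressively
#' eliminating weaker hydrogen bonds) and decomposes it into rigid
#' clusters, in the ambient or cold regime. Cut-offs must be sorted
#' descending (toward more negative values).
#'
#' @param s a \code{PDBStructure} (polar hydrogens recommended).
#' @param cutoffs energy cut-offs, kcal/mol, strictly decreasing
#'   (default -1, -2, -3, -4).
#' @param regime \code{"ambient"} or \code{"cold"}.
#' @param p an \code{\link{interactionParams}} object.
#' @return A \code{\linkS4class{DilutionSeries}}.
#' @export
rigidityDilution <- function(s, cutoffs = c(-1, -2, -3, -4),
                             regime = c("ambient", "cold"),
                             p = interactionParams()) {
  regime <- match.arg(regime)
  if (length(cutoffs) > 1 && any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly decreasing")
  covalent <- detectCovalent(s)
  tethers <- detectTethers(s, p)
  polar <- detectPolar(s, p)
  decomps <- lapply(cutoffs, function(co) {
    net <- buildNetwork(s, co, regime, p, covalent = covalent,
                        tethers = tethers, polar = polar)
    rigidClusters(networkGraph(net))
  })
  new("DilutionSeries", regime = regime, cutoffs = as.numeric(cutoffs),
      decompositions = decomps)
}

#' Export a rigid cluster decomposition
#'
#' \code{writeDecomposition} writes a TSV mapping each atom to its cluster
#' label; \code{clusterViewerScript} writes a PyMOL command script colouring
#' the 20 largest clusters as a red-to-blue rainbow (flexible remainder
#' grey); \code{decompositionSummary} returns the JSON-ready summary list.
#'
#' @param d a \code{\linkS4class{RigidClusterDecomposition}} from
#'   \code{\link{rigidClusters}} on a network graph.
#' @param s the underlying \code{PDBStructure}.
#' @param path output path.
#' @return the path (writers, invisibly) or the summary list.
#' @export
writeDecomposition <- function(d, s, path) {
  rows <- attr(d, "atomRows")
  if (is.null(rows)) stop("decomposition does not map to atoms")
  a <- s@atoms[rows, , drop = FALSE]
  tab <- data.frame(serial = a$serial, chain = a$chainId, resNo = a$resNo,
                    resName = a$resName, atom = a$name,
                    cluster = d@clusterOf, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDecomposition
#' @param nColors number of largest clusters to colour (default 20).
#' @export
clusterViewerScript <- function(d, s, path, nColors = 20) {
  rows <- attr(d, "atomRows")
  if (is.null(rows)) stop("decomposition does not map to atoms")
  a <- s@atoms[rows, , drop = FALSE]
  sz <- lengths(d@clusters)
  nc <- min(nColors, sum(sz > 1))
  lines <- c("bg_color white", "hide everything", "show cartoon",
             "color grey80")
  for (lab in seq_len(nc)) {
    frac <- if (nc > 1) (lab - 1) / (nc - 1) else 0
    # red (largest) -> blue rainbow
    col <- grDevices::hsv(h = 2 / 3 * frac, s = 1, v = 1)
    rgbv <- grDevices::col2rgb(col) / 255
    sel <- a$serial[d@clusterOf == lab]
    lines <- c(lines,
      sprintf("set_color clust%d, [%.3f, %.3f, %.3f]", lab, rgbv[1], rgbv[2], rgbv[3]),
      sprintf("select c%d, id %s", lab, paste(sel, collapse = "+")),
      sprintf("show spheres, c%d", lab),
      sprintf("color clust%d, c%d", lab, lab))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDecomposition
#' @param cutoff,regime annotations recorded in the summary.
#' @export
decompositionSummary <- function(d, cutoff = NA_real_, regime = NA_character_) {
  sz <- lengths(d@clusters)
  list(cutoff = cutoff, regime = regime, n_clusters = length(sz),
       largest_size = if (length(sz)) max(sz) else 0L,
       floppy_modes = d@floppyModes)
}
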