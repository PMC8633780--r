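#' Add polar hydrogens to a structure
#'
#' Places the hydrogen atoms that matter for hydrogen-bond detection:
#' backbone amide H (in the peptide plane, 1.0 A from N, anti to the
#' preceding carbonyl O) and side-chain polar H on Ser/Thr/Tyr/Cys
#' hydroxyl/thiol groups, Lys NZ, Arg NE/NH1/NH2, Asn/Gln amide nitrogens,
#' His NE2 (default NE2-protonated tautomer) and Trp NE1, by ideal internal
#' geometry. Existing hydrogens are preserved (a donor that already carries
#' an H is skipped), heavy atoms are never moved, and a donor missing its
#' heavy-atom anchors is skipped with a warning. The operation is
#' idempotent.
#'
#' @param s a \code{PDBStructure} of standard amino-acid residues.
#' @return A \code{PDBStructure} with hydrogens inserted into their
#'   residues' atom blocks and serials renumbered.
#' @export
addPolarHydrogens <- function(s) {
  a <- s@atoms
  resRows <- .residueRowIndex(a)
  resTab <- .residueTable(a)
  xyz <- .coordMatrix(a)
  warnings <- character()

  pos <- function(rows, nm) {
    i <- rows[a$name[rows] == nm & a$element[rows] != "H"]
    if (length(i)) xyz[i[1], ] else NULL
  }
  hasHNear <- function(rows, anchor, rmax = 1.3) {
    hs <- rows[a$element[rows] == "H"]
    if (!length(hs)) return(FALSE)
    any(sqrt(colSums((t(xyz[hs, , drop = FALSE]) - anchor)^2)) <= rmax)
  }

  newH <- vector("list", length(resRows))
  addH <- function(k, name, p) {
    newH[[k]][[length(newH[[k]]) + 1]] <<- c(name = name, x = p[1], y = p[2], z = p[3])
  }

  for (k in seq_along(resRows)) {
    rows <- resRows[[k]]
    rn <- resTab$resName[k]
    newH[[k]] <- list()

    # backbone amide H: needs the preceding residue's C and O in-chain
    if (rn != "PRO" && rn %in% .standardResidues) {
      N <- pos(rows, "N")
      if (!is.null(N) && k > 1 && resTab$chainId[k - 1] == resTab$chainId[k]) {
        prev <- resRows[[k - 1]]
        Cp <- pos(prev, "C"); Op <- pos(prev, "O")
        if (!is.null(Cp) && !is.null(Op) && .vnorm(N - Cp) < 2.0 &&
            !hasHNear(rows, N))
          addH(k, "H", N + .unit(Cp - Op) * 1.0)
        else if (!is.null(Cp) && is.null(Op))
          warnings <- c(warnings, sprintf("no carbonyl O before %s %s%d",
                                          rn, resTab$chainId[k], resTab$resNo[k]))
      }
    }

    place <- function(donor, A, B, hs) {
      D <- pos(rows, donor)
      if (is.null(D)) return()
      if (hasHNear(rows, D)) return()
      pa <- pos(rows, A); pb <- pos(rows, B)
      if (is.null(pa) || is.null(pb)) {
        warnings <<- c(warnings, sprintf("missing anchor %s/%s for %s of %s %s%d",
                                         A, B, donor, rn, resTab$chainId[k],
                                         resTab$resNo[k]))
        return()
      }
      for (h in hs)
        addH(k, h[["name"]],
             .nerf(pa, pb, D, as.numeric(h[["bond"]]), as.numeric(h[["angle"]]),
                   as.numeric(h[["dih"]])))
    }
    bisector <- function(donor, A, B, hname, bond) {
      D <- pos(rows, donor)
      if (is.null(D) || hasHNear(rows, D)) return()
      pa <- pos(rows, A); pb <- pos(rows, B)
      if (is.null(pa) || is.null(pb)) {
        warnings <<- c(warnings, sprintf("missing anchor %s/%s for %s of %s %s%d",
                                         A, B, donor, rn, resTab$chainId[k],
                                         resTab$resNo[k]))
        return()
      }
      addH(k, hname, D + bond * .unit(.unit(D - pa) + .unit(D - pb)))
    }
    hdef <- function(name, bond, angle, dih)
      list(name = name, bond = bond, angle = angle, dih = dih)

    switch(rn,
      SER = place("OG", "CA", "CB", list(hdef("HG", 0.96, 109.5, 180))),
      THR = place("OG1", "CA", "CB", list(hdef("HG1", 0.96, 109.5, 180))),
      TYR = place("OH", "CE1", "CZ", list(hdef("HH", 0.96, 109.5, 180))),
      CYS = place("SG", "CA", "CB", list(hdef("HG", 1.34, 96.0, 180))),
      LYS = place("NZ", "CD", "CE", list(hdef("HZ1", 1.01, 109.5, 180),
                                         hdef("HZ2", 1.01, 109.5, 60),
                                         hdef("HZ3", 1.01, 109.5, -60))),
      ARG = {
        bisector("NE", "CD", "CZ", "HE", 1.01)
        place("NH1", "NE", "CZ", list(hdef("HH11", 1.01, 120, 0),
                                      hdef("HH12", 1.01, 120, 180)))
        place("NH2", "NE", "CZ", list(hdef("HH21", 1.01, 120, 0),
                                      hdef("HH22", 1.01, 120, 180)))
      },
      ASN = place("ND2", "CB", "CG", list(hdef("HD21", 1.01, 120, 0),
                                          hdef("HD22", 1.01, 120, 180))),
      GLN = place("NE2", "CG", "CD", list(hdef("HE21", 1.01, 120, 0),
                                          hdef("HE22", 1.01, 120, 180))),
      HIS = bisector("NE2", "CD2", "CE1", "HE2", 1.01),
      TRP = bisector("NE1", "CD1", "CE2", "HE1", 1.01),
      NULL)
  }

  nAdded <- sum(lengths(newH))
  if (nAdded == 0) {
    if (length(warnings)) warning(paste(warnings, collapse = "; "))
    return(s)
  }

  blocks <- vector("list", length(resRows))
  for (k in seq_along(resRows)) {
    blk <- a[resRows[[k]], , drop = FALSE]
    if (length(newH[[k]])) {
      hs <- do.call(rbind, lapply(newH[[k]], function(h) {
        data.frame(serial = 0L, name = h[["name"]], element = "H", altLoc = "",
                   resName = resTab$resName[k], chainId = resTab$chainId[k],
                   resNo = resTab$resNo[k], insert = resTab$insert[k],
                   x = as.numeric(h[["x"]]), y = as.numeric(h[["y"]]),
                   z = as.numeric(h[["z"]]), occupancy = 1, b = 0,
                   isHetero = FALSE, stringsAsFactors = FALSE)
      }))
      blk <- rbind(blk, hs)
    }
    blocks[[k]] <- blk
  }
  out <- do.call(rbind, blocks)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (length(warnings)) warning(paste(warnings, collapse = "; "))
  structureFromAtoms(out, title = s@title, seqres = s@seqres)
}
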