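test_that("covalent detection applies residue templates and bond classes", {
  di <- structureFromAtoms(flexrig:::.buildPeptide(c("ALA", "ALA")))
  cov <- detectCovalent(di)
  a <- atoms(di)
  pep <- cov[a$name[cov$i] == "C" & a$name[cov$j] == "N" &
             a$resNo[cov$i] == 1 & a$resNo[cov$j] == 2, ]
  expect_equal(nrow(pep), 1L)
  expect_equal(pep$kind, "covalent_locked")

  ph <- structureFromAtoms(flexrig:::.buildPeptide(c("PHE")))
  cov2 <- detectCovalent(ph)
  a2 <- atoms(ph)
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ringBonds <- cov2[a2$name[cov2$i] %in% ring & a2$name[cov2$j] %in% ring, ]
  expect_equal(nrow(ringBonds), 6L)
  expect_true(all(ringBonds$kind == "covalent_locked"))
})

test_that("disulfides form below 2.3 A and terminal pendants are locked", {
  c1 <- flexrig:::.buildPeptide(c("CYS"))
  c2 <- flexrig:::.buildPeptide(c("CYS"), chainId = "B")
  # translate chain B so the SG-SG distance is exactly 2.05
  sg1 <- unlist(c1[c1$name == "SG", c("x", "y", "z")])
  sg2 <- unlist(c2[c2$name == "SG", c("x", "y", "z")])
  shift <- sg1 + c(2.05, 0, 0) - sg2
  c2$x <- c2$x + shift[1]; c2$y <- c2$y + shift[2]; c2$z <- c2$z + shift[3]
  c2$serial <- c2$serial + max(c1$serial)
  s <- structureFromAtoms(rbind(c1, c2))
  cov <- detectCovalent(s)
  a <- atoms(s)
  ss <- cov[a$name[cov$i] == "SG" & a$name[cov$j] == "SG", ]
  expect_equal(nrow(ss), 1L)

  # Ala CB is a terminal pendant: its bond is locked to the parent body
  ala <- structureFromAtoms(flexrig:::.buildPeptide(c("ALA")))
  cv <- detectCovalent(ala)
  aa <- atoms(ala)
  cb <- cv[aa$name[cv$i] == "CA" & aa$name[cv$j] == "CB" |
           aa$name[cv$j] == "CA" & aa$name[cv$i] == "CB", ]
  expect_equal(cb$kind, "covalent_locked")
})

test_that("tether detection applies the vdW gate and shortest-contact rule", {
  # two Ala CB atoms 6 A apart on different chains: out of range
  a1 <- flexrig:::.buildPeptide(c("ALA"))
  a2 <- flexrig:::.buildPeptide(c("ALA"), chainId = "B")
  a2$x <- a2$x + 6 + diff(range(a1$x))
  a2$serial <- a2$serial + max(a1$serial)
  sFar <- structureFromAtoms(rbind(a1, a2))
  tFar <- detectTethers(sFar)
  expect_equal(sum(atoms(sFar)$chainId[tFar$i] != atoms(sFar)$chainId[tFar$j]), 0L)

  # two Leu side chains, closest C-C just inside the vdW-sum + slop gate:
  # exactly one tether for the residue pair (shortest-contact rule)
  l1 <- flexrig:::.buildPeptide(c("LEU"))
  l2 <- flexrig:::.buildPeptide(c("LEU"), chainId = "B")
  # place chain B far along +x, then pull back until the closest inter-chain
  # C-C contact sits at 3.5 A (inside the 3.65 A gate)
  l2$x <- l2$x + 60
  c1m <- as.matrix(l1[l1$element == "C", c("x", "y", "z")])
  minCC <- function(l2) {
    c2m <- as.matrix(l2[l2$element == "C", c("x", "y", "z")])
    min(sqrt(outer(rowSums(c1m^2), rep(1, nrow(c2m))) +
             outer(rep(1, nrow(c1m)), rowSums(c2m^2)) - 2 * c1m %*% t(c2m)))
  }
  for (it in 1:20) l2$x <- l2$x - (minCC(l2) - 3.5)
  expect_equal(minCC(l2), 3.5, tolerance = 1e-6)
  l2$serial <- l2$serial + max(l1$serial)
  s <- structureFromAtoms(rbind(l1, l2))
  t1 <- detectTethers(s)
  inter <- atoms(s)$chainId[t1$i] != atoms(s)$chainId[t1$j]
  expect_equal(sum(inter), 1L)   # one tether per residue pair (shortest kept)
  expect_equal(t1$distance[inter], 3.5, tolerance = 1e-6)
})

test_that("tether set is invariant under rigid-body transformation", {
  d <- twoHelixDimer(3)
  t0 <- detectTethers(d)
  xyz <- coords(d)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  d2 <- setCoords(d, xyz %*% R + matrix(c(5, -3, 11), nrow(xyz), 3, byrow = TRUE))
  t2 <- detectTethers(d2)
  expect_equal(t2$i, t0$i)
  expect_equal(t2$j, t0$j)
  expect_equal(t2$distance, t0$distance, tolerance = 1e-9)
})

test_that("Mayo well attains -V0 at the equilibrium distance with ideal angles", {
  p <- interactionParams()
  expect_equal(flexrig:::.mayoEnergy(p$mayoEquilibrium, 180, p), -p$mayoWellDepth)
  # continuity around d0 and clamping to [-10, 0]
  d <- seq(2.5, 3.6, by = 0.01)
  e <- vapply(d, flexrig:::.mayoEnergy, numeric(1), thetaDeg = 180, p = p)
  expect_true(all(diff(e) < 0.5))
  expect_true(all(e >= -10 & e <= 0))
})

test_that("helix hydrogen-bond ladder passes the geometric gates", {
  h <- fixHelix()
  pol <- detectPolar(h)
  expect_gte(nrow(pol[!pol$salt, ]), 16)
  expect_true(all(pol$energy >= -10 & pol$energy <= 0))
  # distance gate: stretching donor-acceptor beyond 3.6 A removes detection
  p36 <- interactionParams(hbDonorAcceptorMax = 2.0)
  expect_lt(nrow(detectPolar(h, p36)), nrow(pol))
})

test_that("salt-bridge census counts unique residue pairs within cutoff", {
  k <- flexrig:::.buildPeptide(c("LYS"))
  d <- flexrig:::.buildPeptide(c("ASP"), chainId = "B")
  nz <- unlist(k[k$name == "NZ", c("x", "y", "z")])
  od <- unlist(d[d$name == "OD1", c("x", "y", "z")])
  place <- function(sep) {
    dd <- d
    shift <- nz + c(sep, 0, 0) - od
    dd$x <- dd$x + shift[1]; dd$y <- dd$y + shift[2]; dd$z <- dd$z + shift[3]
    dd$serial <- dd$serial + max(k$serial)
    structureFromAtoms(rbind(k, dd))
  }
  expect_equal(countSaltBridges(place(3.0)), 1L)
  expect_equal(countSaltBridges(place(4.5)), 0L)
  expect_equal(countSaltBridges(place(3.0), selection = "A"), 0L) # pair spans chains
})

test_that("network assembly filters polar constraints by cutoff and regime", {
  h <- fixHelix()
  n1 <- buildNetwork(h, -1, "ambient")
  n4 <- buildNetwork(h, -4, "ambient")
  k1 <- constraints(n1); k4 <- constraints(n4)
  p1 <- paste(k1$i, k1$j)[k1$kind == "polar"]
  p4 <- paste(k4$i, k4$j)[k4$kind == "polar"]
  expect_true(all(p4 %in% p1))
  # polar count non-increasing as the cutoff is lowered
  counts <- vapply(seq(0, -10, by = -1), function(co)
    sum(constraints(buildNetwork(h, co, "ambient"))$kind == "polar"), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # cold regime: every tether carries one bar; ambient two
  cold <- constraints(buildNetwork(h, -1, "cold"))
  expect_true(all(cold$bars[cold$kind == "tether"] == 1L))
  amb <- constraints(n1)
  expect_true(all(amb$bars[amb$kind == "tether"] == 2L))
})

test_that("constraint tables survive a TSV round-trip", {
  net <- buildNetwork(fixHelix(), -2, "ambient")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeConstraints(net, f)
  tab <- readConstraints(f)
  expect_equal(nrow(tab), nrow(constraints(net)))
  expect_true(all(c("kind", "chain_i", "res_i", "atom_i", "energy", "bars") %in%
                  names(tab)))
})
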