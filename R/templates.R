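# Residue chemistry tables: covalent bond topology per standard amino acid
# (with locked/rotatable classification), polar donor/acceptor atoms,
# charged side-chain groups, and internal-coordinate templates used by the
# fixture builders. Locked bonds (bars = 6) are the peptide bond, carbonyl
# and carboxylate/amide/guanidinium groups and all ring bonds; every other
# single bond is rotatable (bars = 5).

.backboneBonds <- list(
  c("N", "CA", "r"), c("CA", "C", "r"), c("C", "O", "l"), c("C", "OXT", "l"),
  c("CA", "CB", "r"))

.sideChainBonds <- list(
  ALA = list(),
  ARG = list(c("CB","CG","r"), c("CG","CD","r"), c("CD","NE","r"),
             c("NE","CZ","l"), c("CZ","NH1","l"), c("CZ","NH2","l")),
  ASN = list(c("CB","CG","r"), c("CG","OD1","l"), c("CG","ND2","l")),
  ASP = list(c("CB","CG","r"), c("CG","OD1","l"), c("CG","OD2","l")),
  CYS = list(c("CB","SG","r")),
  GLN = list(c("CB","CG","r"), c("CG","CD","r"), c("CD","OE1","l"), c("CD","NE2","l")),
  GLU = list(c("CB","CG","r"), c("CG","CD","r"), c("CD","OE1","l"), c("CD","OE2","l")),
  GLY = list(),
  HIS = list(c("CB","CG","r"), c("CG","ND1","l"), c("CG","CD2","l"),
             c("ND1","CE1","l"), c("CD2","NE2","l"), c("CE1","NE2","l")),
  ILE = list(c("CB","CG1","r"), c("CB","CG2","r"), c("CG1","CD1","r")),
  LEU = list(c("CB","CG","r"), c("CG","CD1","r"), c("CG","CD2","r")),
  LYS = list(c("CB","CG","r"), c("CG","CD","r"), c("CD","CE","r"), c("CE","NZ","r")),
  MET = list(c("CB","CG","r"), c("CG","SD","r"), c("SD","CE","r")),
  PHE = list(c("CB","CG","r"), c("CG","CD1","l"), c("CG","CD2","l"),
             c("CD1","CE1","l"), c("CD2","CE2","l"), c("CE1","CZ","l"), c("CE2","CZ","l")),
  PRO = list(c("CB","CG","l"), c("CG","CD","l"), c("CD","N","l")),
  SER = list(c("CB","OG","r")),
  THR = list(c("CB","OG1","r"), c("CB","CG2","r")),
  TRP = list(c("CB","CG","r"), c("CG","CD1","l"), c("CG","CD2","l"),
             c("CD1","NE1","l"), c("NE1","CE2","l"), c("CD2","CE2","l"),
             c("CD2","CE3","l"), c("CE3","CZ3","l"), c("CZ3","CH2","l"),
             c("CH2","CZ2","l"), c("CZ2","CE2","l")),
  TYR = list(c("CB","CG","r"), c("CG","CD1","l"), c("CG","CD2","l"),
             c("CD1","CE1","l"), c("CD2","CE2","l"), c("CE1","CZ","l"),
             c("CE2","CZ","l"), c("CZ","OH","r")),
  VAL = list(c("CB","CG1","r"), c("CB","CG2","r")))

.standardResidues <- names(.sideChainBonds)

# Pro ring closure also locks its backbone N-CA and CA-CB bonds
.prolineLockedBackbone <- c("N CA", "CA CB")

# Hydrogen-bond donor heavy atoms (side chains; backbone N handled separately)
.donorAtoms <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = "NE2",     # NE2-protonated tautomer by default
  TRP = "NE1")

# Hydrogen-bond acceptor atoms (backbone O/OXT handled separately)
.acceptorAtoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = "ND1")     # the unprotonated ring nitrogen in the default tautomer

# Charged side-chain atoms for salt-bridge detection
.acidicAtoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basicAtoms  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))

# element from a PDB atom name: first alphabetic character (H naming like
# "1HB" handled), two-letter metals are not expected in protein chains
.elementFromName <- function(name) {
  vapply(name, function(nm) {
    ch <- strsplit(gsub("[^A-Za-z]", "", nm), "")[[1]]
    if (!length(ch)) return("X")
    toupper(ch[1])
  }, character(1), USE.NAMES = FALSE)
}

.waterNames <- c("HOH", "WAT", "DOD", "H2O")

# ---- internal-coordinate side-chain templates for the fixture builders ----
# rows: atom, refA, refB, refC, bond (A), angle (deg, at refC), dihedral
# (deg, A-B-C-atom). Chi angles fixed at common rotamers (-60/180) so the
# builders are deterministic.
.sideChainICTemplates <- list(
  ALA = list(),
  SER = list(c("OG", "N", "CA", "CB", "1.417", "110.8", "-60")),
  CYS = list(c("SG", "N", "CA", "CB", "1.808", "114.4", "-60")),
  THR = list(c("OG1", "N", "CA", "CB", "1.433", "109.6", "-60"),
             c("CG2", "N", "CA", "CB", "1.521", "110.5", "180")),
  LEU = list(c("CG", "N", "CA", "CB", "1.530", "116.3", "-60"),
             c("CD1", "CA", "CB", "CG", "1.521", "110.7", "180"),
             c("CD2", "CA", "CB", "CG", "1.521", "110.7", "-60")),
  LYS = list(c("CG", "N", "CA", "CB", "1.520", "114.1", "-60"),
             c("CD", "CA", "CB", "CG", "1.520", "111.3", "180"),
             c("CE", "CB", "CG", "CD", "1.520", "111.3", "180"),
             c("NZ", "CG", "CD", "CE", "1.489", "111.9", "180")),
  GLU = list(c("CG", "N", "CA", "CB", "1.520", "114.1", "-60"),
             c("CD", "CA", "CB", "CG", "1.516", "112.6", "180"),
             c("OE1", "CB", "CG", "CD", "1.249", "118.4", "0"),
             c("OE2", "CB", "CG", "CD", "1.249", "118.4", "180")),
  ASP = list(c("CG", "N", "CA", "CB", "1.516", "112.6", "-60"),
             c("OD1", "CA", "CB", "CG", "1.249", "118.4", "0"),
             c("OD2", "CA", "CB", "CG", "1.249", "118.4", "180")),
  ARG = list(c("CG", "N", "CA", "CB", "1.520", "114.1", "-60"),
             c("CD", "CA", "CB", "CG", "1.520", "111.3", "180"),
             c("NE", "CB", "CG", "CD", "1.461", "112.0", "180"),
             c("CZ", "CG", "CD", "NE", "1.329", "124.2", "180"),
             c("NH1", "CD", "NE", "CZ", "1.326", "120.0", "0"),
             c("NH2", "CD", "NE", "CZ", "1.326", "120.0", "180")),
  PHE = list(c("CG", "N", "CA", "CB", "1.502", "113.8", "180"),
             c("CD1", "CA", "CB", "CG", "1.390", "120.8", "90"),
             c("CD2", "CA", "CB", "CG", "1.390", "120.8", "-90"),
             c("CE1", "CB", "CG", "CD1", "1.390", "121.0", "180"),
             c("CE2", "CB", "CG", "CD2", "1.390", "121.0", "180"),
             c("CZ", "CG", "CD1", "CE1", "1.390", "120.0", "0")),
  GLY = list())

.buildableResidues <- names(.sideChainICTemplates)
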