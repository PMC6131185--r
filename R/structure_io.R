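#' Grouping configuration
#'
#' Declares how atoms of a snapshot map to tessellation groups and carries
#' the membrane geometry and the Laguerre water weight.
#'
#' @param waterNames Water residue names.
#' @param lipidNames Lipid residue names.
#' @param ionNames Ion residue names (ions enter the tessellation with
#'   weight 0, like protein atoms).
#' @param ligandName Ligand residue name, or `NA` if no ligand.
#' @param plugRange Residue-number range of the plug domain (default 1-148).
#' @param membraneAxis Membrane normal: `"x"`, `"y"` or `"z"`.
#' @param membraneSlab `c(low, high)` coordinates of the membrane slab along
#'   the axis, or `NA` to infer from the lipid extent.
#' @param waterWeight Laguerre weight (Angstrom^2) of water oxygen;
#'   default 1.48, the calibrated value.
#' @return A [GroupingConfig-class].
#' @export
groupingConfig <- function(waterNames = c("HOH", "SOL", "WAT", "TIP3", "SPC"),
                           lipidNames = c("DMP", "DMPC", "POPC", "POPE", "DPPC", "LIP"),
                           ionNames = c("NA", "CL", "K", "MG", "CA", "ZN", "SOD", "CLA", "ION"),
                           ligandName = NA_character_,
                           plugRange = c(1L, 148L),
                           membraneAxis = "z",
                           membraneSlab = NA_real_,
                           waterWeight = 1.48) {
  new("GroupingConfig", waterNames = waterNames, lipidNames = lipidNames,
      ionNames = ionNames, ligandName = as.character(ligandName),
      plugRange = as.integer(plugRange), membraneAxis = membraneAxis,
      membraneSlab = as.numeric(membraneSlab), waterWeight = waterWeight)
}

#' @describeIn GroupingConfig-class Compact display.
#' @param object A `GroupingConfig`.
#' @export
setMethod("show", "GroupingConfig", function(object) {
  cat(sprintf("GroupingConfig: water weight %.2f A^2, plug residues %d-%d, axis %s\n",
              object@waterWeight, object@plugRange[1], object@plugRange[2],
              object@membraneAxis))
  invisible(object)
})

#' Construct a molecular system from an atom table
#'
#' @param atoms data.frame with columns `serial, atom, element, resname,
#'   resno, chain, x, y, z, occupancy` (extra columns are kept).
#' @param label Snapshot label.
#' @return A [MolecularSystem-class].
#' @export
molecularSystem <- function(atoms, label = "") {
  if (is.null(atoms$element)) atoms$element <- elementFromName(atoms$atom)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  new("MolecularSystem", atoms = atoms, label = as.character(label))
}

#' @describeIn MolecularSystem-class Compact display.
#' @param object A `MolecularSystem`.
#' @export
setMethod("show", "MolecularSystem", function(object) {
  cat(sprintf("MolecularSystem '%s': %d atoms, %d residues\n",
              object@label, nrow(object@atoms),
              length(unique(paste(object@atoms$chain, object@atoms$resno,
                                  object@atoms$resname)))))
  invisible(object)
})

# Best-effort element symbol from a PDB atom name.
elementFromName <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(gsub("^[0-9]+", "", nm), 1, 1)
  el[grepl("^[0-9]*H", nm)] <- "H"
  el[nm %in% c("CL", "CLA")] <- "CL"
  el[nm %in% c("NA", "SOD")] <- "NA"
  el[nm %in% c("MG", "ZN", "FE", "CA2")] <- substr(nm[nm %in% c("MG", "ZN", "FE", "CA2")], 1, 2)
  el
}

#' Read PDB snapshots
#'
#' Parses a PDB file (ATOM/HETATM records; multi-MODEL files yield one
#' system per model).  All atoms, including hydrogens and alternate
#' locations, are loaded; conformer and hydrogen filtering happens in
#' [prepareSites()].
#'
#' @param path Path to a PDB file.
#' @return A list of [MolecularSystem-class], one per MODEL.
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty PDB file: ", path)
  out <- utils::capture.output(
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(serial = at$eleno,
                      atom = at$elety,
                      element = if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
                                  trimws(at$elesy) else elementFromName(at$elety),
                      resname = trimws(at$resid),
                      resno = at$resno,
                      chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = ifelse(is.na(at$o), 1, at$o),
                      alt = ifelse(is.na(at$alt), "", at$alt),
                      stringsAsFactors = FALSE)
  blank <- !nzchar(atoms$element)
  if (any(blank)) atoms$element[blank] <- elementFromName(atoms$atom[blank])
  nModels <- max(1L, nrow(pdb$xyz))
  out <- vector("list", nModels)
  for (m in seq_len(nModels)) {
    a <- atoms
    if (nModels > 1L) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    }
    out[[m]] <- molecularSystem(a, label = if (nModels > 1L)
      sprintf("%s#%d", basename(path), m) else basename(path))
  }
  out
}

# Resolve alternate locations: keep the highest-occupancy conformer per
# (chain, resno, resname, atom name); ties go to the alphabetically first
# altLoc code (i.e. 'A').
resolveAltLoc <- function(atoms) {
  if (is.null(atoms$alt) || !any(nzchar(atoms$alt))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$atom)
  ord <- order(key, -atoms$occupancy, atoms$alt)
  atoms <- atoms[ord, ]
  atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resname, atoms$atom)), ]
}

isHydrogen <- function(atoms) {
  toupper(atoms$element) == "H" | grepl("^[0-9]*H", toupper(trimws(atoms$atom)))
}

classifyKind <- function(atoms, cfg) {
  kind <- rep("protein", nrow(atoms))
  kind[atoms$resname %in% cfg@waterNames] <- "water"
  kind[atoms$resname %in% cfg@lipidNames] <- "lipid"
  kind[atoms$resname %in% cfg@ionNames] <- "ion"
  if (!is.na(cfg@ligandName)) kind[atoms$resname %in% cfg@ligandName] <- "ligand"
  kind
}

#' Reduce a snapshot to weighted tessellation sites
#'
#' Strips hydrogens, reduces each water molecule to its oxygen site with the
#' configured water weight, gives every other heavy atom weight 0, resolves
#' alternate locations (highest occupancy, ties to 'A'), and tags each site
#' with its group kind.
#'
#' @param system A [MolecularSystem-class].
#' @param cfg A [GroupingConfig-class].
#' @return Site data.frame as from [weightedSites()].
#' @export
prepareSites <- function(system, cfg = groupingConfig()) {
  atoms <- resolveAltLoc(system@atoms)
  kind <- classifyKind(atoms, cfg)
  hyd <- isHydrogen(atoms)
  water <- kind == "water"
  wkey <- paste(atoms$chain, atoms$resno)[water]
  isO <- toupper(atoms$element) == "O"
  lacking <- setdiff(unique(wkey), unique(wkey[isO[water]]))
  if (length(lacking))
    stop("water residue(s) without an oxygen atom: ", paste(head(lacking, 3), collapse = "; "))
  keep <- (!water & !hyd) | (water & isO)
  a <- atoms[keep, ]; k <- kind[keep]
  weightedSites(cbind(a$x, a$y, a$z),
                weight = ifelse(k == "water", cfg@waterWeight, 0),
                kind = k, chain = a$chain, resno = a$resno,
                resname = a$resname, atom = a$atom)
}

#' Reduce a snapshot keeping water hydrogens (calibration reference)
#'
#' Like [prepareSites()] but water molecules keep their O and H atoms and
#' every site has weight 0.  This is the all-atom-water reference used by
#' [calibrateWaterWeight()] to define the target surface-water volumes.
#'
#' @inheritParams prepareSites
#' @return Site data.frame.
#' @export
prepareSitesWithHydrogens <- function(system, cfg = groupingConfig()) {
  atoms <- resolveAltLoc(system@atoms)
  kind <- classifyKind(atoms, cfg)
  hyd <- isHydrogen(atoms)
  keep <- !hyd | kind == "water"
  a <- atoms[keep, ]; k <- kind[keep]
  weightedSites(cbind(a$x, a$y, a$z), weight = 0, kind = k, chain = a$chain,
                resno = a$resno, resname = a$resname, atom = a$atom)
}

#' Write / read the debug site-table format (TSV)
#'
#' @param sites Site data.frame.
#' @param path Output path.
#' @return `readSiteTable` returns the site data.frame.
#' @export
writeSiteTable <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chain = "character", resname = "character",
                            atom = "character", kind = "character"))
}

# Membrane slab bounds along the membrane axis; inferred from the lipid
# extent when not set explicitly.
membraneSlab <- function(sites, cfg) {
  if (all(is.finite(cfg@membraneSlab)) && length(cfg@membraneSlab) == 2)
    return(cfg@membraneSlab)
  ax <- match(cfg@membraneAxis, c("x", "y", "z"))
  lip <- sites$kind == "lipid"
  if (!any(lip)) stop("membraneSlab not set and no lipid sites to infer it from")
  range(sites[lip, c("x", "y", "z")[ax]])
}
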