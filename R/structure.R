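#' Atom table of a protein structure
#'
#' Validates a data frame of atom records.  Required columns: `record`
#' (`"ATOM"`/`"HETATM"`), `atom` (PDB atom name), `resid` (residue name),
#' `chain`, `resno`, and Cartesian `x`, `y`, `z` in Angstrom.  An
#' optional `insert` column carries insertion codes (default `""`); an
#' optional `element` column is filled in from the atom name when absent.
#'
#' @param df data frame of atom records.
#' @return The validated data frame with class `structure_atoms`.
#' @export
structure_atoms <- function(df) {
  need <- c("record", "atom", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing atom columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$insert)) df$insert <- ""
  df$insert[is.na(df$insert)] <- ""
  if (is.null(df$element)) df$element <- element_from_name(df$atom)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("coordinates must be finite", call. = FALSE)
  key <- paste(df$chain, df$resno, df$insert, df$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) record: ",
         key[duplicated(key)][1], call. = FALSE)
  class(df) <- c("structure_atoms", "data.frame")
  df
}

# infer the element from a PDB atom name: strip leading digits, take the
# first letter; "1HB"/"HG1" -> H, "OD1" -> O, "NZ" -> N.  Adequate for
# the standard amino-acid and chromophore atom names handled here.
element_from_name <- function(atom) {
  toupper(substr(sub("^[0-9]*", "", trimws(atom)), 1, 1))
}

#' Read a structure from a PDB file
#'
#' Fixed-column parsing via \pkg{bio3d}; only the first model is read and
#' alternate locations other than `'A'` (or blank) are dropped.
#'
#' @param path PDB file path.
#' @return A [structure_atoms()] data frame.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  df <- data.frame(record = at$type, atom = at$elety, resid = at$resid,
                   chain = ifelse(is.na(at$chain), "", at$chain),
                   resno = at$resno,
                   insert = ifelse(is.na(at$insert), "", at$insert),
                   x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  el <- at$elesy
  df$element <- ifelse(is.na(el) | el == "", element_from_name(df$atom),
                       toupper(trimws(el)))
  structure_atoms(df)
}

#' Write atoms to a minimal PDB file
#'
#' @param atoms a [structure_atoms()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  atoms <- structure_atoms(as.data.frame(atoms))
  name4 <- function(a) {           # PDB atom-name column alignment
    if (nchar(a) >= 4) substr(a, 1, 4) else sprintf(" %-3s", a)
  }
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            atoms$record[i], i, name4(atoms$atom[i]), atoms$resid[i],
            atoms$chain[i], atoms$resno[i], atoms$insert[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0, atoms$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# residue identifier strings "chain:resno:insert:resid"
residue_ids <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = ":")
}

select_chromophore <- function(atoms, chromophore) {
  sel <- if (is.numeric(chromophore)) atoms$resno == chromophore
         else atoms$resid == as.character(chromophore)
  if (!any(sel))
    stop("chromophore selector matches no atoms: ", chromophore,
         call. = FALSE)
  sel
}

heavy <- function(atoms) atoms$element != "H"

#' Residues near the chromophore
#'
#' Reports every residue (excluding the chromophore-bearing residue
#' itself) whose minimum heavy-atom distance to any chromophore atom is
#' within `cutoff`, sorted by that distance.  Hydrogens are ignored by
#' default, matching how binding-pocket contacts are conventionally
#' reported.
#'
#' @param atoms a [structure_atoms()] data frame.
#' @param chromophore residue name (character) or residue number
#'   (numeric) selecting the chromophore.
#' @param cutoff distance cutoff in Angstrom, > 0.
#' @param include_hydrogens include hydrogen atoms in the distances.
#' @return Data frame with columns `residue` (id string), `resid`,
#'   `chain`, `resno`, `distance`, sorted ascending by distance.
#' @export
residues_within_cutoff <- function(atoms, chromophore, cutoff = 2.5,
                                   include_hydrogens = FALSE) {
  atoms <- structure_atoms(as.data.frame(atoms))
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  sel <- select_chromophore(atoms, chromophore)
  if (!include_hydrogens) {
    hv <- heavy(atoms)
    chromo <- atoms[sel & hv, , drop = FALSE]
    other <- atoms[!sel & hv, , drop = FALSE]
  } else {
    chromo <- atoms[sel, , drop = FALSE]
    other <- atoms[!sel, , drop = FALSE]
  }
  if (nrow(chromo) == 0)
    stop("chromophore has no atoms after hydrogen filtering", call. = FALSE)
  ids <- residue_ids(other)
  cm <- as.matrix(chromo[, c("x", "y", "z")])
  res <- lapply(split(seq_len(nrow(other)), ids), function(idx) {
    om <- as.matrix(other[idx, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(om^2), rowSums(cm^2), `+`) - 2 * om %*% t(cm)
    min(sqrt(pmax(d2, 0)))
  })
  df <- data.frame(residue = names(res),
                   distance = unlist(res, use.names = FALSE),
                   stringsAsFactors = FALSE)
  parts <- strsplit(df$residue, ":", fixed = TRUE)
  df$chain <- vapply(parts, `[`, character(1), 1)
  df$resno <- as.integer(vapply(parts, `[`, character(1), 2))
  df$resid <- vapply(parts, `[`, character(1), 4)
  df <- df[df$distance <= cutoff, , drop = FALSE]
  df <- df[order(df$distance, df$residue), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("residue", "resid", "chain", "resno", "distance")]
}

# side-chain oxygen atom names by standard PDB naming: carboxylate
# (OD1/OD2, OE1/OE2), carboxamide (OD1, OE1), hydroxyl (OG, OG1, OH)
SIDECHAIN_OXYGENS <- c("OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH")

#' Side-chain-oxygen distances to the Schiff base nitrogen
#'
#' For each listed residue, the minimum distance from its side-chain
#' oxygen atoms to the named nitrogen atom of the chromophore (the
#' lysine-derived Schiff base nitrogen), ranked ascending.  Residues
#' without a side-chain oxygen are retained with `NA` distance and
#' `has_oxygen = FALSE`.
#'
#' @param atoms a [structure_atoms()] data frame.
#' @param chromophore residue name or number selecting the chromophore.
#' @param nitrogen_atom_name atom name of the Schiff base nitrogen within
#'   the chromophore residue (chromophore naming varies between model
#'   files, hence configurable).
#' @param residues integer vector of residue numbers to report.
#' @return Data frame with columns `resno`, `resid`, `chain`,
#'   `distance`, `has_oxygen`, sorted ascending by distance with
#'   flagged (no-oxygen) residues last.
#' @export
schiff_base_distances <- function(atoms, chromophore,
                                  nitrogen_atom_name = "NZ", residues) {
  atoms <- structure_atoms(as.data.frame(atoms))
  sel <- select_chromophore(atoms, chromophore)
  nsel <- sel & atoms$atom == nitrogen_atom_name
  if (!any(nsel))
    stop("nitrogen atom not found in chromophore: ", nitrogen_atom_name,
         call. = FALSE)
  nz <- as.numeric(atoms[which(nsel)[1], c("x", "y", "z")])
  rows <- lapply(residues, function(rn) {
    ra <- atoms[!sel & atoms$resno == rn, , drop = FALSE]
    if (nrow(ra) == 0)
      stop("listed residue not found: ", rn, call. = FALSE)
    ox <- ra[ra$atom %in% SIDECHAIN_OXYGENS, , drop = FALSE]
    d <- if (nrow(ox) == 0) NA_real_ else
      min(sqrt((ox$x - nz[1])^2 + (ox$y - nz[2])^2 + (ox$z - nz[3])^2))
    data.frame(resno = rn, resid = ra$resid[1], chain = ra$chain[1],
               distance = d, has_oxygen = nrow(ox) > 0,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(is.na(df$distance), df$distance), , drop = FALSE]
  rownames(df) <- NULL
  df
}
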