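#' Read the protons of a ligand-protein complex from a PDB file
#'
#' Minimal fixed-column reader for `ATOM`/`HETATM` records (no
#' general-purpose PDB parser is part of this package's dependency set).
#' Only hydrogens are kept: the structure must carry explicit protons --
#' an unprotonated model is rejected with a pointer to protonate upstream.
#'
#' Ownership: `HETATM` records, and any record whose residue name is in
#' `ligand_resnames`, are ligand protons; everything else is protein.
#' Methyl groups are detected as exactly three hydrogens of one residue
#' sharing an atom-name stem after stripping the trailing digit
#' (HB1/HB2/HB3 style). The default saturated set is all protein methyl
#' protons, emulating on-resonance irradiation in the methyl region;
#' override with a `chain:resname` filter via `saturate`.
#'
#' @param path PDB file path.
#' @param ligand_resnames residue names to treat as ligand in addition to
#'   HETATM records.
#' @param saturate `"methyl"` (default), `"none"`, or a character vector
#'   of `chain:resname` filters (e.g. `"A:ALA"`; `"*:LEU"` matches any
#'   chain) selecting the saturated protein protons.
#' @return a [spin_system].
#' @export
read_pdb_protons <- function(path, ligand_resnames = character(),
                             saturate = "methyl") {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0) stopf("no ATOM/HETATM records in %s", path)
  fld <- function(a, b) trimws(substring(lines, a, b))
  name <- fld(13, 16)
  resname <- fld(18, 20)
  chain <- fld(22, 22)
  resseq <- fld(23, 26)
  x <- as.numeric(fld(31, 38)); y <- as.numeric(fld(39, 46))
  z <- as.numeric(fld(47, 54))
  elem <- fld(77, 78)
  ## hydrogen: element column if present, else atom-name heuristic
  is_h <- ifelse(elem != "", elem == "H",
                 grepl("^[0-9]*H", name))
  if (!any(is_h))
    stopf("%s contains no explicit hydrogens; protonate the model upstream (e.g. with reduce/obabel) before simulation", path)
  het <- trimws(substring(lines, 1, 6)) == "HETATM"
  lig <- het | resname %in% ligand_resnames
  idx <- which(is_h)
  resid <- paste(chain[idx], resname[idx], resseq[idx], sep = ":")
  stem <- sub("[0-9]+$", "", name[idx])
  grp <- paste(resid, stem, sep = "/")
  tab <- table(grp)
  ## HB1/HB2/HB3-style triples; a bare "H" stem (H1, H2, ... ring protons)
  ## is not a methyl
  methyl_id <- ifelse(grp %in% names(tab)[tab == 3] & nchar(stem) >= 2,
                      grp, NA)
  labels <- make.unique(paste(resid, name[idx], sep = ":"))
  owner <- ifelse(lig[idx], "ligand", "protein")
  sat <- rep(FALSE, length(idx))
  if (identical(saturate, "methyl")) {
    sat <- owner == "protein" & !is.na(methyl_id)
  } else if (!identical(saturate, "none")) {
    for (f in saturate) {
      parts <- strsplit(f, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) stopf("bad saturate filter '%s': use chain:resname", f)
      hit <- (parts[1] == "*" | chain[idx] == parts[1]) &
        resname[idx] == parts[2] & owner == "protein"
      sat <- sat | hit
    }
  }
  if (sum(owner == "ligand") == 0)
    stopf("no ligand protons found: mark the ligand as HETATM or pass ligand_resnames")
  spin_system(labels, owner, cbind(x, y, z)[idx, , drop = FALSE],
              methyl_id = methyl_id, saturated = sat)
}
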