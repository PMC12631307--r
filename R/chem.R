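# OpenBabel-backed structure handling. All SMILES I/O goes through
# ChemmineOB::convertFormat in batches; a parse failure aborts the remainder
# of an OpenBabel batch, so conversion resumes after each offending input.

ob_options <- function(neutralize = FALSE) {
  if (neutralize) {
    data.frame(names = c("gen2D", "neutralize"), args = c("", ""))
  } else {
    data.frame(names = "gen2D", args = "")
  }
}

# Batch-convert SMILES, returning a vector aligned to the input with NA for
# inputs OpenBabel cannot parse.
ob_convert_smiles <- function(smiles, to = "CAN", neutralize = FALSE) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  ids <- paste0("m", seq_len(n))
  todo <- seq_len(n)
  repeat {
    src <- paste(paste0(smiles[todo], "\t", ids[todo]), collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", to, source = src,
                                     options = ob_options(neutralize))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      got_id <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, "")
      got_sm <- vapply(parts, function(p) trimws(p[[1]]), "")
      keep <- !is.na(got_id)
      out[match(got_id[keep], ids)] <- got_sm[keep]
    }
    missing <- todo[is.na(out[todo])]
    if (!length(missing)) break
    # first missing input is the offender; everything after it was dropped
    out[missing[1]] <- NA_character_
    todo <- missing[-1]
    if (!length(todo)) break
  }
  out
}

# SMILES -> V2000 molfile text, one string per input, NA where unparsable.
ob_molfiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  ids <- paste0("m", seq_len(n))
  todo <- seq_len(n)
  repeat {
    src <- paste(paste0(smiles[todo], "\t", ids[todo]), collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", "SDF", source = src)
    mols <- strsplit(res, "\\$\\$\\$\\$\n?")[[1]]
    mols <- mols[grepl("V2000", mols, fixed = TRUE)]
    for (m in mols) {
      title <- sub("\n.*$", "", m)
      i <- match(trimws(title), ids)
      if (!is.na(i)) out[i] <- sub("^\n+", "", m)
    }
    missing <- todo[is.na(out[todo])]
    if (!length(missing)) break
    out[missing[1]] <- NA_character_
    todo <- missing[-1]
    if (!length(todo)) break
  }
  out
}

# Convert molfile texts to canonical SMILES (batch, aligned, NA-safe).
ob_molfile_to_can <- function(molfiles) {
  n <- length(molfiles)
  out <- rep(NA_character_, n)
  ok <- which(!is.na(molfiles))
  if (!length(ok)) return(out)
  ids <- paste0("s", ok)
  blocks <- molfiles[ok]
  # force the title line to carry our id
  blocks <- vapply(seq_along(blocks), function(j) {
    b <- blocks[[j]]
    sub("^[^\n]*", ids[j], b)
  }, "")
  src <- paste0(paste(blocks, collapse = "\n$$$$\n"), "\n$$$$\n")
  res <- ChemmineOB::convertFormat("SDF", "CAN", source = src)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2) {
      i <- as.integer(sub("^s", "", trimws(p[[2]])))
      out[i] <- trimws(p[[1]])
    }
  }
  out
}

# count heavy-atom tokens in a SMILES fragment (for largest-fragment choice)
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    n_br <- lengths(regmatches(s, gregexpr("\\[[^]]*\\]", s)))
    s2 <- gsub("\\[[^]]*\\]", "", s)
    n_at <- lengths(regmatches(s2, gregexpr("Cl|Br|Si|Se|[BCNOPSFI]|[bcnops]", s2)))
    n_br + n_at
  }, integer(1), USE.NAMES = FALSE)
}

#' Standardize structures to a canonical, neutralized parent form
#'
#' Applies the package's structure-standardization pipeline: SMILES are
#' parsed with OpenBabel, +1/-1 charges are neutralized, the largest covalent
#' fragment is kept (salt/solvate stripping) and the result is written as a
#' canonical SMILES string. Identical molecules map to identical strings and
#' the transformation is idempotent.
#'
#' @param smiles character vector of raw SMILES.
#' @return Character vector of canonical SMILES aligned to the input, with
#'   `NA` for unparsable entries; the indices and inputs of rejected entries
#'   are attached as attribute `"rejected"` and reported via `message()`.
#' @examples
#' \donttest{
#' standardize_structure(c("C1=CC=CC=C1", "c1ccccc1", "OCC"))
#' }
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles))
  if (any(!nzchar(smiles) | is.na(smiles))) {
    stop("empty or NA SMILES are not valid input")
  }
  can <- ob_convert_smiles(smiles, "CAN", neutralize = TRUE)
  # salt stripping: keep the largest fragment, then re-canonicalize
  multi <- which(!is.na(can) & grepl(".", can, fixed = TRUE))
  if (length(multi)) {
    stripped <- vapply(can[multi], function(s) {
      frags <- strsplit(s, ".", fixed = TRUE)[[1]]
      frags[which.max(heavy_atom_count(frags))]
    }, "", USE.NAMES = FALSE)
    can[multi] <- ob_convert_smiles(stripped, "CAN", neutralize = TRUE)
  }
  bad <- which(is.na(can))
  if (length(bad)) {
    message(sprintf("standardize_structure: rejected %d unparsable SMILES (%s)",
                    length(bad),
                    paste(utils::head(smiles[bad], 5), collapse = ", ")))
    attr(can, "rejected") <- data.frame(index = bad, smiles = smiles[bad],
                                        reason = "unparsable SMILES",
                                        stringsAsFactors = FALSE)
  }
  can
}

# ---- molfile graph utilities -------------------------------------------------

parse_molfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  chg <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)), " +")[[1]]
    flds <- as.integer(flds)
    idx <- flds[seq(1, length(flds), 2)]
    chg[idx] <- flds[seq(2, length(flds), 2)]
  }
  list(elem = elem, bonds = bonds, charge = chg,
       atom_lines = atom_lines, n_atoms = na)
}

write_molfile <- function(mol, keep) {
  keep <- sort(keep)
  remap <- integer(mol$n_atoms)
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  hdr <- c("scaffold", "  mtperm", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    length(keep), nrow(b))
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        remap[b$a1], remap[b$a2], b$order)
  chg_lines <- character(0)
  ch <- which(mol$charge[keep] != 0)
  if (length(ch)) {
    chg_lines <- vapply(ch, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, mol$charge[keep[i]])
    }, "")
  }
  paste(c(hdr, counts, mol$atom_lines[keep],
          if (nrow(b)) bond_lines, chg_lines, "M  END"), collapse = "\n")
}

# Murcko framework atom set: iteratively prune terminal atoms, then re-attach
# atoms joined to the framework by a double/triple bond (exocyclic =O etc.).
murcko_atoms <- function(mol) {
  deg <- integer(mol$n_atoms)
  adj <- mol$bonds
  alive <- rep(TRUE, mol$n_atoms)
  repeat {
    deg[] <- 0L
    act <- adj[alive[adj$a1] & alive[adj$a2], , drop = FALSE]
    tb <- tabulate(c(act$a1, act$a2), nbins = mol$n_atoms)
    terminal <- which(alive & tb <= 1)
    if (!length(terminal)) break
    alive[terminal] <- FALSE
    if (!any(alive)) break
  }
  if (!any(alive)) return(integer(0))
  core <- which(alive)
  multi <- mol$bonds[mol$bonds$order >= 2, , drop = FALSE]
  extra <- c(multi$a1[multi$a2 %in% core], multi$a2[multi$a1 %in% core])
  sort(unique(c(core, setdiff(extra, core))))
}

#' Compute Bemis-Murcko scaffolds
#'
#' Reduces each molecule to its ring systems plus the linkers connecting
#' them, retaining atoms attached to the framework by double or triple bonds
#' (the usual Murcko convention), and returns the framework as a canonical
#' SMILES string. Acyclic molecules, which have no ring framework, map to the
#' empty string.
#'
#' @param smiles character vector of standardized SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules), aligned to the input.
#' @examples
#' \donttest{
#' bemis_murcko_scaffold(c("OCCc1ccccc1", "CCO"))
#' }
#' @export
bemis_murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  mf <- ob_molfiles(smiles)
  if (anyNA(mf)) {
    stop("invalid SMILES: ", paste(utils::head(smiles[is.na(mf)], 5), collapse = ", "))
  }
  out <- character(length(smiles))
  scaffold_mf <- rep(NA_character_, length(smiles))
  for (i in seq_along(mf)) {
    mol <- parse_molfile(mf[i])
    keep <- murcko_atoms(mol)
    if (length(keep)) scaffold_mf[i] <- write_molfile(mol, keep)
  }
  has <- which(!is.na(scaffold_mf))
  if (length(has)) {
    can <- ob_molfile_to_can(scaffold_mf)
    out[has] <- can[has]
  }
  out
}

# Shared SDFset builder for descriptor/fingerprint code.
smiles_to_sdfset <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("CMP", seq_along(smiles))
  mf <- ob_molfiles(smiles)
  if (anyNA(mf)) {
    stop("invalid SMILES: ", paste(utils::head(smiles[is.na(mf)], 5), collapse = ", "))
  }
  mf <- ifelse(endsWith(mf, "\n"), mf, paste0(mf, "\n"))
  txt <- paste0(paste(mf, collapse = "$$$$\n"), "$$$$")
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(txt, "\n", fixed = TRUE)[[1]]))
  ChemmineR::cid(sdf) <- ids
  sdf
}
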