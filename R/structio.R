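# Canonical in-memory protein structure representation and file I/O.
#
# A "pdbstruct" is a flat atom table plus an id. Residue identity follows
# author numbering as deposited (chain, resno, insertion code), never a
# sequential index, so residue labels like "S2" match published tables.

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `occ`. Row order is file order.
#' @param id character identifier for the structure.
#' @return An object of class `pdbstruct`.
#' @export
pdbstruct <- function(atoms, id = "structure") {
  req <- c("chain", "resno", "icode", "resname", "atom", "element",
           "x", "y", "z", "occ")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms[req]), class = "pdbstruct")
}

#' @export
print.pdbstruct <- function(x, ...) {
  res <- structure_residues(x)
  cat("<pdbstruct>", x$id, "-", nrow(x$atoms), "atoms,",
      nrow(res), "residues, chains:",
      paste(unique(res$chain), collapse = ","), "\n")
  invisible(x)
}

residue_key <- function(chain, resno, icode) {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = "|")
}

#' Residue table of a structure
#'
#' One row per residue in file order, with a unique key combining chain,
#' author residue number and insertion code.
#'
#' @param x a `pdbstruct`.
#' @param chain optional chain id to restrict to.
#' @return data.frame with columns `key`, `chain`, `resno`, `icode`,
#'   `resname`.
#' @export
structure_residues <- function(x, chain = NULL) {
  a <- x$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  key <- residue_key(a$chain, a$resno, a$icode)
  keep <- !duplicated(key)
  out <- data.frame(key = key[keep], chain = a$chain[keep],
                    resno = a$resno[keep], icode = a$icode[keep],
                    resname = a$resname[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# three-letter -> one-letter; non-standard residues map to X but keep
# their geometry for distance/SASA work
AA3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa_three_to_one <- function(resname) {
  out <- unname(AA3to1[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

#' One-letter sequence of a chain
#'
#' @param x a `pdbstruct`.
#' @param chain chain id (default: first chain in the file).
#' @return character scalar; non-standard residues appear as `X`.
#' @export
chain_sequence <- function(x, chain = NULL) {
  res <- structure_residues(x)
  if (is.null(chain)) chain <- res$chain[1L]
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) stop("no residues on chain ", chain)
  paste(aa_three_to_one(res$resname), collapse = "")
}

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Fixed-column PDB text is parsed via \code{bio3d::read.pdb}; water and
#' heteroatom records are excluded by default and alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by file order).
#'
#' @param path PDB file path.
#' @param model_index 1-based model to select for multi-model files.
#' @param altloc_policy `"occupancy"` (default, highest occupancy wins,
#'   ties -> first in file) or `"first"` (first conformer in file order).
#' @param keep_hetero keep HETATM records (waters are still dropped).
#' @param keep_water keep water residues.
#' @param chain optional chain id(s) to restrict to.
#' @param id structure identifier; defaults to the file base name.
#' @return A `pdbstruct`.
#' @export
read_structure <- function(path, model_index = 1L,
                           altloc_policy = c("occupancy", "first"),
                           keep_hetero = FALSE, keep_water = FALSE,
                           chain = NULL, id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pdb_lines(path)
  multi <- model_index > 1L
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("malformed PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (multi) {
    nmod <- nrow(pdb$xyz)
    if (model_index > nmod) {
      stop("model_index ", model_index, " out of range: file has ",
           nmod, " model(s)")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  if (!keep_water) at <- at[!(toupper(at$resid) %in% WATER_NAMES), , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure after filtering: ", path)

  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altlocs within each (chain, resno, icode, atom-name) group
  if (any(!is.na(at$alt))) {
    grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    keep <- rep(TRUE, nrow(at))
    for (g in unique(grp[duplicated(grp)])) {
      idx <- which(grp == g)
      win <- if (altloc_policy == "occupancy") idx[which.max(at$o[idx])] else idx[1L]
      keep[setdiff(idx, win)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      icode = at$insert, resname = toupper(at$resid),
                      atom = at$elety, element = toupper(elem),
                      x = at$x, y = at$y, z = at$z, occ = at$o,
                      stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdbstruct(atoms, id = id)
}

# cheap pre-scan so malformed coordinate records are reported with their
# line number (bio3d's parser is lenient and positional)
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(coord) == 0L) {
    stop("no ATOM/HETATM records in '", path, "'")
  }
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop("malformed PDB record at line ", i, " of '", path,
           "': shorter than coordinate field (54 columns)")
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("malformed PDB record at line ", i, " of '", path,
           "': non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

guess_element <- function(elety) {
  e <- gsub("[^A-Za-z]", "", elety)
  # standard protein atom names start with the element's single letter;
  # two-letter elements in ATOM records (SE of MSE) are handled explicitly
  out <- substr(e, 1L, 1L)
  out[toupper(substr(e, 1L, 2L)) == "SE"] <- "SE"
  toupper(out)
}

#' Write a structure to a PDB file
#'
#' @param x a `pdbstruct`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$atom, chain = a$chain, insert = a$icode,
                   o = a$occ, b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference identifier of the record whose ungapped numbering defines
#'   reference coordinates.
#' @return An `msa` object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), reference) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
      off <- ids[w != stats::median(w)]
      stop("ragged alignment: records of deviating length: ",
           paste(off, collapse = ", "))
    }
  } else {
    m <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(m)
    ids <- names(seqs)
  }
  names(seqs) <- NULL
  msa(ids, toupper(seqs), reference)
}

#' Construct a multiple sequence alignment object
#'
#' @param ids record identifiers.
#' @param seqs aligned sequences (equal length, `-` for gaps).
#' @param reference id of the reference record.
#' @return list of class `msa` with the alignment, the reference id and
#'   `ref_map`, the alignment column of each ungapped reference position.
#' @export
msa <- function(ids, seqs, reference) {
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicated record identifiers")
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    stop("ragged alignment: records of deviating length: ",
         paste(ids[w != stats::median(w)], collapse = ", "))
  }
  if (!reference %in% ids) stop("reference record '", reference, "' not found")
  refseq <- strsplit(seqs[match(reference, ids)], "")[[1]]
  ref_map <- which(refseq != "-")
  structure(list(ids = ids, seqs = seqs, reference = reference,
                 ref_map = ref_map),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa>", length(x$ids), "records x", nchar(x$seqs[1L]),
      "columns; reference:", x$reference,
      sprintf("(%d ungapped positions)\n", length(x$ref_map)))
  invisible(x)
}

#' Write an epitope table to TSV
#'
#' Serialises the output of [predict_epitopes()]: one row per epitope with
#' semicolon-joined `chain:resno:resname` member lists and per-member
#' provenance.
#'
#' @param table an `epitope_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epitope_table <- function(table, path) {
  cols <- c("structure", "epitope_id", "centers", "members",
            "n_residues", "provenance")
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0L) stop("epitope table missing columns: ",
                              paste(miss, collapse = ", "))
  utils::write.table(table[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an epitope table written by [write_epitope_table()]
#'
#' @param path TSV path.
#' @return data.frame of class `epitope_table`.
#' @export
read_epitope_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(structure = "character",
                                          epitope_id = "integer",
                                          centers = "character",
                                          members = "character",
                                          n_residues = "integer",
                                          provenance = "character"))
  class(out) <- c("epitope_table", "data.frame")
  out
}

#' Parse a compact epitope residue-list specification
#'
#' Published discontinuous epitopes are transcribed as semicolon-separated
#' runs `start-end:SEQ` or single residues `pos:X`, e.g.
#' `"2-10:SWQTYVDDH;35:Q;125:Y;129-131:QGL"`. The one-letter stretch must
#' match the run length.
#'
#' @param text compact specification string.
#' @return data.frame with columns `resno` and `aa` (one row per residue).
#' @export
parse_epitope_spec <- function(text) {
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  out <- lapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad epitope segment: '", p, "'")
    rng <- as.integer(strsplit(kv[1], "-", fixed = TRUE)[[1]])
    resno <- if (length(rng) == 2L) seq(rng[1], rng[2]) else rng
    aa <- strsplit(kv[2], "")[[1]]
    if (length(aa) != length(resno)) {
      stop("segment '", p, "' has ", length(resno), " positions but ",
           length(aa), " residue letters")
    }
    data.frame(resno = resno, aa = aa, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
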