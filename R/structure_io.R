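# structure_io: read/write PDB and mmCIF, expose atoms as a structure_model.
#
# PDB parsing/writing is delegated to bio3d. mmCIF atom_site records are
# parsed/written in-package with a header-driven loop reader, so column order
# in the file does not matter.

#' Construct a structure model
#'
#' The internal container for a macromolecular structure: an ordered atom
#' table with per-residue predictor confidence (pLDDT convention: stored in
#' the B-factor column of files, range 0-100). Coordinates are Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number`, `x`, `y`, `z`, `element`, `confidence`.
#'   A `vdw_radius` column is derived from `element` if absent.
#' @return Object of class `structure_model`: a list with element `atoms`.
#' @export
structure_model <- function(atoms) {
  req <- c("serial", "atom_name", "residue_name", "chain_id",
           "residue_number", "x", "y", "z", "element", "confidence")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(atoms$residue_number < 1)) {
    stop("residue numbers must be >= 1 (1-based convention)")
  }
  out_of_range <- atoms$confidence < 0 | atoms$confidence > 100
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range), " confidence values outside [0,100]; clamped")
    atoms$confidence <- pmin(pmax(atoms$confidence, 0), 100)
  }
  if (is.null(atoms$vdw_radius)) {
    atoms$vdw_radius <- vdw_radius_of(atoms$element)
  }
  # residue numbers must not decrease within a chain
  for (ch in unique(atoms$chain_id)) {
    rn <- atoms$residue_number[atoms$chain_id == ch]
    if (is.unsorted(rn)) {
      stop("residue numbers not non-decreasing within chain ", ch)
    }
  }
  rownames(atoms) <- NULL
  obj <- structure(list(atoms = atoms), class = "structure_model")
  ca <- atoms$atom_name == "CA"
  std <- atoms$residue_name %in% names(AA_321)
  res_with_ca <- unique(atoms$residue_number[ca])
  std_res <- unique(atoms$residue_number[std])
  if (length(setdiff(std_res, res_with_ca)) > 0) {
    warning("some standard residues lack a CA atom")
  }
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<structure_model> %d atoms, %d residues, chain(s) %s\n",
    nrow(a), n_residues(x), paste(unique(a$chain_id), collapse = ",")
  ))
  invisible(x)
}

#' Number of residues in a model
#' @param model structure_model
#' @param chain optional chain id; default all chains
#' @return integer count of distinct (chain, residue_number) pairs
#' @export
n_residues <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain_id == chain, , drop = FALSE]
  nrow(unique(a[, c("chain_id", "residue_number")]))
}

#' Residue numbers present in a model
#' @inheritParams n_residues
#' @return sorted integer vector
#' @export
residue_numbers <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain_id == chain, , drop = FALSE]
  sort(unique(a$residue_number))
}

# CA coordinate matrix, rownames = residue numbers
ca_coords <- function(model, chain = NULL, residues = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain_id == chain, , drop = FALSE]
  a <- a[a$atom_name == "CA", , drop = FALSE]
  a <- a[!duplicated(a$residue_number), , drop = FALSE]
  if (!is.null(residues)) a <- a[a$residue_number %in% residues, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$residue_number
  m
}

atom_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# replace coordinates, preserving everything else
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# subset a model to a residue-number window (all chains)
subset_residues <- function(model, start, end) {
  keep <- model$atoms$residue_number >= start & model$atoms$residue_number <= end
  if (!any(keep)) stop("no atoms in residue range [", start, ", ", end, "]")
  structure_model(model$atoms[keep, , drop = FALSE])
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  stop("cannot guess format from extension '.", ext,
       "'; pass format = 'pdb' or 'mmcif'")
}

#' Read a structure file (PDB or mmCIF)
#'
#' Residue numbering and the B-factor column (interpreted as per-residue
#' predictor confidence, pLDDT-style) are preserved. Only the first model of
#' a multi-model file is read (with a warning). For alternate locations the
#' highest-occupancy conformer is kept; insertion codes are rejected because
#' predictor outputs never carry them.
#'
#' @param path file path
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension)
#' @return [structure_model()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  at <- if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
  if (nrow(at) == 0) stop("no atoms found in ", path)
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes present in ", path,
         "; renumber the structure (predictor outputs have none)")
  }
  # altloc: keep highest occupancy per (chain, residue, atom name)
  if (any(!is.na(at$alt) & nzchar(at$alt))) {
    ord <- order(at$chain_id, at$residue_number, at$atom_name, -at$occupancy)
    at <- at[ord, , drop = FALSE]
    key <- paste(at$chain_id, at$residue_number, at$atom_name)
    at <- at[!duplicated(key), , drop = FALSE]
    at <- at[order(at$serial), , drop = FALSE]
  }
  at$insert <- NULL
  at$alt <- NULL
  at$occupancy <- NULL
  structure_model(at)
}

read_pdb_atoms <- function(path) {
  n_models <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
  if (n_models > 1) {
    warning("multi-model file; taking the first model only")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  a <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- substr(trimws(a$elety[blank]), 1, 1)
  data.frame(
    serial = as.integer(a$eleno),
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    chain_id = ifelse(is.na(a$chain), "A", a$chain),
    residue_number = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    element = toupper(trimws(elem)),
    confidence = a$b,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    insert = ifelse(is.na(a$insert), "", a$insert),
    stringsAsFactors = FALSE
  )
}

# minimal header-driven mmCIF atom_site loop reader
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) stop("no _atom_site loop in ", path, " (format error)")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  data_start <- max(hdr_idx) + 1
  rows <- list()
  for (i in data_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(#|loop_|_[A-Za-z]|data_)", ln)) break
    tok <- scan(text = ln, what = character(), quiet = TRUE)
    if (length(tok) != length(fields)) {
      stop("mmCIF atom_site row with ", length(tok), " tokens, expected ",
           length(fields), " (format error)")
    }
    rows[[length(rows) + 1L]] <- tok
  }
  if (length(rows) == 0) stop("empty _atom_site loop in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  col <- function(nms, default = NA_character_) {
    for (nm in nms) if (nm %in% fields) return(m[, nm])
    rep(default, nrow(m))
  }
  grp <- col("group_PDB", "ATOM")
  keep <- grp %in% c("ATOM", "HETATM")
  m <- m[keep, , drop = FALSE]
  col <- function(nms, default = NA_character_) {
    for (nm in nms) if (nm %in% fields) return(m[, nm])
    rep(default, nrow(m))
  }
  modelnum <- col("pdbx_PDB_model_num", "1")
  if (length(unique(modelnum)) > 1) {
    warning("multi-model file; taking the first model only")
    m <- m[modelnum == modelnum[1], , drop = FALSE]
  }
  dot <- function(x, repl = "") ifelse(x %in% c(".", "?") | is.na(x), repl, x)
  data.frame(
    serial = as.integer(col("id")),
    atom_name = dot(col(c("auth_atom_id", "label_atom_id"))),
    residue_name = dot(col(c("auth_comp_id", "label_comp_id"))),
    chain_id = dot(col(c("auth_asym_id", "label_asym_id")), "A"),
    residue_number = as.integer(dot(col(c("auth_seq_id", "label_seq_id")), "0")),
    x = as.numeric(col("Cartn_x")),
    y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    element = toupper(dot(col("type_symbol"))),
    confidence = as.numeric(dot(col("B_iso_or_equiv"), "0")),
    occupancy = as.numeric(dot(col("occupancy"), "1")),
    alt = dot(col("label_alt_id")),
    insert = dot(col("pdbx_PDB_ins_code")),
    stringsAsFactors = FALSE
  )
}

#' Write a structure model to PDB or mmCIF
#'
#' Confidence is emitted in the B-factor column with two decimals. PDB chain
#' identifiers are limited to one character by the format; longer ids raise
#' an error rather than being truncated (use mmCIF for long ids).
#'
#' @param model [structure_model()]
#' @param path output file path
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension)
#' @return invisibly, `path`
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  a <- model$atoms
  if (nrow(a) == 0) stop("empty model: nothing to write")
  if (format == "pdb") {
    if (any(nchar(a$chain_id) > 1)) {
      stop("PDB chain ids are limited to 1 character; found '",
           a$chain_id[which(nchar(a$chain_id) > 1)[1]],
           "'. Write mmCIF instead.")
    }
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(a)),
      resno = a$residue_number, resid = a$residue_name,
      eleno = a$serial, elety = a$atom_name, chain = a$chain_id,
      o = rep(1, nrow(a)), b = round(a$confidence, 2),
      elesy = a$element
    )
  } else {
    write_mmcif_atoms(a, path)
  }
  invisible(path)
}

write_mmcif_atoms <- function(a, path) {
  hdr <- c(
    "data_megastitch", "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_seq_id", "pdbx_PDB_ins_code",
      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "auth_seq_id", "auth_asym_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- sprintf(
    "ATOM %d %s %s . %s %s %d ? %.3f %.3f %.3f 1.00 %.2f %d %s 1",
    a$serial, a$element, a$atom_name, a$residue_name, a$chain_id,
    a$residue_number, a$x, a$y, a$z, a$confidence, a$residue_number,
    a$chain_id
  )
  writeLines(c(hdr, rows, "#"), path)
}

#' Extract the one-letter sequence of a chain
#'
#' One letter per residue in residue-number order; non-standard residues map
#' to `"X"`. Numbering gaps are recorded in the `gaps` attribute.
#'
#' @param model [structure_model()]
#' @param chain chain id; default the first chain in the model
#' @return character scalar with attributes `residue_numbers` (integer) and
#'   `gaps` (data.frame of missing runs, zero rows when numbering is
#'   contiguous)
#' @export
extract_sequence <- function(model, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain_id[1]
  a <- a[a$chain_id == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' not present in model")
  a <- a[!duplicated(a$residue_number), , drop = FALSE]
  a <- a[order(a$residue_number), , drop = FALSE]
  letters1 <- aa_three_to_one(a$residue_name)
  seq <- paste(letters1, collapse = "")
  rn <- a$residue_number
  gap_after <- which(diff(rn) > 1)
  gaps <- data.frame(
    from = rn[gap_after] + 1L,
    to = rn[gap_after + 1L] - 1L
  )
  attr(seq, "residue_numbers") <- rn
  attr(seq, "gaps") <- gaps
  seq
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA file
#' @return upper-case amino-acid string (gap characters removed)
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fa <- bio3d::read.fasta(path)
  s <- toupper(paste(fa$ali[1, ], collapse = ""))
  gsub("[-.*]", "", s)
}
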