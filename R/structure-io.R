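#' Standard amino-acid three-letter codes
#'
#' The default polymer whitelist used when flagging residues as polymer
#' (protein) versus hetero groups.  Non-standard residues can be treated as
#' polymer by extending this vector and passing it to [parse_structure()] /
#' [select_polymer()].
#'
#' @return Character vector of 20 three-letter residue codes.
#' @export
standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# two-letter element symbols recognised when the element column is absent
.ion_elements <- c("CA", "MG", "ZN", "NA", "FE", "MN", "CL", "CU", "NI", "K")

.guess_element <- function(name, resname, hetero) {
  nm <- gsub("[^A-Za-z]", "", name)
  nm <- toupper(nm)
  if (hetero && toupper(resname) == nm && nm %in% .ion_elements) return(nm)
  if (nchar(nm) == 0L) return("X")
  substr(nm, 1L, 1L)
}

.residue_key <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", ".", insert),
        sep = "|")
}

#' Parse PDB-format text into a structure model
#'
#' Reads the fixed-column ATOM/HETATM/HELIX subset of the PDB format (via
#' \pkg{bio3d}) into a flat atom table grouped by residue and chain.  Only the
#' first MODEL of a multi-model file is used (with a warning).  Alternate
#' locations are resolved deterministically: the altloc with the highest
#' occupancy is kept; ties go to the lexicographically smallest altloc
#' character.  Waters and other hetero groups are retained and flagged
#' `hetero = TRUE`; hydrogens are retained but ignored by all detectors.
#'
#' @param pdb_text Character vector of PDB lines, or a single string
#'   containing newline-separated lines.
#' @param structure_id Identifier stored on the returned model.
#' @param polymer_whitelist Residue names treated as polymer (default the 20
#'   standard amino acids); everything else is flagged hetero-like for
#'   analysis purposes.
#' @return An object of class `structure_model`: a list with elements
#'   `structure_id`, `atoms` (data frame with columns `serial`, `name`,
#'   `alt`, `resname`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`,
#'   `b`, `element`, `hetero`, `polymer`) and `helix` (data frame with
#'   columns `chain`, `start`, `end`; zero rows when no HELIX records).
#' @examples
#' m <- parse_structure(c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
#' ))
#' nrow(m$atoms)
#' @export
parse_structure <- function(pdb_text, structure_id = "structure",
                            polymer_whitelist = standard_aa()) {
  if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1L]]
  }
  if (length(pdb_text) == 0L || all(!nzchar(pdb_text))) {
    stop("empty PDB input: no ATOM or HETATM records found")
  }
  is_atom <- grepl("^(ATOM|HETATM)", pdb_text)
  if (!any(is_atom)) {
    stop("no ATOM or HETATM records found in input")
  }
  for (i in which(is_atom)) {
    ln <- pdb_text[i]
    if (nchar(ln) < 54L) {
      stop(sprintf("malformed fixed-column record at line %d: too short", i))
    }
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(flds)))) {
      stop(sprintf("malformed fixed-column record at line %d: bad coordinate field", i))
    }
  }
  # multi-model files: keep the first MODEL only
  model_lines <- grep("^MODEL ", pdb_text)
  if (length(model_lines) > 1L) {
    warning("multiple MODEL records found; using the first model only")
    endmdl <- grep("^ENDMDL", pdb_text)[1L]
    pdb_text <- pdb_text[seq_len(endmdl - 1L)]
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)

  a <- pdb$atom
  occ <- ifelse(is.na(a$o), 1, a$o)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  insert <- ifelse(is.na(a$insert), "", a$insert)
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  element <- a$elesy
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    element[miss] <- mapply(.guess_element, a$elety[miss], a$resid[miss],
                            a$type[miss] == "HETATM")
  }
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, alt = alt, resname = a$resid,
    chain = chain, resno = a$resno, insert = insert,
    x = a$x, y = a$y, z = a$z, occ = occ,
    b = ifelse(is.na(a$b), 0, a$b),
    element = toupper(element),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )

  # altloc resolution: keep highest occupancy, tie -> smallest altloc char
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$serial, a$eleno)), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$polymer <- !atoms$hetero & atoms$resname %in% polymer_whitelist

  helix <- data.frame(chain = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!is.null(pdb$helix) && length(pdb$helix$start) > 0L) {
    helix <- data.frame(chain = as.character(pdb$helix$chain),
                        start = as.integer(pdb$helix$start),
                        end = as.integer(pdb$helix$end),
                        stringsAsFactors = FALSE)
  }

  structure(list(structure_id = structure_id, atoms = atoms, helix = helix),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  rk <- .residue_key(a$chain, a$resno, a$insert)
  cat(sprintf(
    "<structure_model> %s: %d atoms, %d residues, chains: %s; %d HELIX record(s)\n",
    x$structure_id, nrow(a), length(unique(rk)),
    paste(unique(a$chain), collapse = ","), nrow(x$helix)))
  invisible(x)
}

#' Restrict a structure model to one chain
#'
#' Returns the model restricted to the named chain.  Standard amino acids stay
#' flagged `polymer = TRUE`; waters, ions and other ligands of the chain are
#' retained with `polymer = FALSE` so that metal-coordination analysis still
#' sees them.
#'
#' @param model A `structure_model`.
#' @param chain_id Chain identifier; default `NULL` selects the first chain in
#'   file order.
#' @param polymer_whitelist Residue names treated as polymer.
#' @return A `structure_model` containing only the selected chain.
#' @export
select_polymer <- function(model, chain_id = NULL,
                           polymer_whitelist = standard_aa()) {
  stopifnot(inherits(model, "structure_model"))
  chains <- unique(model$atoms$chain)
  if (is.null(chain_id)) chain_id <- chains[1L]
  if (!chain_id %in% chains) {
    stop(sprintf("unknown chain '%s'; available chains: %s",
                 chain_id, paste(chains, collapse = ", ")))
  }
  atoms <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$polymer <- !atoms$hetero & atoms$resname %in% polymer_whitelist
  helix <- model$helix[model$helix$chain == chain_id, , drop = FALSE]
  structure(list(structure_id = model$structure_id, atoms = atoms,
                 helix = helix),
            class = "structure_model")
}

#' Write a structure model as fixed-column PDB text
#'
#' Inverse of [parse_structure()]: `parse_structure(write_structure(m))`
#' preserves residue identities and coordinates to three decimals.  HELIX
#' annotations are emitted before the coordinate records.
#'
#' @param model A `structure_model` with at least one atom.
#' @return Character vector of PDB lines.
#' @export
write_structure <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0L) stop("cannot write an empty model (0 atoms)")
  if (any(nchar(a$name) > 4L)) {
    stop("atom name longer than 4 characters cannot be written in PDB format")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = tf, xyz = xyz,
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    alt = ifelse(a$alt == "", NA, a$alt),
    o = a$occ, b = a$b, elesy = a$element
  )
  lines <- readLines(tf)
  if (nrow(model$helix) > 0L) {
    h <- model$helix
    res_at <- function(ch, no) {
      hit <- a$chain == ch & a$resno == no
      if (any(hit)) a$resname[hit][1L] else "ALA"
    }
    hl <- vapply(seq_len(nrow(h)), function(i) {
      paste0("HELIX  ", sprintf("%3d", i), " ", sprintf("%3d", i), " ",
             sprintf("%3s", res_at(h$chain[i], h$start[i])), " ",
             h$chain[i], " ", sprintf("%4d", h$start[i]), "  ",
             sprintf("%3s", res_at(h$chain[i], h$end[i])), " ",
             h$chain[i], " ", sprintf("%4d", h$end[i]), "  1",
             strrep(" ", 30),
             sprintf("%6d", h$end[i] - h$start[i] + 1L))
    }, character(1L))
    lines <- c(hl, lines)
  }
  lines
}

# residue-level view: one row per residue in file order, with atom row indices
.residues <- function(model, polymer_only = TRUE) {
  a <- model$atoms
  if (polymer_only) {
    if (!any(a$polymer)) {
      stop("no polymer residues in model; run select_polymer() or check the whitelist")
    }
    idx <- which(a$polymer & a$element != "H")
  } else {
    idx <- seq_len(nrow(a))
  }
  key <- .residue_key(a$chain[idx], a$resno[idx], a$insert[idx])
  split_idx <- split(idx, factor(key, levels = unique(key)))
  info <- data.frame(
    key = names(split_idx),
    chain = a$chain[vapply(split_idx, `[`, 1L, 1L)],
    resno = a$resno[vapply(split_idx, `[`, 1L, 1L)],
    resname = a$resname[vapply(split_idx, `[`, 1L, 1L)],
    stringsAsFactors = FALSE
  )
  rownames(info) <- NULL
  list(info = info, atoms = split_idx)
}
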