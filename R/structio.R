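# Structure I/O and residue/atom addressing.
#
# A decaaf_structure is a light wrapper around a bio3d-style atom table: one
# row per atom, residues addressed by (chain, resno, insert) in author
# numbering exactly as deposited. Parsing goes through bio3d; altloc
# resolution and PQR charge handling are done here.

#' Default residue-to-reactive-atom map
#'
#' Each residue is represented in motif matching by a single functionally
#' relevant ("reactive") atom: the nucleophilic or charged side-chain atom for
#' polar residues, the backbone amide nitrogen for Gly and Ala (whose oxyanion
#' hole role is backbone-mediated), and CA as a fallback so every residue type
#' remains addressable.
#'
#' @return Named character vector mapping 3-letter residue codes to atom
#'   names. Residue types absent from the map fall back to `"CA"` (see
#'   [reactive_atom_name()]).
#' @examples
#' default_reactive_atoms()[["SER"]]
#' @export
default_reactive_atoms <- function() {
  c(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
    HIS = "ND1", LYS = "NZ", ARG = "NH1",
    ASP = "OD1", GLU = "OE1", ASN = "OD1", GLN = "OE1",
    GLY = "N", ALA = "N")
}

#' Reactive atom name for a residue type
#'
#' @param resname 3-letter residue code (case-insensitive).
#' @param map named map as returned by [default_reactive_atoms()].
#' @return Atom name; `"CA"` for residue types not in the map.
#' @export
reactive_atom_name <- function(resname, map = default_reactive_atoms()) {
  resname <- toupper(resname)
  out <- unname(map[resname])
  out[is.na(out)] <- "CA"
  out
}

new_structure <- function(id, atoms, source = NA_character_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  structure(list(id = id, atoms = atoms, source = source),
            class = "decaaf_structure")
}

#' @export
print.decaaf_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("decaaf structure '%s': %d atoms, %d residues (%d waters)\n",
              x$id, nrow(x$atoms), nrow(res), sum(res$is_water)))
  invisible(x)
}

#' Read a protein structure from PDB or PQR
#'
#' All ATOM/HETATM records of the selected model are retained, including
#' waters. Alternate locations are resolved per `altloc`: the default keeps,
#' for each (chain, residue, atom name), the conformer with the highest
#' occupancy, breaking ties by file order.
#'
#' @param path path to a PDB or PQR file.
#' @param model 1-based model index for multi-model (e.g. NMR) files.
#' @param altloc `"occupancy"` (default), `"first"`, or `"all"` (no
#'   resolution; atom names may then repeat within a residue).
#' @param format `"auto"` (by extension), `"pdb"` or `"pqr"`. PQR files carry
#'   per-atom partial charges and radii, which populate the `charge` and
#'   `radius` columns.
#' @param id structure identifier; defaults to the file base name.
#' @return A `decaaf_structure`: a list with `id`, `atoms` (data frame with
#'   columns `type`, `serial`, `name`, `altloc`, `resname`, `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `occupancy`, `bfactor`, `element`, `charge`,
#'   `radius`, `potential`) and `source`.
#' @export
read_structure <- function(path, model = 1L,
                           altloc = c("occupancy", "first", "all"),
                           format = c("auto", "pdb", "pqr"),
                           id = NULL) {
  altloc <- match.arg(altloc)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.(pdb|pqr|ent)$", "", basename(path),
                             ignore.case = TRUE)

  if (format == "pqr") {
    p <- tryCatch(bio3d::read.pqr(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PQR '", path, "': ",
                                           conditionMessage(e)))
    at <- p$atom
    if (nrow(at) == 0) stop("no atoms in '", path, "'")
    if (model != 1L) stop("model index out of range: PQR files hold one model")
    charge <- at$o     # read.pqr stores charge in the occupancy column
    radius <- at$b     # ... and radius in the B-factor column
    occupancy <- rep(1, nrow(at))
    bfactor <- rep(NA_real_, nrow(at))
  } else {
    p <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e)))
    at <- p$atom
    if (nrow(at) == 0) stop("no atoms in '", path, "'")
    n_models <- if (is.matrix(p$xyz)) nrow(p$xyz) else 1L
    if (model < 1L || model > n_models) {
      stop("model index out of range: file has ", n_models, " model(s)")
    }
    if (model > 1L) {
      xyz <- matrix(p$xyz[model, ], ncol = 3, byrow = TRUE)
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    }
    charge <- suppressWarnings(as.numeric(at$charge))
    radius <- rep(NA_real_, nrow(at))
    occupancy <- ifelse(is.na(at$o), 1, at$o)
    bfactor <- at$b
  }

  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  miss <- is.na(element) | element == ""
  element[miss] <- guess_element(at$elety[miss])

  atoms <- data.frame(
    type = at$type,
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = toupper(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = occupancy,
    bfactor = bfactor,
    element = element,
    charge = charge,
    radius = radius,
    potential = NA_real_,
    stringsAsFactors = FALSE
  )

  if (altloc != "all") {
    atoms <- resolve_altlocs(atoms, policy = altloc)
  }
  new_structure(id, atoms, source = path)
}

# element symbol from the atom name, PDB convention (digit-stripped lead char;
# two-letter cases among standard protein/solvent atoms are rare enough that
# the leading letter suffices for heavy-atom vs hydrogen decisions)
guess_element <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  toupper(substr(stripped, 1, 1))
}

resolve_altlocs <- function(atoms, policy = "occupancy") {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  ord <- switch(policy,
    occupancy = order(key, -atoms$occupancy, seq_len(nrow(atoms))),
    first = order(key, seq_len(nrow(atoms))))
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at the PDB format's 3-decimal precision.
#'
#' @param s a `decaaf_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resname,
                   eleno = a$serial, elety = a$name,
                   chain = ifelse(a$chain == "", " ", a$chain),
                   insert = ifelse(a$insert == "", "", a$insert),
                   o = a$occupancy,
                   b = ifelse(is.na(a$bfactor), 0, a$bfactor),
                   elesy = a$element)
  invisible(path)
}

#' Residue table of a structure
#'
#' @param s a `decaaf_structure`.
#' @return Data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, `label` (e.g. `"Ser195"`), `is_water`, `n_atoms`, in file
#'   order.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resname = a$resname[first],
                    stringsAsFactors = FALSE)
  out$label <- residue_label(out$resname, out$resno, out$insert)
  out$is_water <- is_water(out$resname)
  out$n_atoms <- as.vector(table(factor(key, levels = key[first])))
  rownames(out) <- NULL
  out
}

#' Human-readable residue label, e.g. "Ser195" or "HOH2076"
#'
#' @param resname,resno,insert residue name, number, insertion code.
#' @return Character vector of labels.
#' @export
residue_label <- function(resname, resno, insert = "") {
  nm <- ifelse(is_water(resname), toupper(resname),
               paste0(toupper(substr(resname, 1, 1)),
                      tolower(substr(resname, 2, nchar(resname)))))
  paste0(nm, resno, ifelse(is.na(insert) | insert == "", "", insert))
}

#' Is a residue (name) a water?
#'
#' @param resname residue name(s).
#' @param water_names residue names treated as water.
#' @return Logical vector.
#' @export
is_water <- function(resname, water_names = c("HOH", "WAT", "DOD")) {
  toupper(resname) %in% water_names
}

# rows of s$atoms belonging to one residue; chain = NULL matches any chain but
# must be unambiguous
residue_rows <- function(s, resno, chain = NULL, insert = "") {
  a <- s$atoms
  sel <- a$resno == resno & a$insert == (insert %||% "")
  if (!is.null(chain)) sel <- sel & a$chain == chain
  idx <- which(sel)
  if (length(idx) == 0) {
    stop("residue ", resno, if (!is.null(chain)) paste0(" (chain ", chain, ")"),
         " not found in structure '", s$id, "'")
  }
  chains <- unique(a$chain[idx])
  if (is.null(chain) && length(chains) > 1) {
    stop("residue ", resno, " is ambiguous across chains ",
         paste(chains, collapse = ", "), "; specify a chain")
  }
  idx
}

#' Look up a single atom in a structure
#'
#' @param s a `decaaf_structure`.
#' @param resno residue number (author numbering).
#' @param atom atom name.
#' @param chain chain identifier, or `NULL` if unambiguous.
#' @param insert insertion code.
#' @return One-row data frame (a slice of `s$atoms`).
#' @export
get_atom <- function(s, resno, atom, chain = NULL, insert = "") {
  idx <- residue_rows(s, resno, chain, insert)
  hit <- idx[s$atoms$name[idx] == atom]
  if (length(hit) == 0) {
    stop("atom ", atom, " not found in residue ",
         residue_label(s$atoms$resname[idx[1]], resno, insert),
         " of '", s$id, "' (side chain incomplete?)")
  }
  out <- s$atoms[hit[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reactive atom of a residue
#'
#' Resolves the residue's single reactive atom via the map (see
#' [default_reactive_atoms()]); an explicit `override` atom name wins over the
#' map. Deterministic and independent of atom order within the residue.
#'
#' @inheritParams get_atom
#' @param map residue-to-atom map.
#' @param override atom name overriding the map (e.g. backbone `"N"`), or
#'   `NULL`.
#' @return One-row data frame describing the atom, with a `label` attribute
#'   such as `"Ser195/OG"`.
#' @export
get_reactive_atom <- function(s, resno, chain = NULL, insert = "",
                              map = default_reactive_atoms(),
                              override = NULL) {
  idx <- residue_rows(s, resno, chain, insert)
  resname <- s$atoms$resname[idx[1]]
  atom <- if (!is.null(override)) override else reactive_atom_name(resname, map)
  out <- get_atom(s, resno, atom, chain = s$atoms$chain[idx[1]],
                  insert = insert)
  attr(out, "label") <- paste0(residue_label(resname, resno, insert), "/", atom)
  out
}

atom_coord <- function(atom_row) {
  as.numeric(atom_row[1, c("x", "y", "z")])
}

coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
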