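# Template motifs and partial-motif libraries.
#
# A template motif is an ordered set of N >= 3 active-site positions, each
# represented by one reactive atom, with reference pairwise distances and
# (optionally) reference pairwise potential differences. Partial motifs are
# order-preserved k-subsets; the library of all size-k subsets drives the
# scaffold scan.

#' Build a template motif from active-site residues
#'
#' Reference pairwise distances between reactive atoms are computed
#' immediately; reference potential differences are computed if a potential
#' source is given, stored in position order (earlier position minus later).
#'
#' @param s template `decaaf_structure`.
#' @param positions data frame with one row per motif position: column
#'   `resno` (required) and optional `chain`, `insert`, `atom` (override of
#'   the reactive-atom map, e.g. backbone `"N"`), `allowed`
#'   (comma-separated extra residue types allowed at the position).
#' @param map residue-to-reactive-atom map.
#' @param potentials a `potential_source`, or `NULL` to skip potentials.
#' @return A `decaaf_motif`: positions table (with labels such as `"Ser195"`),
#'   per-position allowed-residue sets with their reactive atoms, reference
#'   coordinates, `ref_dist` (N x N, Angstrom) and `ref_pd` (N x N, kT/e, or
#'   `NULL`).
#' @examples
#' s <- anchor_fixture("hne_1b0f")
#' m <- build_template(s, data.frame(resno = c(195, 57, 214)))
#' round(m$ref_dist, 1)
#' @export
build_template <- function(s, positions, map = default_reactive_atoms(),
                           potentials = NULL) {
  stopifnot(is.data.frame(positions), "resno" %in% names(positions))
  n <- nrow(positions)
  if (n < 3) stop("a motif needs at least 3 positions")
  if (!is.null(potentials)) s <- assign_potentials(s, potentials)

  chain <- if ("chain" %in% names(positions)) positions$chain else rep(NA, n)
  insert <- if ("insert" %in% names(positions)) positions$insert else rep("", n)
  override <- if ("atom" %in% names(positions)) positions$atom else rep(NA, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- if (is.na(chain[i])) NULL else chain[i]
    ov <- if (is.na(override[i]) || override[i] == "") NULL else override[i]
    rows[[i]] <- get_reactive_atom(s, positions$resno[i], chain = ch,
                                   insert = insert[i] %||% "",
                                   map = map, override = ov)
  }
  pos <- data.frame(
    label = vapply(rows, function(r) residue_label(r$resname, r$resno,
                                                   r$insert), character(1)),
    chain = vapply(rows, function(r) r$chain, character(1)),
    resno = vapply(rows, function(r) r$resno, numeric(1)),
    insert = vapply(rows, function(r) r$insert, character(1)),
    resname = vapply(rows, function(r) r$resname, character(1)),
    atom = vapply(rows, function(r) r$name, character(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(pos$label)) stop("duplicate motif positions")

  allowed <- vector("list", n)
  names(allowed) <- pos$label
  for (i in seq_len(n)) {
    al <- stats::setNames(pos$atom[i], pos$resname[i])
    extra <- if ("allowed" %in% names(positions)) positions$allowed[i] else NA
    if (!is.na(extra) && nzchar(extra)) {
      ex <- toupper(trimws(strsplit(extra, ",")[[1]]))
      ex <- setdiff(ex, pos$resname[i])
      al <- c(al, stats::setNames(reactive_atom_name(ex, map), ex))
    }
    allowed[[i]] <- al
  }

  xyz <- t(vapply(rows, atom_coord, numeric(3)))
  ref_dist <- as.matrix(stats::dist(xyz))
  dimnames(ref_dist) <- list(pos$label, pos$label)

  ref_pd <- NULL
  if (!is.null(potentials)) {
    v <- vapply(rows, function(r) r$potential, numeric(1))
    if (anyNA(v)) stop("potential source did not cover all reactive atoms")
    ref_pd <- outer(v, v, "-")
    dimnames(ref_pd) <- dimnames(ref_dist)
  }

  structure(list(structure_id = s$id, positions = pos, allowed = allowed,
                 coords = xyz, ref_dist = ref_dist, ref_pd = ref_pd),
            class = "decaaf_motif")
}

#' @export
print.decaaf_motif <- function(x, ...) {
  cat(sprintf("motif from '%s' (%d positions): %s\n", x$structure_id,
              nrow(x$positions),
              paste(paste0(x$positions$label, "/", x$positions$atom),
                    collapse = ", ")))
  invisible(x)
}

#' Stereochemical equivalence presets
#'
#' Functionally interchangeable residue groups usable with
#' [expand_equivalence()]: hydroxyl/thiol nucleophiles, carboxylates, amides,
#' Gly/Ala via the backbone nitrogen, and side-chain cations. Off by default;
#' applied per position.
#'
#' @return Named list of character vectors of residue codes.
#' @export
equivalence_presets <- function() {
  list(nucleophile = c("SER", "THR", "TYR", "CYS"),
       carboxylate = c("ASP", "GLU"),
       amide = c("ASN", "GLN"),
       backbone_n = c("GLY", "ALA"),
       cation = c("LYS", "ARG"))
}

#' Allow stereochemically equivalent residues at a motif position
#'
#' Expands the set of residue types that may occupy a position (e.g. letting a
#' Ser position be matched by Tyr, or Gly by Ala via the backbone N). The
#' reactive atom of each added residue type comes from the map.
#'
#' @param m a `decaaf_motif`.
#' @param label position label (e.g. `"Ser214"`) or 1-based position index.
#' @param residues character vector of extra 3-letter residue codes, or the
#'   name of a preset from [equivalence_presets()].
#' @param map residue-to-reactive-atom map.
#' @return The motif with the expanded allowed set.
#' @examples
#' s <- anchor_fixture("hne_1b0f")
#' m <- build_template(s, data.frame(resno = c(195, 57, 214)))
#' m2 <- expand_equivalence(m, "Ser214", "TYR")
#' m2$allowed[["Ser214"]]
#' @export
expand_equivalence <- function(m, label, residues,
                               map = default_reactive_atoms()) {
  stopifnot(inherits(m, "decaaf_motif"))
  i <- if (is.numeric(label)) as.integer(label) else match(label, m$positions$label)
  if (is.na(i) || i < 1 || i > nrow(m$positions)) {
    stop("unknown motif position: ", label)
  }
  if (length(residues) == 1 && residues %in% names(equivalence_presets())) {
    residues <- equivalence_presets()[[residues]]
  }
  residues <- setdiff(toupper(residues), names(m$allowed[[i]]))
  if (length(residues)) {
    m$allowed[[i]] <- c(m$allowed[[i]],
                        stats::setNames(reactive_atom_name(residues, map),
                                        residues))
  }
  m
}

#' Enumerate partial motifs of size k
#'
#' All C(N, k) order-preserved k-subsets of the template positions, in
#' deterministic lexicographic order of position indices. Each partial motif
#' carries its parent's reference distances and potential differences
#' restricted to the subset (no recomputation).
#'
#' @param m a `decaaf_motif` with N positions.
#' @param k subset size, 3 <= k <= N.
#' @return List of `decaaf_partial_motif` objects.
#' @examples
#' s <- anchor_fixture("hne_1b0f")
#' m <- build_template(s, data.frame(resno = c(195, 57, 214)))
#' length(partial_motifs(m, 3))
#' @export
partial_motifs <- function(m, k) {
  stopifnot(inherits(m, "decaaf_motif"))
  n <- nrow(m$positions)
  if (k < 3 || k > n) stop("k must be between 3 and ", n)
  subsets <- utils::combn(n, k, simplify = FALSE)
  lapply(subsets, function(idx) partial_motif(m, idx))
}

#' Restrict a template motif to an ordered subset of positions
#'
#' @param m a `decaaf_motif`.
#' @param idx increasing integer vector of position indices, length >= 3.
#' @return A `decaaf_partial_motif`: list with `parent`, `idx`, and the
#'   restricted `positions`, `allowed`, `ref_dist`, `ref_pd`.
#' @export
partial_motif <- function(m, idx) {
  idx <- as.integer(idx)
  stopifnot(length(idx) >= 3, !is.unsorted(idx, strictly = TRUE),
            all(idx >= 1), all(idx <= nrow(m$positions)))
  structure(list(parent = m, idx = idx,
                 positions = m$positions[idx, , drop = FALSE],
                 allowed = m$allowed[idx],
                 ref_dist = m$ref_dist[idx, idx, drop = FALSE],
                 ref_pd = if (is.null(m$ref_pd)) NULL
                          else m$ref_pd[idx, idx, drop = FALSE]),
            class = "decaaf_partial_motif")
}

#' @export
print.decaaf_partial_motif <- function(x, ...) {
  cat(sprintf("partial motif (k=%d): %s\n", length(x$idx),
              paste(x$positions$label, collapse = ", ")))
  invisible(x)
}

#' Read a motif definition file (YAML)
#'
#' The file holds a `positions` list with one entry per motif position:
#' `resno` (required), optional `chain`, `insert`, `atom` and `allowed` (list
#' of extra residue types).
#'
#' @param path YAML file path.
#' @return Positions data frame for [build_template()].
#' @export
read_motif_file <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$positions %||% y
  pos <- do.call(rbind, lapply(entries, function(e) {
    data.frame(resno = e$resno,
               chain = e$chain %||% NA_character_,
               insert = e$insert %||% "",
               atom = e$atom %||% NA_character_,
               allowed = paste(unlist(e$allowed %||% character(0)),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(pos) <- NULL
  pos
}

# labels "ab", "ac", ... for pairs of k positions, paper table style
pair_labels <- function(k) {
  cmb <- utils::combn(k, 2)
  apply(cmb, 2, function(p) paste0(letters[p[1]], letters[p[2]]))
}
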