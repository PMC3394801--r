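# End-to-end runs and tab-separated report writers mirroring the published
# table layouts: a rank table (id, description, DScore) and a per-motif
# best-match detail table (assignment, pairwise distance deviations, pairwise
# potential differences, score).

#' Scan a set of targets with a partial-motif library and write rank tables
#'
#' Builds the template motif, enumerates the size-`k` partial-motif library,
#' ranks every target by DScore and (optionally) writes two TSV files:
#' `<out_prefix>_ranks.tsv` and `<out_prefix>_details.tsv`.
#'
#' @param template a `decaaf_structure` or path to the template PDB/PQR.
#' @param positions motif positions data frame (see [build_template()]) or
#'   path to a motif YAML file (see [read_motif_file()]).
#' @param targets list of `decaaf_structure`s, a character vector of structure
#'   file paths, or a directory containing `.pdb`/`.pqr` files.
#' @param k partial motif size.
#' @param cfg a [scan_config()].
#' @param potentials optional `potential_source` applied to template and all
#'   targets (sets `cfg$use_potentials`).
#' @param out_prefix output path prefix, or `NULL` to skip writing.
#' @param header write a provenance header (`# key: value` comment lines) in
#'   the TSVs.
#' @param digits decimal places in the written tables (`NULL` = full
#'   precision).
#' @return The `decaaf_dscore_table`, invisibly when writing.
#' @export
run_scan <- function(template, positions, targets, k = 3,
                     cfg = scan_config(), potentials = NULL,
                     out_prefix = NULL, header = TRUE, digits = 1) {
  if (is.character(template)) template <- read_structure(template)
  if (is.character(positions)) positions <- read_motif_file(positions)
  targets <- load_target_set(targets)
  if (!is.null(potentials)) {
    cfg$use_potentials <- TRUE
    targets <- lapply(targets, assign_potentials, src = potentials)
  }
  m <- build_template(template, positions, potentials = potentials)
  library <- partial_motifs(m, k)
  tab <- rank_targets(targets, library, cfg)

  if (!is.null(out_prefix)) {
    hdr <- if (header) scan_header(m, k, cfg) else character(0)
    write_tsv(format_ranks(tab, digits), paste0(out_prefix, "_ranks.tsv"), hdr)
    write_tsv(format_details(tab, library, digits),
              paste0(out_prefix, "_details.tsv"), hdr)
    return(invisible(tab))
  }
  tab
}

load_target_set <- function(targets) {
  if (is.character(targets) && length(targets) == 1 && dir.exists(targets)) {
    targets <- list.files(targets, pattern = "\\.(pdb|pqr|ent)$",
                          full.names = TRUE, ignore.case = TRUE)
    if (length(targets) == 0) stop("no structure files in target directory")
  }
  if (is.character(targets)) {
    missing <- targets[!file.exists(targets)]
    if (length(missing)) stop("target file(s) not found: ",
                              paste(missing, collapse = ", "))
    targets <- lapply(targets, read_structure)
  }
  stopifnot(length(targets) >= 1,
            all(vapply(targets, inherits, logical(1), "decaaf_structure")))
  if (is.null(names(targets))) {
    names(targets) <- vapply(targets, `[[`, character(1), "id")
  }
  targets
}

scan_header <- function(m, k, cfg) {
  c(sprintf("# template: %s", m$structure_id),
    sprintf("# motif: %s", paste(paste0(m$positions$label, "/",
                                        m$positions$atom), collapse = ", ")),
    sprintf("# k: %d", k),
    sprintf("# distance_window: %g  d_weight: %g  pd_weight: %g  pd_floor: %g",
            cfg$distance_window, cfg$d_weight, cfg$pd_weight, cfg$pd_floor),
    sprintf("# use_potentials: %s  penalty: %g", cfg$use_potentials,
            cfg$penalty))
}

format_ranks <- function(tab, digits) {
  out <- as.data.frame(tab)
  if (!is.null(digits)) out$dscore <- round(out$dscore, digits + 2)
  out
}

format_details <- function(tab, library, digits) {
  details <- attr(tab, "details")
  rows <- list()
  for (id in names(details)) {
    for (mi in seq_along(library)) {
      b <- details[[id]][[mi]]
      motif_lab <- paste(library[[mi]]$positions$label, collapse = "+")
      if (is.null(b)) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = id, motif = motif_lab, assignment = "",
          pair = "", dev_d = NA_real_, dev_pd = NA_real_,
          score = NA_real_, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          target = id, motif = motif_lab,
          assignment = paste(b$assignment$residue, collapse = "+"),
          pair = names(b$dev_d),
          dev_d = unname(b$dev_d),
          dev_pd = if (is.null(b$dev_pd)) NA_real_ else unname(b$dev_pd),
          score = b$score, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    out$dev_d <- round(out$dev_d, digits)
    out$dev_pd <- round(out$dev_pd, digits)
    out$score <- round(out$score, digits + 2)
  }
  out
}

write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Superpose two structures on anchor residues and write the results
#'
#' Resolves the anchor reactive atoms, superposes via [superpose_pair()], and
#' (optionally) writes both transformed structures as PDB plus a TSV summary
#' with the before/after coordinate block and anchor residuals.
#'
#' @param template,target `decaaf_structure`s or file paths.
#' @param t_positions,g_positions data frames with >= 3 rows (`resno`,
#'   optional `chain`, `insert`, `atom` override); the first three rows are
#'   the anchors.
#' @param out_prefix output prefix (`<prefix>_template.pdb`,
#'   `<prefix>_target.pdb`, `<prefix>_summary.tsv`), or `NULL` to skip
#'   writing.
#' @param map residue-to-reactive-atom map.
#' @param digits decimal places in the written summary.
#' @return The [superpose_pair()] result, invisibly when writing.
#' @export
run_superpose <- function(template, t_positions, target, g_positions,
                          out_prefix = NULL, map = default_reactive_atoms(),
                          digits = 1) {
  if (is.character(template)) template <- read_structure(template)
  if (is.character(target)) target <- read_structure(target)
  stopifnot(nrow(t_positions) >= 3, nrow(g_positions) >= 3)
  t_anchors <- resolve_anchor_list(template, t_positions[1:3, , drop = FALSE],
                                   map)
  g_anchors <- resolve_anchor_list(target, g_positions[1:3, , drop = FALSE],
                                   map)
  sp <- superpose_pair(template, t_anchors, target, g_anchors)
  if (!is.null(out_prefix)) {
    write_structure(sp$template, paste0(out_prefix, "_template.pdb"))
    write_structure(sp$target, paste0(out_prefix, "_target.pdb"))
    summ <- sp$summary
    if (!is.null(digits)) {
      num <- vapply(summ, is.numeric, logical(1)) &
        names(summ) != "anchor"
      summ[num] <- lapply(summ[num], round, digits)
    }
    write_tsv(summ, paste0(out_prefix, "_summary.tsv"))
    return(invisible(sp))
  }
  sp
}

resolve_anchor_list <- function(s, positions, map) {
  lapply(seq_len(nrow(positions)), function(i) {
    ch <- if ("chain" %in% names(positions) && !is.na(positions$chain[i]))
      positions$chain[i] else NULL
    ov <- if ("atom" %in% names(positions) && !is.na(positions$atom[i]) &&
              nzchar(positions$atom[i])) positions$atom[i] else NULL
    get_reactive_atom(s, positions$resno[i], chain = ch,
                      insert = if ("insert" %in% names(positions))
                        positions$insert[i] %||% "" else "",
                      map = map, override = ov)
  })
}
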