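# Congruence matching of partial motifs in target structures.
#
# A candidate match assigns to each motif position a distinct target residue
# whose type is in the position's allowed set, represented by that type's
# reactive atom. Candidates are built position by position with incremental
# distance pruning: a new atom is accepted only if every pairwise distance to
# the atoms already placed deviates from the reference by at most the
# distance window. Survivors are scored by normalized mean deviation; lower
# is better and 0 means perfect spatial (and electrostatic) congruence.

#' Scan configuration
#'
#' @param distance_window prune candidates with any pairwise absolute distance
#'   deviation above this, Angstrom. The default (2.5) comfortably admits the
#'   largest deviation ever accepted in a worked example (1.9).
#' @param d_weight,pd_weight dimensionless weights of the distance and
#'   potential-difference terms; not both zero.
#' @param pd_floor kT/e floor on the reference potential difference used to
#'   normalize the electrostatic term, guarding near-zero references.
#' @param max_results keep at most this many matches per motif.
#' @param use_potentials compare potential differences as well as distances
#'   (requires potentials on both template motif and target).
#' @param penalty score charged for a motif with no surviving match when
#'   aggregating into a DScore.
#' @return A `scan_config` list.
#' @export
scan_config <- function(distance_window = 2.5, d_weight = 1, pd_weight = 1,
                        pd_floor = 10, max_results = 100,
                        use_potentials = FALSE, penalty = 1) {
  stopifnot(distance_window > 0, d_weight >= 0, pd_weight >= 0,
            d_weight + pd_weight > 0, pd_floor > 0, max_results >= 1,
            penalty >= 0)
  structure(list(distance_window = distance_window, d_weight = d_weight,
                 pd_weight = pd_weight, pd_floor = pd_floor,
                 max_results = max_results, use_potentials = use_potentials,
                 penalty = penalty),
            class = "scan_config")
}

#' Congruence score of a set of pairwise deviations
#'
#' `score = (1/P) * sum_pairs [ d_weight*|dd|/d_ref +
#' pd_weight*|dpd|/max(|pd_ref|, pd_floor) ]` over the P = k(k-1)/2 position
#' pairs. Zero iff every deviation is zero; monotone non-decreasing in each
#' absolute deviation.
#'
#' @param dev_d vector of distance deviations (reference minus target),
#'   Angstrom, one per pair.
#' @param ref_d vector of reference distances, Angstrom.
#' @param dev_pd,ref_pd optional vectors of potential-difference deviations
#'   and references, kT/e.
#' @param cfg a [scan_config()].
#' @return Non-negative scalar score.
#' @examples
#' congruence_score(c(0.1, 0.2, 0.3), c(5, 6.8, 4.7),
#'                  cfg = scan_config(pd_weight = 0))
#' @export
congruence_score <- function(dev_d, ref_d, dev_pd = NULL, ref_pd = NULL,
                             cfg = scan_config()) {
  stopifnot(length(dev_d) == length(ref_d))
  term <- cfg$d_weight * abs(dev_d) / ref_d
  if (!is.null(dev_pd)) {
    stopifnot(length(dev_pd) == length(ref_pd))
    term <- term + cfg$pd_weight * abs(dev_pd) / pmax(abs(ref_pd), cfg$pd_floor)
  }
  mean(term)
}

# per-position candidate atoms in a target structure: one row per (residue,
# allowed type) whose reactive atom exists
candidate_atoms <- function(pm, target) {
  a <- target$atoms
  lapply(seq_along(pm$allowed), function(i) {
    al <- pm$allowed[[i]]
    hits <- lapply(seq_along(al), function(j) {
      sel <- a$resname == names(al)[j] & a$name == unname(al[j])
      a[sel, c("chain", "resno", "insert", "resname", "name",
               "x", "y", "z", "potential"), drop = FALSE]
    })
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out
  })
}

#' Find congruent matches of a partial motif in a target structure
#'
#' @param pm a `decaaf_partial_motif` (or full `decaaf_motif`).
#' @param target a `decaaf_structure`; must carry potentials if
#'   `cfg$use_potentials`.
#' @param cfg a [scan_config()].
#' @return A `decaaf_matches` list, ascending by score (ties broken by residue
#'   numbers), truncated at `cfg$max_results`. Each match has `assignment`
#'   (data frame: position label, target residue label, chain, resno,
#'   resname, atom), `dev_d` and (if used) `dev_pd` named by pair (`"ab"`,
#'   `"ac"`, ...), and `score`. Empty list when no candidate survives.
#' @export
find_matches <- function(pm, target, cfg = scan_config()) {
  if (inherits(pm, "decaaf_motif")) pm <- partial_motif(pm, seq_len(nrow(pm$positions)))
  stopifnot(inherits(pm, "decaaf_partial_motif"),
            inherits(target, "decaaf_structure"))
  k <- nrow(pm$positions)
  use_pd <- isTRUE(cfg$use_potentials)
  if (use_pd && is.null(pm$ref_pd)) {
    stop("cfg$use_potentials is TRUE but the motif has no reference ",
         "potential differences")
  }
  cand <- candidate_atoms(pm, target)
  if (any(vapply(cand, nrow, integer(1)) == 0)) {
    return(empty_matches(pm, target))
  }
  if (use_pd && anyNA(unlist(lapply(cand, `[[`, "potential")))) {
    stop("target potentials not assigned for all candidate reactive atoms")
  }

  ref <- pm$ref_dist
  win <- cfg$distance_window
  results <- list()

  # depth-first assembly with incremental pruning
  assign_next <- function(level, chosen_rows, chosen_keys) {
    cc <- cand[[level]]
    for (r in seq_len(nrow(cc))) {
      key <- paste(cc$chain[r], cc$resno[r], cc$insert[r], sep = "\r")
      if (key %in% chosen_keys) next
      ok <- TRUE
      for (p in seq_len(level - 1)) {
        prev <- chosen_rows[[p]]
        d <- sqrt((prev$x - cc$x[r])^2 + (prev$y - cc$y[r])^2 +
                  (prev$z - cc$z[r])^2)
        if (abs(ref[p, level] - d) > win) { ok <- FALSE; break }
      }
      if (!ok) next
      rows2 <- c(chosen_rows, list(cc[r, , drop = FALSE]))
      if (level == k) {
        results[[length(results) + 1L]] <<- score_assignment(pm, rows2, cfg)
      } else {
        assign_next(level + 1L, rows2, c(chosen_keys, key))
      }
    }
  }
  assign_next(1L, list(), character(0))

  if (length(results) == 0) return(empty_matches(pm, target))
  scores <- vapply(results, `[[`, numeric(1), "score")
  tiebreak <- vapply(results, function(m) {
    paste(sprintf("%s%09d%s", m$assignment$chain, m$assignment$resno,
                  m$assignment$insert), collapse = "|")
  }, character(1))
  ord <- order(scores, tiebreak)
  results <- results[ord][seq_len(min(length(results), cfg$max_results))]
  structure(results, class = "decaaf_matches",
            motif = pm, target_id = target$id)
}

empty_matches <- function(pm, target) {
  structure(list(), class = "decaaf_matches", motif = pm,
            target_id = target$id)
}

score_assignment <- function(pm, rows, cfg) {
  k <- length(rows)
  xyz <- t(vapply(rows, function(r) c(r$x, r$y, r$z), numeric(3)))
  labs <- pair_labels(k)
  cmb <- utils::combn(k, 2)
  tgt_d <- apply(cmb, 2, function(p) sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2)))
  ref_d <- apply(cmb, 2, function(p) pm$ref_dist[p[1], p[2]])
  dev_d <- stats::setNames(ref_d - tgt_d, labs)

  dev_pd <- NULL; ref_pd <- NULL
  if (isTRUE(cfg$use_potentials)) {
    v <- vapply(rows, function(r) r$potential, numeric(1))
    tgt_pd <- apply(cmb, 2, function(p) v[p[1]] - v[p[2]])
    ref_pd <- stats::setNames(apply(cmb, 2, function(p) pm$ref_pd[p[1], p[2]]),
                              labs)
    dev_pd <- stats::setNames(ref_pd - tgt_pd, labs)
  }

  assignment <- do.call(rbind, rows)
  assignment <- data.frame(
    position = pm$positions$label,
    residue = residue_label(assignment$resname, assignment$resno,
                            assignment$insert),
    chain = assignment$chain, resno = assignment$resno,
    insert = assignment$insert, resname = assignment$resname,
    atom = assignment$name, stringsAsFactors = FALSE)

  list(assignment = assignment, dev_d = dev_d,
       ref_d = stats::setNames(ref_d, labs),
       dev_pd = dev_pd, ref_pd = ref_pd,
       score = congruence_score(dev_d, ref_d, dev_pd, ref_pd, cfg))
}

#' @export
print.decaaf_matches <- function(x, ...) {
  pm <- attr(x, "motif")
  cat(sprintf("%d match(es) of (%s) in '%s'\n", length(x),
              paste(pm$positions$label, collapse = ", "),
              attr(x, "target_id")))
  if (length(x)) {
    best <- x[[1]]
    cat("best:", paste(best$assignment$residue, collapse = ", "),
        sprintf(" score %.4g\n", best$score))
  }
  invisible(x)
}

#' Cumulative per-protein score over a motif library (DScore)
#'
#' Mean over the size-k motif library of each motif's best match score, with
#' unmatched motifs charged the penalty. Lower is better; 0 means every motif
#' is matched perfectly. Never compared across different k.
#'
#' @param best_scores numeric vector, one per motif in the library; `NA` for
#'   motifs with no surviving match.
#' @param penalty score substituted for `NA` entries.
#' @return Scalar DScore.
#' @examples
#' dscore(c(rep(0.02, 9), NA), penalty = 1)
#' @export
dscore <- function(best_scores, penalty = 1) {
  if (length(best_scores) == 0) stop("empty motif library")
  best_scores[is.na(best_scores)] <- penalty
  mean(best_scores)
}

#' Rank target structures by cumulative congruence with a motif library
#'
#' Runs [find_matches()] for every (motif, target) pair and aggregates each
#' target's best scores into a DScore via [dscore()].
#'
#' @param targets list of `decaaf_structure` objects (optionally named; names
#'   default to structure ids).
#' @param library list of partial motifs of a single size k, e.g. from
#'   [partial_motifs()].
#' @param cfg a [scan_config()].
#' @param descriptions optional character vector of per-target descriptions.
#' @return A `decaaf_dscore_table` data frame (`id`, `description`, `dscore`)
#'   sorted ascending by dscore, ties broken by id. The per-target best
#'   matches are attached as attribute `"details"`.
#' @export
rank_targets <- function(targets, library, cfg = scan_config(),
                         descriptions = NULL) {
  stopifnot(length(targets) >= 1, length(library) >= 1)
  ids <- names(targets)
  if (is.null(ids)) ids <- vapply(targets, `[[`, character(1), "id")
  if (is.null(descriptions)) descriptions <- rep("", length(targets))

  details <- vector("list", length(targets))
  names(details) <- ids
  ds <- numeric(length(targets))
  for (t in seq_along(targets)) {
    best <- lapply(library, function(pm) {
      mm <- find_matches(pm, targets[[t]], cfg)
      if (length(mm)) mm[[1]] else NULL
    })
    scores <- vapply(best, function(b) if (is.null(b)) NA_real_ else b$score,
                     numeric(1))
    ds[t] <- dscore(scores, cfg$penalty)
    details[[t]] <- best
  }
  out <- data.frame(id = ids, description = descriptions, dscore = ds,
                    stringsAsFactors = FALSE)
  out <- out[order(out$dscore, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decaaf_dscore_table", "data.frame")
  attr(out, "details") <- details
  out
}
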