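# Canonical-frame superposition, steric neighborhoods, mutation suggestions.
#
# The superposition is the exact three-anchor frame construction, not a
# least-squares fit: each structure is rigidly moved so that its first anchor
# sits at the origin, its second on the +X axis, and its third in the Z = 0
# plane with positive Y. Superposing template and target each into their own
# canonical frame overlays the matched partial scaffolds.

#' Rigid transform taking three anchor atoms into the canonical frame
#'
#' Returns the unique proper rigid motion T with T(a) = (0,0,0), T(b) on the
#' +X axis, and T(c) in the Z = 0 plane with positive Y. Being proper (no
#' reflection), it preserves all distances and chirality.
#'
#' @param a,b,c 3-vectors (Angstrom): first, second and third anchor.
#' @return A `rigid_transform`: list with `rotation` (3 x 3 proper orthogonal
#'   matrix) and `translation` (3-vector), applying as `x' = R x + t`.
#' @examples
#' tf <- canonical_frame(c(64.4, 57, 53.8), c(63.3, 54.8, 58.2),
#'                       c(63.6, 50.6, 56.1))
#' round(apply_transform(c(63.3, 54.8, 58.2), tf), 1)
#' @export
canonical_frame <- function(a, b, c) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  stopifnot(length(a) == 3, length(b) == 3, length(c) == 3,
            all(is.finite(c(a, b, c))))
  u <- b - a
  v <- c - a
  nu <- sqrt(sum(u^2))
  w <- cross3(u, v)
  nw <- sqrt(sum(w^2))
  # smallest triangle height = 2*area / longest side; reject degenerate anchors
  sides <- c(nu, sqrt(sum(v^2)), sqrt(sum((c - b)^2)))
  if (min(sides) == 0 || nw / max(sides) < 1e-6) {
    stop("anchor atoms are collinear or coincident")
  }
  e1 <- u / nu
  e3 <- w / nw
  e2 <- cross3(e3, e1)
  r <- rbind(e1, e2, e3)
  dimnames(r) <- NULL
  structure(list(rotation = r, translation = as.vector(-r %*% a)),
            class = "rigid_transform")
}

cross3 <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

#' Apply a rigid transform
#'
#' @param x a 3-vector, an n x 3 coordinate matrix, or a `decaaf_structure`.
#' @param tf a `rigid_transform`.
#' @return The transformed object, same shape as the input.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "decaaf_structure")) {
    xyz <- apply_transform(coords(x), tf)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  if (is.matrix(x)) {
    return(sweep(x %*% t(tf$rotation), 2, tf$translation, "+"))
  }
  as.vector(tf$rotation %*% as.numeric(x)) + tf$translation
}

#' Superimpose template and target on a three-atom partial match
#'
#' Both whole structures are moved into their own canonical frames (see
#' [canonical_frame()]), so the first anchor pair coincides at the origin and
#' the matched partial scaffolds overlay. The anchors always superpose up to
#' the residual shape difference of the two triangles; the summary reports the
#' residual anchor-pair distances so geometric strain is visible.
#'
#' @param template,target `decaaf_structure` objects.
#' @param t_anchors,g_anchors anchors in the template and target: a list of
#'   three one-row atom data frames (e.g. from [get_reactive_atom()]) or a
#'   3 x 3 coordinate matrix (rows = anchors).
#' @return List with `template` and `target` (transformed structures),
#'   `t_transform`, `g_transform`, and `summary`: a data frame with one row
#'   per anchor giving structure, label, before/after coordinates and the
#'   residual distance between the paired anchors after superposition.
#' @export
superpose_pair <- function(template, t_anchors, target, g_anchors) {
  t_xyz <- anchor_coords(t_anchors)
  g_xyz <- anchor_coords(g_anchors)
  t_tf <- canonical_frame(t_xyz[1, ], t_xyz[2, ], t_xyz[3, ])
  g_tf <- canonical_frame(g_xyz[1, ], g_xyz[2, ], g_xyz[3, ])
  t_after <- apply_transform(t_xyz, t_tf)
  g_after <- apply_transform(g_xyz, g_tf)
  residual <- sqrt(rowSums((t_after - g_after)^2))

  summary <- data.frame(
    structure = rep(c(template$id, target$id), each = 3),
    anchor = rep(1:3, 2),
    label = c(anchor_labels(t_anchors), anchor_labels(g_anchors)),
    before_x = c(t_xyz[, 1], g_xyz[, 1]),
    before_y = c(t_xyz[, 2], g_xyz[, 2]),
    before_z = c(t_xyz[, 3], g_xyz[, 3]),
    after_x = c(t_after[, 1], g_after[, 1]),
    after_y = c(t_after[, 2], g_after[, 2]),
    after_z = c(t_after[, 3], g_after[, 3]),
    residual = rep(residual, 2),
    stringsAsFactors = FALSE
  )
  list(template = apply_transform(template, t_tf),
       target = apply_transform(target, g_tf),
       t_transform = t_tf, g_transform = g_tf, summary = summary)
}

anchor_coords <- function(anchors) {
  if (is.matrix(anchors)) {
    stopifnot(nrow(anchors) == 3, ncol(anchors) == 3)
    return(anchors)
  }
  stopifnot(is.list(anchors), length(anchors) == 3)
  t(vapply(anchors, atom_coord, numeric(3)))
}

anchor_labels <- function(anchors) {
  if (is.matrix(anchors)) return(paste0("anchor", 1:3))
  vapply(anchors, function(a) {
    attr(a, "label") %||% paste0(residue_label(a$resname, a$resno, a$insert),
                                 "/", a$name)
  }, character(1))
}

#' Sorted steric neighborhood of an atom or point
#'
#' Lists atoms within `radius` of the center, ascending by distance (ties
#' broken by residue number, then atom name). The center atom itself is listed
#' at distance 0. With `stop_at_water` the list is truncated immediately after
#' the first water atom encountered, mirroring how catalytic-cleft
#' accessibility is reported: solvent marks the open cleft.
#'
#' @param s a `decaaf_structure`.
#' @param resno,atom,chain,insert address of the center atom; alternatively
#'   give `point`.
#' @param point a 3-vector center (Angstrom); with `point`, `resno`/`chain`
#'   may still be given to name the center's own residue (used for
#'   self-exclusion in [steric_obstruction_compare()]).
#' @param radius cutoff, Angstrom.
#' @param stop_at_water truncate after the first water.
#' @param include_hydrogens include hydrogen atoms (default `FALSE`: reports
#'   list heavy atoms only).
#' @return A `neighbor_report`: data frame (`distance`, `residue`, `atom`,
#'   `chain`, `resno`, `insert`, `resname`, `is_water`) with attributes
#'   `center` (label), `center_residue` (chain/resno/insert or `NULL`) and
#'   `truncated`.
#' @export
neighbor_report <- function(s, resno = NULL, atom = NULL, chain = NULL,
                            insert = "", point = NULL, radius = 5,
                            stop_at_water = TRUE, include_hydrogens = FALSE) {
  stopifnot(radius > 0)
  center_res <- NULL
  if (is.null(point)) {
    if (is.null(resno) || is.null(atom)) {
      stop("give either (resno, atom) or point")
    }
    ctr_row <- get_atom(s, resno, atom, chain = chain, insert = insert)
    point <- atom_coord(ctr_row)
    center_res <- list(chain = ctr_row$chain, resno = ctr_row$resno,
                       insert = ctr_row$insert)
    center_label <- paste0(residue_label(ctr_row$resname, ctr_row$resno,
                                         ctr_row$insert), "/", ctr_row$name)
  } else {
    point <- as.numeric(point)
    stopifnot(length(point) == 3)
    if (!is.null(resno)) {
      center_res <- list(chain = chain %||% "", resno = resno,
                         insert = insert)
    }
    center_label <- sprintf("point(%.1f, %.1f, %.1f)",
                            point[1], point[2], point[3])
  }

  a <- s$atoms
  if (!include_hydrogens) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  d <- sqrt((a$x - point[1])^2 + (a$y - point[2])^2 + (a$z - point[3])^2)
  keep <- d <= radius
  a <- a[keep, , drop = FALSE]
  d <- d[keep]
  # ties at the coordinate precision break by residue number, then atom name
  ord <- order(round(d, 6), a$resno, a$name)
  a <- a[ord, , drop = FALSE]
  d <- d[ord]

  wat <- is_water(a$resname)
  truncated <- FALSE
  if (stop_at_water && any(wat)) {
    first <- which(wat)[1]
    if (first < length(d)) truncated <- TRUE
    a <- a[seq_len(first), , drop = FALSE]
    d <- d[seq_len(first)]
    wat <- wat[seq_len(first)]
  }

  out <- data.frame(distance = d,
                    residue = residue_label(a$resname, a$resno, a$insert),
                    atom = a$name, chain = a$chain, resno = a$resno,
                    insert = a$insert, resname = a$resname,
                    is_water = wat, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("neighbor_report", "data.frame"),
            center = center_label, center_residue = center_res,
            truncated = truncated, radius = radius)
}

#' @export
print.neighbor_report <- function(x, ...) {
  cat("atoms within", attr(x, "radius"), "A of", attr(x, "center"),
      if (attr(x, "truncated")) "(truncated at first water)", "\n")
  print.data.frame(cbind(D = round(x$distance, 1),
                         x[, c("residue", "atom")]), row.names = FALSE)
  invisible(x)
}

#' Compare steric obstruction across superposed sites
#'
#' For each neighbor report around a cognate catalytic atom, counts heavy
#' atoms of *other* residues (the center's own residue and waters excluded)
#' within the clearance radius; any such foreign atom flags the site as
#' sterically obstructed.
#'
#' @param reports list of [neighbor_report()] objects (named or not).
#' @param clearance_radius Angstrom; the classic open-cleft criterion is about
#'   3.
#' @return Data frame with `center`, `n_foreign`, `obstructed`, and the
#'   foreign residue labels found.
#' @export
steric_obstruction_compare <- function(reports, clearance_radius = 3) {
  stopifnot(length(reports) >= 1)
  rows <- lapply(reports, function(rp) {
    cr <- attr(rp, "center_residue")
    foreign <- rp$distance > 0 & rp$distance <= clearance_radius & !rp$is_water
    if (!is.null(cr)) {
      own <- rp$resno == cr$resno & rp$insert == (cr$insert %||% "") &
        (cr$chain %||% "" == "" | rp$chain == cr$chain)
      foreign <- foreign & !own
    }
    data.frame(center = attr(rp, "center"),
               n_foreign = sum(foreign),
               obstructed = any(foreign),
               foreign_residues = paste(unique(rp$residue[foreign]),
                                        collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(reports))) out$center <- names(reports)
  rownames(out) <- NULL
  out
}

#' Propose mutations replicating unmatched template residues
#'
#' After superposition, each unmatched template motif residue's reactive atom
#' marks where the missing catalytic group should sit. Target residues
#' (waters and already-matched residues excluded) with any heavy atom within
#' `cutoff` of that position are candidates for substitution by the template
#' residue's type.
#'
#' @param template,target superposed `decaaf_structure` objects (e.g. the
#'   `$template`/`$target` of [superpose_pair()]).
#' @param unmatched data frame of unmatched template residues: column `resno`,
#'   optional `chain`, `insert`, `atom` (reactive-atom override).
#' @param matched_target optional data frame (`resno`, optional `chain`,
#'   `insert`) of target residues already in the partial match, to exclude.
#' @param cutoff candidate distance, Angstrom.
#' @param map residue-to-reactive-atom map.
#' @return List of `mutation_suggestion` objects, one per unmatched residue:
#'   each has `template_residue`, `template_atom`, and `candidates` (data
#'   frame `residue`, `chain`, `resno`, `resname`, `closest_atom`, `distance`,
#'   `substitution` such as `"Asn35Asp"`), sorted by distance.
#' @export
suggest_mutations <- function(template, target, unmatched,
                              matched_target = NULL, cutoff = 5,
                              map = default_reactive_atoms()) {
  stopifnot(is.data.frame(unmatched), "resno" %in% names(unmatched))
  ta <- target$atoms
  ta <- ta[!is_water(ta$resname) & !(ta$element %in% c("H", "D")), ,
           drop = FALSE]
  if (!is.null(matched_target)) {
    mk <- paste(if ("chain" %in% names(matched_target)) matched_target$chain
                else "", matched_target$resno,
                if ("insert" %in% names(matched_target)) matched_target$insert
                else "", sep = "\r")
    tk <- paste(ta$chain, ta$resno, ta$insert, sep = "\r")
    mk_any <- paste("", matched_target$resno, "", sep = "\r")
    tk_any <- paste("", ta$resno, ta$insert, sep = "\r")
    ta <- ta[!(tk %in% mk | tk_any %in% mk_any), , drop = FALSE]
  }

  lapply(seq_len(nrow(unmatched)), function(i) {
    ch <- if ("chain" %in% names(unmatched) && !is.na(unmatched$chain[i]))
      unmatched$chain[i] else NULL
    ov <- if ("atom" %in% names(unmatched) && !is.na(unmatched$atom[i]))
      unmatched$atom[i] else NULL
    tat <- get_reactive_atom(template, unmatched$resno[i], chain = ch,
                             map = map, override = ov)
    p <- atom_coord(tat)
    d <- sqrt((ta$x - p[1])^2 + (ta$y - p[2])^2 + (ta$z - p[3])^2)
    near <- d <= cutoff
    cand <- data.frame(chain = ta$chain[near], resno = ta$resno[near],
                       insert = ta$insert[near], resname = ta$resname[near],
                       atom = ta$name[near], distance = d[near],
                       stringsAsFactors = FALSE)
    # closest atom per residue
    cand <- cand[order(cand$distance), , drop = FALSE]
    key <- paste(cand$chain, cand$resno, cand$insert, sep = "\r")
    cand <- cand[!duplicated(key), , drop = FALSE]
    subs_to <- residue_label(tat$resname, 0)
    subs_to <- sub("0$", "", subs_to)  # bare title-case residue type
    cand_out <- data.frame(
      residue = residue_label(cand$resname, cand$resno, cand$insert),
      chain = cand$chain, resno = cand$resno, resname = cand$resname,
      closest_atom = cand$atom, distance = cand$distance,
      substitution = paste0(residue_label(cand$resname, cand$resno,
                                          cand$insert), subs_to),
      stringsAsFactors = FALSE)
    rownames(cand_out) <- NULL
    structure(list(template_residue = attr(tat, "label"),
                   template_atom = tat$name,
                   candidates = cand_out),
              class = "mutation_suggestion")
  })
}

#' @export
print.mutation_suggestion <- function(x, ...) {
  cat("unmatched template residue", x$template_residue, "-",
      nrow(x$candidates), "candidate(s)\n")
  if (nrow(x$candidates)) {
    print.data.frame(
      cbind(x$candidates[, c("substitution", "closest_atom")],
            D = round(x$candidates$distance, 1)), row.names = FALSE)
  }
  invisible(x)
}
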