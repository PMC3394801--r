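# Synthetic structures and potential sources, so every pipeline stage runs
# without downloads: minimal anchor fixtures with the published worked-example
# coordinates, planted-motif decoy structures with recorded ground truth, and
# a synthetic reconstruction of the published steric-neighborhood tables.

#' Build a structure from a data frame of atoms
#'
#' Convenience constructor for toy and generated structures.
#'
#' @param id structure id.
#' @param atoms data frame with columns `resname`, `resno`, `atom`, `x`, `y`,
#'   `z`; optional `chain` (default `"A"`), `insert`, `element`, `charge`.
#' @return A `decaaf_structure`.
#' @export
make_structure <- function(id, atoms) {
  stopifnot(all(c("resname", "resno", "atom", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  df <- data.frame(
    type = ifelse(is_water(atoms$resname), "HETATM", "ATOM"),
    serial = seq_len(n),
    name = atoms$atom,
    altloc = "",
    resname = toupper(atoms$resname),
    chain = if ("chain" %in% names(atoms)) atoms$chain else rep("A", n),
    resno = atoms$resno,
    insert = if ("insert" %in% names(atoms)) atoms$insert else rep("", n),
    x = atoms$x, y = atoms$y, z = atoms$z,
    occupancy = rep(1, n), bfactor = rep(0, n),
    element = if ("element" %in% names(atoms)) atoms$element
              else guess_element(atoms$atom),
    charge = if ("charge" %in% names(atoms)) atoms$charge else rep(NA_real_, n),
    radius = rep(NA_real_, n),
    potential = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  new_structure(id, df, source = "generated")
}

# published anchor coordinates of the elastase/P14A worked example
.anchor_data <- list(
  hne_1b0f = data.frame(
    resname = c("SER", "HIS", "SER"),
    resno = c(195, 57, 214),
    atom = c("OG", "ND1", "OG"),
    x = c(64.4, 63.3, 63.6), y = c(57.0, 54.8, 50.6),
    z = c(53.8, 58.2, 56.1), stringsAsFactors = FALSE),
  p14a_1cfe = data.frame(
    resname = c("SER", "HIS", "TYR"),
    resno = c(49, 48, 36),
    atom = c("OG", "ND1", "OH"),
    x = c(8.8, 9.2, 13.7), y = c(-6.3, -2.4, -1.6),
    z = c(-4.8, -1.8, -3.7), stringsAsFactors = FALSE)
)

#' Minimal anchor fixtures of the elastase/P14A worked example
#'
#' Three-residue structures holding exactly the published anchor reactive
#' atoms of the human neutrophil elastase (1B0F: Ser195/OG, His57/ND1,
#' Ser214/OG) and P14A (1CFE: Ser49/OG, His48/ND1, Tyr36/OH) partial match,
#' plus backbone N/CA stubs so each residue parses and writes as a valid PDB
#' residue.
#'
#' @param which `"hne_1b0f"` or `"p14a_1cfe"`.
#' @return A `decaaf_structure` with 3 residues.
#' @examples
#' s <- anchor_fixture("hne_1b0f")
#' get_reactive_atom(s, 195)
#' @export
anchor_fixture <- function(which = c("hne_1b0f", "p14a_1cfe")) {
  which <- match.arg(which)
  d <- .anchor_data[[which]]
  rows <- lapply(seq_len(nrow(d)), function(i) {
    # backbone stubs at fixed offsets from the reactive atom
    data.frame(resname = d$resname[i], resno = d$resno[i],
               atom = c("N", "CA", d$atom[i]),
               x = d$x[i] + c(-1.8, -1.2, 0),
               y = d$y[i] + c(-0.9, -0.4, 0),
               z = d$z[i] + c(0.7, 0.3, 0),
               stringsAsFactors = FALSE)
  })
  id <- toupper(sub(".*_", "", which))
  make_structure(id, do.call(rbind, rows))
}

#' Plant a motif copy in a synthetic decoy structure
#'
#' Copies the motif's reactive-atom geometry, perturbs each atom with
#' isotropic Gaussian noise, embeds it among random decoy residues (reactive
#' atoms placed uniformly in a box of density about `density` residues per
#' cubic Angstrom, dense enough to create near-miss candidates), and applies
#' a random rigid motion to the whole structure. The planted ground truth is
#' recorded for tests.
#'
#' @param m a `decaaf_motif` or `decaaf_partial_motif`.
#' @param noise_sigma per-coordinate Gaussian noise, Angstrom (>= 0).
#' @param n_decoys number of decoy residues.
#' @param seed integer seed; fixed seed gives identical output.
#' @param rigid apply a random rigid motion (rotation + translation).
#' @param density decoy box density, residues per cubic Angstrom.
#' @param id structure id.
#' @return A `decaaf_structure` with attributes `ground_truth` (data frame of
#'   planted residues: `position`, `chain`, `resno`, `resname`, `atom` and
#'   the planted, post-motion coordinates) and `rigid_transform`.
#' @examples
#' s <- anchor_fixture("hne_1b0f")
#' m <- build_template(s, data.frame(resno = c(195, 57, 214)))
#' decoy <- plant_motif(m, noise_sigma = 0.3, n_decoys = 20, seed = 7)
#' attr(decoy, "ground_truth")
#' @export
plant_motif <- function(m, noise_sigma = 0, n_decoys = 50, seed = 1,
                        rigid = TRUE, density = 0.01, id = "planted") {
  stopifnot(noise_sigma >= 0, n_decoys >= 0, density > 0)
  if (inherits(m, "decaaf_partial_motif")) {
    pos <- m$positions
    xyz <- m$parent$coords[m$idx, , drop = FALSE]
  } else {
    stopifnot(inherits(m, "decaaf_motif"))
    pos <- m$positions
    xyz <- m$coords
  }
  k <- nrow(pos)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  n_total <- n_decoys + k
  side <- (n_total / density)^(1 / 3)
  aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

  # center the planted copy in the decoy box, perturb
  centroid <- colMeans(xyz)
  planted <- sweep(xyz, 2, centroid, "-") +
    matrix(side / 2, k, 3) +
    matrix(stats::rnorm(3 * k, sd = noise_sigma), k, 3)

  decoys <- data.frame(resname = character(0), resno = integer(0),
                       atom = character(0), x = numeric(0), y = numeric(0),
                       z = numeric(0), stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    decoys <- data.frame(resname = sample(aa20, n_decoys, replace = TRUE),
                         resno = seq_len(n_decoys),
                         stringsAsFactors = FALSE)
    decoys$atom <- reactive_atom_name(decoys$resname)
    decoys$x <- stats::runif(n_decoys, 0, side)
    decoys$y <- stats::runif(n_decoys, 0, side)
    decoys$z <- stats::runif(n_decoys, 0, side)
  }
  planted_df <- data.frame(resname = pos$resname,
                           resno = n_decoys + seq_len(k),
                           atom = pos$atom,
                           x = planted[, 1], y = planted[, 2], z = planted[, 3],
                           stringsAsFactors = FALSE)
  atoms <- rbind(decoys[, c("resname", "resno", "atom", "x", "y", "z")],
                 planted_df)

  tf <- if (rigid) random_rigid_transform() else identity_transform()
  xyz_all <- apply_transform(as.matrix(atoms[, c("x", "y", "z")]), tf)
  atoms$x <- xyz_all[, 1]; atoms$y <- xyz_all[, 2]; atoms$z <- xyz_all[, 3]

  s <- make_structure(id, atoms)
  gt <- planted_df
  gt_xyz <- apply_transform(as.matrix(planted_df[, c("x", "y", "z")]), tf)
  gt$x <- gt_xyz[, 1]; gt$y <- gt_xyz[, 2]; gt$z <- gt_xyz[, 3]
  gt <- cbind(position = pos$label, chain = "A", gt,
              stringsAsFactors = FALSE)
  attr(s, "ground_truth") <- gt
  attr(s, "rigid_transform") <- tf
  s
}

#' A uniformly random proper rigid motion
#'
#' Rotation drawn via QR decomposition of a Gaussian matrix (sign-fixed to
#' determinant +1), translation uniform in a +/- 20 Angstrom cube. Uses the
#' current RNG state.
#'
#' @param max_translation half-width of the translation cube, Angstrom.
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_translation = 20) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  r <- r %*% d
  if (det(r) < 0) r[, 1] <- -r[, 1]
  structure(list(rotation = r,
                 translation = stats::runif(3, -max_translation,
                                            max_translation)),
            class = "rigid_transform")
}

identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0)),
            class = "rigid_transform")
}

# published steric neighborhoods around the superposed deacylation-base
# position (beta-lactamase Glu166/OE1 and its cognates): distance (Angstrom),
# residue name, residue number, atom
.glu166_site_data <- list(
  "1E25" = list(center_resno = 166, rows = data.frame(
    d = c(0, 1.3, 2.2, 2.4, 2.7, 3.0, 3.1),
    resname = c(rep("GLU", 6), "HOH"),
    resno = c(rep(166, 6), 2076),
    atom = c("OE1", "CD", "OE2", "CG", "CB", "CA", "O"),
    stringsAsFactors = FALSE)),
  "2J7V" = list(center_resno = 158, rows = data.frame(
    d = c(1.6, 1.6, 1.8, 2.4, 2.7, 2.7, 2.7, 2.8, 2.9, 3.1, 3.2, 3.4),
    resname = c("PRO", "PRO", "PRO", "LEU", "ASP", "PRO", "LEU", "PRO",
                "LEU", "LEU", "LEU", "HOH"),
    resno = c(159, 159, 159, 158, 160, 159, 158, 159, 158, 158, 158, 2146),
    atom = c("C", "CA", "O", "CD1", "N", "N", "CA", "CB", "CB", "CG", "C",
             "O"),
    stringsAsFactors = FALSE)),
  "2J9O" = list(center_resno = 158, rows = data.frame(
    d = c(1.6, 1.6, 1.9, 1.9, 2.6, 2.7, 2.7, 2.8, 2.8, 2.9, 3.1, 3.3),
    resname = c("PRO", "PRO", "GLU", "PRO", "ASP", "GLU", "PRO", "GLU",
                "GLU", "PRO", "GLU", "HOH"),
    resno = c(159, 159, 158, 159, 160, 158, 159, 158, 158, 159, 158, 2234),
    atom = c("C", "CA", "OE1", "O", "N", "CA", "N", "CB", "CD", "CB", "C",
             "O"),
    stringsAsFactors = FALSE)),
  "1NZO" = list(center_resno = 153, rows = data.frame(
    d = c(1.4, 2.7, 2.8),
    resname = c("LEU", "LEU", "HOH"),
    resno = c(153, 153, 475),
    atom = c("CD2", "CG", "O"),
    stringsAsFactors = FALSE))
)

#' Synthetic reconstruction of the published Glu166-site neighborhoods
#'
#' Rebuilds, from the published distance tables, the steric neighborhoods
#' around the superposed deacylation-base position (Glu166/OE1 of a Class A
#' beta-lactamase and its spatial cognates in two PBP-A forms and PBP-5).
#' Atoms are placed at their published distances from the origin (the
#' superposed center) along deterministic, well-spread unit vectors; distances
#' to the center are exact by construction, the geometry *between* neighbors
#' is synthetic. Intended for testing neighbor reports and obstruction
#' comparisons offline; it is not the deposited structure.
#'
#' @param which `"1E25"`, `"2J7V"`, `"2J9O"` or `"1NZO"`.
#' @return A `decaaf_structure` with attribute `center_resno` (the residue
#'   number of the site's own cognate residue, for self-exclusion).
#' @export
glu166_site_fixture <- function(which = c("1E25", "2J7V", "2J9O", "1NZO")) {
  which <- match.arg(which)
  site <- .glu166_site_data[[which]]
  rows <- site$rows
  n <- nrow(rows)
  u <- fibonacci_sphere(n)
  atoms <- data.frame(resname = rows$resname, resno = rows$resno,
                      atom = rows$atom,
                      x = rows$d * u[, 1], y = rows$d * u[, 2],
                      z = rows$d * u[, 3], stringsAsFactors = FALSE)
  s <- make_structure(paste0(which, "-site-synthetic"), atoms)
  attr(s, "center_resno") <- site$center_resno
  s
}

# n well-spread unit vectors (golden-spiral lattice on the sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
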