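# Electrostatic potentials at reactive atoms, in dimensionless kT/e.
#
# Three sources: a scalar grid from a Poisson-Boltzmann solver (OpenDX, as
# written by APBS), a per-atom table, or a built-in screened-Coulomb model for
# PQR input. The solver itself is out of scope; the Coulomb model keeps the
# pipeline self-contained.

# e/(4*pi*eps0) in volt-Angstrom; kB in eV/K
.COUL_VA <- 14.399645
.KB_EV <- 8.617333262e-5

#' Conversion factor from e/(eps * Angstrom) Coulomb units to kT/e
#' @param temperature_K temperature in kelvin.
#' @return Dimensionless multiplier.
#' @export
kT_e_factor <- function(temperature_K = 298) {
  stopifnot(temperature_K > 0)
  .COUL_VA / (.KB_EV * temperature_K)
}

#' Potential sources
#'
#' Constructors for the three ways of attaching potentials to atoms:
#' * `grid_source()`: trilinear interpolation in a scalar grid (kT/e) on a
#'   regular axis-aligned lattice, e.g. APBS output read by [read_opendx()].
#' * `table_source()`: per-atom values keyed by (chain, resno, atom name);
#'   chain may be empty to match any chain.
#' * `coulomb_source()`: screened Coulomb sum over the structure's partial
#'   charges (PQR input), \eqn{V(x) = C(T)/\epsilon \sum_i q_i e^{-r_i/\lambda}/r_i},
#'   converted to kT/e. Defaults follow a solute dielectric of 2, 298 K and
#'   zero ionic strength (no screening).
#'
#' @param grid a `dx_grid` (see [read_opendx()]) or a path to an OpenDX file.
#' @param table data frame with columns `chain`, `resno`, `atom`, `potential`,
#'   or a path to such a TSV.
#' @param dielectric relative dielectric constant (>= 1).
#' @param temperature_K temperature in kelvin.
#' @param screening_length Debye screening length in Angstrom, or `NULL` for
#'   none (zero ionic strength).
#' @param min_dist distance clamp in Angstrom avoiding the singularity at
#'   bonded neighbors.
#' @return A `potential_source` object.
#' @name potential_source
NULL

#' @rdname potential_source
#' @export
grid_source <- function(grid) {
  if (is.character(grid)) grid <- read_opendx(grid)
  stopifnot(inherits(grid, "dx_grid"))
  structure(list(kind = "grid", grid = grid), class = "potential_source")
}

#' @rdname potential_source
#' @export
table_source <- function(table) {
  if (is.character(table)) {
    table <- utils::read.table(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = c(chain = "character"))
  }
  stopifnot(all(c("chain", "resno", "atom", "potential") %in% names(table)))
  table$chain[is.na(table$chain)] <- ""
  structure(list(kind = "table", table = table), class = "potential_source")
}

#' @rdname potential_source
#' @export
coulomb_source <- function(dielectric = 2, temperature_K = 298,
                           screening_length = NULL, min_dist = 0.5) {
  stopifnot(dielectric >= 1, temperature_K > 0, min_dist > 0)
  structure(list(kind = "coulomb", dielectric = dielectric,
                 temperature_K = temperature_K,
                 screening_length = screening_length,
                 min_dist = min_dist),
            class = "potential_source")
}

#' @export
print.potential_source <- function(x, ...) {
  cat("potential source, kind:", x$kind, "\n")
  invisible(x)
}

#' Read an OpenDX scalar grid
#'
#' Parses the regular-grid OpenDX dialect written by Poisson-Boltzmann solvers
#' (`object 1 class gridpositions counts nx ny nz`, `origin`, three axis-aligned
#' `delta` rows, then the data array with the z index varying fastest).
#'
#' @param path path to a .dx file.
#' @return A `dx_grid`: list with `origin` (3-vector, Angstrom), `delta`
#'   (3-vector of spacings), `counts` (3 integers) and `values` (array
#'   `counts[1] x counts[2] x counts[3]`, kT/e).
#' @export
read_opendx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  cl <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(cl) == 0) stop("not an OpenDX gridpositions file: ", path)
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", cl[1])), "\\s+")[[1]])
  ol <- grep("^\\s*origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(sub("origin", "", ol[1])), "\\s+")[[1]])
  dl <- grep("^\\s*delta", lines, value = TRUE)
  dmat <- t(vapply(dl[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(dmat[upper.tri(dmat)]) > 0 | abs(dmat[lower.tri(dmat)]) > 0)) {
    stop("only axis-aligned grids are supported")
  }
  delta <- diag(dmat)
  if (any(delta <= 0)) stop("grid spacing must be positive")
  i0 <- grep("data follows", lines)
  if (length(i0) == 0) stop("no data section in ", path)
  iend <- grep("^\\s*(attribute|object|component)", lines)
  iend <- iend[iend > i0[1]]
  iend <- if (length(iend)) min(iend) else length(lines) + 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0[1] + 1):(iend - 1)]),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(counts)) {
    stop("expected ", prod(counts), " grid values, found ", length(vals))
  }
  # file order: z fastest, then y, then x
  values <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  structure(list(origin = origin, delta = delta, counts = counts,
                 values = values),
            class = "dx_grid")
}

#' Write an OpenDX scalar grid
#'
#' Inverse of [read_opendx()]; useful for generating small solver-style grids.
#'
#' @param grid a `dx_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(grid, path) {
  n <- grid$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0.0 0.0", grid$delta[1]),
    sprintf("delta 0.0 %g 0.0", grid$delta[2]),
    sprintf("delta 0.0 0.0 %g", grid$delta[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  # 3 values per line, z fastest
  idx <- seq(1, length(vals), by = 3)
  writeLines(vapply(idx, function(i) {
    paste(format(vals[i:min(i + 2, length(vals))], digits = 12),
          collapse = " ")
  }, character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

# trilinear interpolation of a dx_grid at an n x 3 coordinate matrix
interp_grid <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  frac <- sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$delta, "/")
  n <- grid$counts
  if (any(frac < -1e-9) || any(sweep(frac, 2, n - 1, "-") > 1e-9)) {
    stop("atom coordinate outside the potential grid")
  }
  frac <- pmin(pmax(frac, 0), matrix(rep(n - 1, each = nrow(frac)), ncol = 3))
  i0 <- pmin(floor(frac), matrix(rep(n - 2, each = nrow(frac)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- frac - i0
  v <- grid$values
  out <- numeric(nrow(xyz))
  for (r in seq_len(nrow(xyz))) {
    i <- i0[r, 1] + 1; j <- i0[r, 2] + 1; k <- i0[r, 3] + 1
    fx <- f[r, 1]; fy <- f[r, 2]; fz <- f[r, 3]
    c00 <- v[i, j, k] * (1 - fx) + v[i + 1, j, k] * fx
    c10 <- v[i, j + 1, k] * (1 - fx) + v[i + 1, j + 1, k] * fx
    c01 <- v[i, j, k + 1] * (1 - fx) + v[i + 1, j, k + 1] * fx
    c11 <- v[i, j + 1, k + 1] * (1 - fx) + v[i + 1, j + 1, k + 1] * fx
    c0 <- c00 * (1 - fy) + c10 * fy
    c1 <- c01 * (1 - fy) + c11 * fy
    out[r] <- c0 * (1 - fz) + c1 * fz
  }
  out
}

#' Attach electrostatic potentials to a structure's atoms
#'
#' Fills the `potential` column of the atom table (kT/e). Grid sources sample
#' by trilinear interpolation at each atom center; Coulomb sources require
#' per-atom charges (PQR input) and evaluate the screened Coulomb sum over all
#' other atoms; table sources set the listed atoms (others stay unassigned and
#' error on later use).
#'
#' @param s a `decaaf_structure`.
#' @param src a `potential_source`.
#' @return The structure with potentials assigned.
#' @export
assign_potentials <- function(s, src) {
  stopifnot(inherits(src, "potential_source"))
  a <- s$atoms
  if (src$kind == "grid") {
    a$potential <- interp_grid(src$grid, as.matrix(a[, c("x", "y", "z")]))
  } else if (src$kind == "coulomb") {
    if (anyNA(a$charge)) {
      stop("coulomb potential source requires per-atom charges ",
           "(read the structure from PQR)")
    }
    a$potential <- coulomb_potentials(as.matrix(a[, c("x", "y", "z")]),
                                      a$charge, src)
  } else if (src$kind == "table") {
    tb <- src$table
    for (r in seq_len(nrow(tb))) {
      sel <- a$resno == tb$resno[r] & a$name == tb$atom[r]
      if (!is.na(tb$chain[r]) && tb$chain[r] != "") {
        sel <- sel & a$chain == tb$chain[r]
      }
      if (!any(sel)) {
        stop("table potential entry matches no atom: ",
             tb$chain[r], ":", tb$resno[r], ":", tb$atom[r])
      }
      a$potential[sel] <- tb$potential[r]
    }
  }
  s$atoms <- a
  s
}

coulomb_potentials <- function(xyz, q, src) {
  n <- nrow(xyz)
  fac <- kT_e_factor(src$temperature_K) / src$dielectric
  d <- as.matrix(stats::dist(xyz))
  d[d < src$min_dist] <- src$min_dist
  w <- 1 / d
  if (!is.null(src$screening_length)) w <- w * exp(-d / src$screening_length)
  diag(w) <- 0
  fac * as.vector(w %*% q)
}

#' Potential difference between two atoms
#'
#' Signed difference V(a) - V(b) in kT/e, with `a` preceding `b` in motif
#' position order; antisymmetric under argument swap.
#'
#' @param a,b one-row atom data frames with assigned potentials (e.g. from
#'   [get_reactive_atom()] after [assign_potentials()]).
#' @return Numeric scalar, kT/e.
#' @export
potential_difference <- function(a, b) {
  va <- a$potential[1]; vb <- b$potential[1]
  if (is.na(va) || is.na(vb)) {
    stop("potential not assigned; run assign_potentials() first")
  }
  va - vb
}
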