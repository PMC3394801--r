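# Small PDB/PQR text fixtures written at test time.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, alt = " ", type = "ATOM", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, resname, chain, resno, x, y, z, occ, 10,
          element)
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# triad-like toy: Ser10, His20, Asp30 + a water, single model
toy_triad_lines <- function(shift = 0) {
  c(pdb_line(1, "N", "SER", "A", 10, 0 + shift, 0, 0),
    pdb_line(2, "CA", "SER", "A", 10, 1 + shift, 0, 0),
    pdb_line(3, "OG", "SER", "A", 10, 2 + shift, 1, 0),
    pdb_line(4, "CA", "HIS", "A", 20, 4 + shift, 4, 0),
    pdb_line(5, "ND1", "HIS", "A", 20, 5 + shift, 3, 1),
    pdb_line(6, "OD1", "ASP", "A", 30, 1 + shift, 5, 2),
    pdb_line(7, "O", "HOH", "A", 99, 9 + shift, 9, 9, type = "HETATM"))
}

# degenerate (collinear/coincident) anchor triple, used to skip invalid draws
canonical_degenerate <- function(pts) {
  u <- pts[2, ] - pts[1, ]
  v <- pts[3, ] - pts[1, ]
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  sides <- c(sqrt(sum(u^2)), sqrt(sum(v^2)), sqrt(sum((pts[3, ] - pts[2, ])^2)))
  min(sides) == 0 || sqrt(sum(w^2)) / max(sides) < 1e-4
}
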