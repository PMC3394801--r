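t4_1b0f <- matrix(c(64.4, 57.0, 53.8,
                    63.3, 54.8, 58.2,
                    63.6, 50.6, 56.1), 3, 3, byrow = TRUE)
t4_1cfe <- matrix(c(8.8, -6.3, -4.8,
                    9.2, -2.4, -1.8,
                    13.7, -1.6, -3.7), 3, 3, byrow = TRUE)

test_that("the canonical frame reproduces the published worked-example coordinates", {
  tf <- canonical_frame(t4_1b0f[1, ], t4_1b0f[2, ], t4_1b0f[3, ])
  after <- apply_transform(t4_1b0f, tf)
  expect_equal(after[1, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(after[2, ], c(5.0, 0, 0), tolerance = 0.1)
  expect_equal(after[3, ], c(5.0, 4.7, 0), tolerance = 0.1)

  tf2 <- canonical_frame(t4_1cfe[1, ], t4_1cfe[2, ], t4_1cfe[3, ])
  after2 <- apply_transform(t4_1cfe, tf2)
  expect_equal(after2[1, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(after2[2, ], c(4.9, 0, 0), tolerance = 0.1)
  # published (4.7, 5, 0); recomputation from the rounded inputs gives
  # (4.78, 4.95, 0)
  expect_equal(after2[3, ], c(4.7, 5.0, 0), tolerance = 0.1)
})

test_that("already-canonical anchors give the identity transform", {
  tf <- canonical_frame(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("the canonical frame is proper, rigid, and invariant to pre-applied rigid motions", {
  set.seed(1234)
  for (i in 1:200) {
    pts <- matrix(rnorm(9, sd = 5), 3, 3)
    if (canonical_degenerate(pts)) next
    tf <- canonical_frame(pts[1, ], pts[2, ], pts[3, ])
    r <- tf$rotation
    expect_equal(det(r), 1, tolerance = 1e-9)
    expect_equal(crossprod(r), diag(3), tolerance = 1e-9)
    after <- apply_transform(pts, tf)
    # canonical shape: origin, +X, Z=0 with Y>0
    expect_equal(after[1, ], c(0, 0, 0), tolerance = 1e-9)
    expect_equal(after[2, 2:3], c(0, 0), tolerance = 1e-9)
    expect_gt(after[2, 1], 0)
    expect_equal(after[3, 3], 0, tolerance = 1e-9)
    expect_gt(after[3, 2], 0)
    # rigidity: pairwise distances preserved
    expect_equal(c(dist(after)), c(dist(pts)), tolerance = 1e-9)
    # invariance: a random rigid motion before the construction changes nothing
    moved <- apply_transform(pts, random_rigid_transform())
    tfm <- canonical_frame(moved[1, ], moved[2, ], moved[3, ])
    expect_equal(apply_transform(moved, tfm), after, tolerance = 1e-8)
  }
})

test_that("the canonical frame never reflects: tetrahedron chirality is preserved", {
  set.seed(77)
  for (i in 1:50) {
    pts <- matrix(rnorm(12, sd = 4), 4, 3)
    if (canonical_degenerate(pts[1:3, ])) next
    chir <- function(x) sign(det(rbind(x[2, ] - x[1, ], x[3, ] - x[1, ],
                                       x[4, ] - x[1, ])))
    tf <- canonical_frame(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(chir(apply_transform(pts, tf)), chir(pts))
  }
})

test_that("collinear or coincident anchors are rejected", {
  expect_error(canonical_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  expect_error(canonical_frame(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "collinear|coincident")
})

test_that("superpose_pair overlays the worked example and reports residuals", {
  hne <- anchor_fixture("hne_1b0f")
  cfe <- anchor_fixture("p14a_1cfe")
  t_anchors <- list(get_reactive_atom(hne, 195), get_reactive_atom(hne, 57),
                    get_reactive_atom(hne, 214))
  g_anchors <- list(get_reactive_atom(cfe, 49), get_reactive_atom(cfe, 48),
                    get_reactive_atom(cfe, 36))
  sp <- superpose_pair(hne, t_anchors, cfe, g_anchors)
  # after-block matches the published table to 0.1 A
  aft <- as.matrix(sp$summary[, c("after_x", "after_y", "after_z")])
  expect_equal(aft[1, ], c(0, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(aft[2, ], c(5.0, 0, 0), tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(aft[3, ], c(5.0, 4.7, 0), tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(aft[5, ], c(4.9, 0, 0), tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(aft[6, ], c(4.7, 5.0, 0), tolerance = 0.12, ignore_attr = TRUE)
  # first anchors coincide exactly; the others are close (congruent triangles)
  expect_equal(sp$summary$residual[1], 0, tolerance = 1e-9)
  expect_lt(max(sp$summary$residual), 0.5)
  # the transformed structures carry the moved coordinates
  og <- get_reactive_atom(sp$template, 195)
  expect_equal(c(og$x, og$y, og$z), c(0, 0, 0), tolerance = 1e-9)
})

test_that("self-superposition is exact", {
  hne <- anchor_fixture("hne_1b0f")
  anchors <- list(get_reactive_atom(hne, 195), get_reactive_atom(hne, 57),
                  get_reactive_atom(hne, 214))
  sp <- superpose_pair(hne, anchors, hne, anchors)
  expect_equal(coords(sp$template), coords(sp$target), tolerance = 1e-9)
  expect_equal(sp$summary$residual, rep(0, 6), tolerance = 1e-9)
})

test_that("neighbor reports sort ascending, respect the radius, and stop at water", {
  s <- make_structure("toy", data.frame(
    resname = c("GLU", "ALA", "HOH", "GLY"),
    resno = c(1, 2, 3, 4),
    atom = c("OE1", "CB", "O", "N"),
    x = c(0, 1, 2, 3), y = 0, z = 0))
  rp <- neighbor_report(s, resno = 1, atom = "OE1", radius = 3.5)
  # truncated immediately after the first water (2 A), the 3 A atom dropped
  expect_equal(rp$distance, c(0, 1, 2))
  expect_true(attr(rp, "truncated"))
  expect_equal(rp$residue, c("Glu1", "Ala2", "HOH3"))
  # without truncation the report is a superset
  rp_all <- neighbor_report(s, resno = 1, atom = "OE1", radius = 3.5,
                            stop_at_water = FALSE)
  expect_equal(rp_all$distance, c(0, 1, 2, 3))
  # radius cuts before the water is reached
  rp_near <- neighbor_report(s, resno = 1, atom = "OE1", radius = 1.5)
  expect_equal(rp_near$distance, c(0, 1))
  expect_error(neighbor_report(s, resno = 9, atom = "X"), "not found")
})

test_that("hydrogens are excluded from reports unless requested", {
  s <- make_structure("toy", data.frame(
    resname = c("GLU", "GLU", "ALA"), resno = c(1, 1, 2),
    atom = c("OE1", "HE1", "CB"), x = c(0, 0.5, 2), y = 0, z = 0,
    element = c("O", "H", "C")))
  expect_equal(neighbor_report(s, resno = 1, atom = "OE1", radius = 3)$atom,
               c("OE1", "CB"))
  expect_equal(neighbor_report(s, resno = 1, atom = "OE1", radius = 3,
                               include_hydrogens = TRUE)$atom,
               c("OE1", "HE1", "CB"))
})

test_that("the reconstructed lactamase site tables behave as published", {
  e25 <- glu166_site_fixture("1E25")
  rp <- neighbor_report(e25, resno = 166, atom = "OE1", radius = 3.5)
  expect_equal(rp$distance[1], 0)
  expect_equal(rp$residue[1], "Glu166")
  # nearest non-self heavy atom: the carboxylate carbon at 1.3 A
  expect_equal(rp$atom[2], "CD")
  expect_equal(rp$distance[2], 1.3, tolerance = 1e-9)
  # the list ends at the first water
  expect_equal(rp$residue[nrow(rp)], "HOH2076")
  expect_equal(rp$distance[nrow(rp)], 3.1, tolerance = 1e-9)
  expect_false(any(rp$is_water[-nrow(rp)]))

  # equal-distance rows order by residue number then atom name
  j7v <- glu166_site_fixture("2J7V")
  rj <- neighbor_report(j7v, point = c(0, 0, 0), resno = 158, radius = 3.5)
  expect_equal(rj$atom[1:2], c("C", "CA"))
  expect_equal(rj$residue[1:2], c("Pro159", "Pro159"))
})

test_that("obstruction comparison flags the PBP-A site but not the lactamase or PBP-5 sites", {
  reports <- lapply(c("1E25", "2J7V", "2J9O", "1NZO"), function(w) {
    s <- glu166_site_fixture(w)
    neighbor_report(s, point = c(0, 0, 0), resno = attr(s, "center_resno"),
                    radius = 3.5)
  })
  names(reports) <- c("1E25", "2J7V", "2J9O", "1NZO")
  cmp <- steric_obstruction_compare(reports, clearance_radius = 3)
  expect_equal(cmp$obstructed, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cmp$n_foreign[1], 0)
  expect_true(grepl("Pro159", cmp$foreign_residues[3]))
  expect_true(grepl("Asp160", cmp$foreign_residues[3]))
  # an empty neighborhood is unobstructed
  empty <- make_structure("e", data.frame(resname = "GLY", resno = 1,
                                          atom = "N", x = 50, y = 50, z = 50))
  rp0 <- neighbor_report(empty, point = c(0, 0, 0), radius = 3)
  expect_false(steric_obstruction_compare(list(rp0))$obstructed)
})

test_that("mutation suggestions find residues near the unmatched template atom", {
  hne <- anchor_fixture("hne_1b0f")
  # template with an extra carboxylate whose position the target lacks
  hne$atoms <- rbind(hne$atoms, make_structure("x", data.frame(
    resname = "ASP", resno = 102, atom = "OD1",
    x = 60.0, y = 54.0, z = 55.0))$atoms)
  # target: one residue planted exactly at the unmatched atom, one far away
  target <- make_structure("tgt", data.frame(
    resname = c("ASN", "SER", "GLY"), resno = c(35, 39, 80),
    atom = c("OD1", "OG", "N"),
    x = c(60.0, 61.5, 10), y = c(54.0, 54.5, 10), z = c(55.0, 55.5, 10)))
  sug <- suggest_mutations(hne, target,
                           unmatched = data.frame(resno = 102),
                           cutoff = 5)
  expect_length(sug, 1)
  cand <- sug[[1]]$candidates
  expect_equal(cand$residue[1], "Asn35")
  expect_equal(cand$distance[1], 0, tolerance = 1e-9)
  expect_equal(cand$substitution[1:2], c("Asn35Asp", "Ser39Asp"))
  expect_false(any(cand$resno == 80))
  expect_equal(cand$distance, sort(cand$distance))
  # matched residues and waters are excluded
  sug2 <- suggest_mutations(hne, target, data.frame(resno = 102),
                            matched_target = data.frame(resno = 35),
                            cutoff = 5)
  expect_false(any(sug2[[1]]$candidates$resno == 35))
  # empty unmatched list gives empty output
  expect_length(suggest_mutations(hne, target,
                                  unmatched = data.frame(resno = numeric(0))),
                0)
})

test_that("suggestion distances are invariant to a common pre-superposition motion", {
  m <- build_template(anchor_fixture("hne_1b0f"),
                      data.frame(resno = c(195, 57, 214)))
  hne <- anchor_fixture("hne_1b0f")
  hne$atoms <- rbind(hne$atoms, make_structure("x", data.frame(
    resname = "ASP", resno = 102, atom = "OD1",
    x = 60, y = 54, z = 55))$atoms)
  target <- plant_motif(m, noise_sigma = 0.2, n_decoys = 10, seed = 3,
                        rigid = FALSE)

  run_once <- function(tpl, tgt) {
    gt <- attr(target, "ground_truth")
    t_anchors <- lapply(c(195, 57, 214), function(r) get_reactive_atom(tpl, r))
    g_anchors <- lapply(gt$resno, function(r) get_reactive_atom(tgt, r))
    sp <- superpose_pair(tpl, t_anchors, tgt, g_anchors)
    suggest_mutations(sp$template, sp$target, data.frame(resno = 102),
                      cutoff = 20)[[1]]$candidates
  }
  base <- run_once(hne, target)
  set.seed(8)
  moved <- run_once(apply_transform(hne, random_rigid_transform()),
                    apply_transform(target, random_rigid_transform()))
  expect_equal(moved$distance, base$distance, tolerance = 1e-8)
  expect_equal(moved$residue, base$residue)
})
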