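hne3 <- function() {
  build_template(anchor_fixture("hne_1b0f"), data.frame(resno = c(195, 57, 214)))
}

test_that("a template self-match is found with score exactly 0", {
  s <- anchor_fixture("hne_1b0f")
  m <- hne3()
  mm <- find_matches(m, s)
  expect_gt(length(mm), 0)
  best <- mm[[1]]
  expect_identical(best$score, 0)
  expect_equal(best$assignment$residue, c("Ser195", "His57", "Ser214"))
  expect_equal(unname(best$dev_d), c(0, 0, 0))
})

test_that("Ser-or-Tyr equivalence recovers the published cross-protein match", {
  m <- expand_equivalence(hne3(), "Ser214", "TYR")
  cfe <- anchor_fixture("p14a_1cfe")
  mm <- find_matches(m, cfe)
  best <- mm[[1]]
  expect_equal(best$assignment$residue, c("Ser49", "His48", "Tyr36"))
  expect_equal(best$assignment$atom, c("OG", "ND1", "OH"))
  # reference-minus-target sign convention: the ab deviation is printed as 0.1
  expect_equal(round(unname(best$dev_d["ab"]), 1), 0.1)
  # without the equivalence the position is unsatisfiable here (no other Ser)
  expect_length(find_matches(hne3(), cfe), 0)
})

test_that("targets lacking a required residue type yield an empty result, not an error", {
  decoy <- make_structure("decoy", data.frame(
    resname = c("SER", "GLY"), resno = 1:2, atom = c("OG", "N"),
    x = c(0, 3), y = 0, z = 0))
  mm <- find_matches(hne3(), decoy)
  expect_s3_class(mm, "decaaf_matches")
  expect_length(mm, 0)
})

test_that("the congruence score is zero only at perfect congruence, linear and monotone", {
  cfg <- scan_config(pd_weight = 0)
  expect_identical(congruence_score(c(0, 0, 0), c(5, 6.8, 4.7), cfg = cfg), 0)
  s1 <- congruence_score(c(0.1, 0.2, 0.3), c(5, 6.8, 4.7), cfg = cfg)
  expect_equal(s1, (0.1 / 5 + 0.2 / 6.8 + 0.3 / 4.7) / 3)
  # doubling every deviation doubles the score
  expect_equal(congruence_score(c(0.2, 0.4, 0.6), c(5, 6.8, 4.7), cfg = cfg),
               2 * s1)
  # monotone in each |deviation|, distance and potential terms alike
  cfg2 <- scan_config()
  base <- congruence_score(c(0.1, -0.2, 0.3), c(5, 6.8, 4.7),
                           dev_pd = c(5, -3, 2), ref_pd = c(50, 100, 5),
                           cfg = cfg2)
  for (i in 1:3) {
    dd <- c(0.1, -0.2, 0.3); dd[i] <- dd[i] * 3
    expect_gte(congruence_score(dd, c(5, 6.8, 4.7), c(5, -3, 2),
                                c(50, 100, 5), cfg2), base)
    dp <- c(5, -3, 2); dp[i] <- dp[i] * 3
    expect_gte(congruence_score(c(0.1, -0.2, 0.3), c(5, 6.8, 4.7), dp,
                                c(50, 100, 5), cfg2), base)
  }
  # near-zero reference PDs are guarded by the floor
  expect_lt(congruence_score(c(0, 0, 0), c(5, 6.8, 4.7), c(1, 1, 1),
                             c(0.01, 0.01, 0.01), cfg2), Inf)
})

test_that("electrostatic deviations are signed raw differences in position order", {
  s <- anchor_fixture("hne_1b0f")
  tb <- data.frame(chain = "A", resno = c(195, 57, 214),
                   atom = c("OG", "ND1", "OG"), potential = c(10, -40, -40))
  src <- table_source(tb)
  m <- build_template(s, data.frame(resno = c(195, 57, 214)),
                      potentials = src)
  tgt <- assign_potentials(s, table_source(
    data.frame(chain = "A", resno = c(195, 57, 214),
               atom = c("OG", "ND1", "OG"), potential = c(10, -45, -40))))
  mm <- find_matches(m, tgt, scan_config(use_potentials = TRUE))
  best <- mm[[1]]
  # ref PD(ab) = 50, target PD(ab) = 55 -> deviation -5
  expect_equal(unname(best$dev_pd["ab"]), -5)
  expect_equal(unname(best$dev_pd["bc"]), 5)
  expect_equal(unname(best$dev_d), c(0, 0, 0))
  expect_gt(best$score, 0)
})

test_that("matching agrees with the brute-force oracle on small structures", {
  m <- hne3()
  cfg <- scan_config(pd_weight = 0)
  for (seed in 1:8) {
    tgt <- plant_motif(m, noise_sigma = 0.4, n_decoys = 25, seed = seed)
    mm <- find_matches(m, tgt, cfg)
    oracle <- oracle_best_match(m, tgt, cfg)
    if (is.null(oracle)) {
      expect_length(mm, 0)
    } else {
      expect_gt(length(mm), 0)
      expect_equal(mm[[1]]$score, oracle$score, tolerance = 1e-12)
      expect_equal(sort(mm[[1]]$assignment$resno), sort(oracle$residues))
    }
  }
})

test_that("geometric scores are invariant under rigid motion of the target", {
  m <- hne3()
  tgt <- plant_motif(m, noise_sigma = 0.5, n_decoys = 20, seed = 42)
  cfg <- scan_config(pd_weight = 0)
  best0 <- find_matches(m, tgt, cfg)[[1]]
  set.seed(99)
  tgt_moved <- apply_transform(tgt, random_rigid_transform())
  best1 <- find_matches(m, tgt_moved, cfg)[[1]]
  expect_equal(best1$score, best0$score, tolerance = 1e-9)
  expect_equal(best1$assignment$resno, best0$assignment$resno)
})

test_that("the distance window prunes and max_results truncates", {
  m <- hne3()
  tgt <- plant_motif(m, noise_sigma = 3, n_decoys = 40, seed = 2)
  loose <- find_matches(m, tgt, scan_config(distance_window = 10,
                                            max_results = 1000))
  tight <- find_matches(m, tgt, scan_config(distance_window = 0.5,
                                            max_results = 1000))
  expect_lte(length(tight), length(loose))
  capped <- find_matches(m, tgt, scan_config(distance_window = 10,
                                             max_results = 3))
  expect_lte(length(capped), 3)
  if (length(capped) && length(loose)) {
    expect_equal(capped[[1]]$score, loose[[1]]$score)
  }
  # results come back ascending by score
  sc <- vapply(loose, `[[`, numeric(1), "score")
  expect_false(is.unsorted(sc))
})

test_that("DScore aggregates best scores with a penalty for unmatched motifs", {
  expect_equal(dscore(rep(0, 10)), 0)
  expect_equal(dscore(rep(NA_real_, 4), penalty = 1), 1)
  expect_equal(dscore(c(rep(0.02, 9), NA), penalty = 1), 0.118)
  expect_error(dscore(numeric(0)), "empty")
})

test_that("target ranking is ascending, order-invariant, and puts a planted copy first", {
  m <- hne3()
  lib <- partial_motifs(m, 3)
  template_s <- anchor_fixture("hne_1b0f")
  exact <- plant_motif(m, noise_sigma = 0, n_decoys = 15, seed = 10,
                       id = "exact")
  noisy <- plant_motif(m, noise_sigma = 1, n_decoys = 15, seed = 11,
                       id = "noisy")
  cfg <- scan_config(pd_weight = 0)
  tab <- rank_targets(list(noisy = noisy, self = template_s, exact = exact),
                      lib, cfg)
  expect_equal(tab$dscore, sort(tab$dscore))
  # the template itself and the exact planted copy both sit at (numerically)
  # zero, ahead of the noisy copy
  expect_setequal(tab$id[1:2], c("exact", "self"))
  expect_lt(max(tab$dscore[1:2]), 1e-9)
  expect_equal(tab$dscore[tab$id == "self"], 0)
  expect_gt(tab$dscore[tab$id == "noisy"], 1e-6)
  # permuting the input order changes nothing
  tab2 <- rank_targets(list(exact = exact, self = template_s, noisy = noisy),
                       lib, cfg)
  expect_equal(tab2$id, tab$id)
  expect_equal(tab2$dscore, tab$dscore)
})
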