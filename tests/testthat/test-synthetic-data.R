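test_that("optoDroplet generator honours the one-to-one and mixture regimes", {
  # all totals below the threshold: after-activation stays unimodal and the
  # recorded dense fractions are zero
  low <- gen_optodroplet_cells(n_cells = 12, csat_true = 5000,
                               total_intensity_range = c(500, 3000),
                               pixel_count_per_cell = 200, seed = 2)
  gt <- attr(low, "ground_truth")
  expect_true(all(gt$dense_fraction == 0))
  # generative definition: totals above csat give a bimodal mixture whose
  # dilute component sits at csat (noiseless check, within the cell gain)
  hi <- gen_optodroplet_cells(n_cells = 10, csat_true = 1000,
                              total_intensity_range = c(1200, 3000),
                              noise_cv = 0, cell_gain_cv = 0,
                              pixel_count_per_cell = 300, seed = 3)
  gt2 <- attr(hi, "ground_truth")
  expect_true(all(gt2$dense_fraction > 0))
  for (cid in unique(hi$cell_id)) {
    px <- hi$intensity_after[hi$cell_id == cid]
    tot <- gt2$totals[match(cid, unique(hi$cell_id))]
    expect_true(all(round(px, 6) %in% round(c(1000, 5 * tot), 6)))
    expect_true(any(round(px, 6) == 1000))  # dilute component present
  }
})

test_that("mixture weights solve intensity conservation exactly", {
  px <- gen_optodroplet_cells(n_cells = 25, seed = 4)
  gt <- attr(px, "ground_truth")
  sup <- gt$totals > gt$csat_true
  f <- gt$dense_fraction[sup]
  tot <- gt$totals[sup]
  expect_equal((1 - f) * gt$csat_true + f * gt$dense_fold * tot, tot,
               tolerance = 1e-12)
  expect_true(all(f > 0 & f < 1))
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_optodroplet_cells(n_cells = 6, seed = 11),
                   gen_optodroplet_cells(n_cells = 6, seed = 11))
  expect_identical(gen_variant_table(seed = 11), gen_variant_table(seed = 11))
  e1 <- gen_ensemble("ACDEFGHIKLMNPQRSTVWY", n_conformations = 5, seed = 11)
  e2 <- gen_ensemble("ACDEFGHIKLMNPQRSTVWY", n_conformations = 5, seed = 11)
  expect_identical(e1$conformations, e2$conformations)
  p1 <- gen_proteome_and_abundance(n_proteins = 8, seed = 11)
  p2 <- gen_proteome_and_abundance(n_proteins = 8, seed = 11)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$abundance, p2$abundance)
})

test_that("generator parameter validation rejects impossible inputs", {
  expect_error(gen_optodroplet_cells(n_cells = 0), "n_cells")
  expect_error(gen_optodroplet_cells(dense_fold = 0.5), "dense_fold")
  expect_error(gen_ensemble("ACD"), "n >= 5")
  expect_error(gen_ensemble("ACDEFGHIKL", sticker_positions = 40L), "outside")
  expect_error(gen_proteome_and_abundance(planted_bias = c(R = 0.99)),
               "infeasible")
})

test_that("variant generator encodes the polyphasic-linkage law", {
  cfg <- thermo_config()
  # p_U(0) = 0.5: a variant whose shifted dG is zero costs exactly 2 c*
  v <- gen_variant_table(dG_list = c(12.9, -20, 5), dG_shift_true = -12.9,
                         c_star_true = 7, noise_cv = 0, seed = 1)
  expect_equal(v$csat_measured[1], 14, tolerance = 1e-9)
  # deeply unstable after the shift: c_sat tends to c*
  expect_equal(v$csat_measured[2], 7, tolerance = 1e-4)
  # noiseless identity for every variant
  v2 <- gen_variant_table(noise_cv = 0, seed = 2)
  expect_equal(v2$csat_measured * fraction_unfolded(v2$dG_U, cfg, -12.9),
               rep(10.83, nrow(v2)), tolerance = 1e-12)
})

test_that("attraction-free ensembles match their own chain baseline within MC error", {
  s <- substr(foldphase:::base_variant_sequence(), 1, 30)
  # two independent attraction-free target pools agree residue by residue
  pools <- lapply(c(50L, 250L), function(s0) sapply(1:4, function(r)
    mean_contact_probability(
      gen_ensemble(s, sticker_positions = c(8L, 20L), attraction_strength = 0,
                   n_conformations = 120, seed = s0 + r))))
  m1 <- rowMeans(pools[[1]]); m2 <- rowMeans(pools[[2]])
  se <- sqrt(apply(pools[[1]], 1, sd)^2 + apply(pools[[2]], 1, sd)^2) / sqrt(4)
  expect_true(mean(abs(m1 - m2) <= 3 * pmax(se, 1e-4)) > 0.9)
  # the ideal-chain reference is more contact-rich than the self-avoiding
  # target, which is what makes its maximum a conservative threshold
  ref <- pool_ensembles(lapply(1:4, function(r)
    gen_ensemble(s, reference = TRUE, n_conformations = 120, seed = 50 + r)))
  expect_gt(max(mean_contact_probability(ref)), max(m1))
})

test_that("bond geometry and excluded volume hold in sampled conformations", {
  e <- gen_ensemble("ACDEFGHIKLMNPQRSTVWYACDEF", n_conformations = 10,
                    bond_length = 3.8, seed = 7)
  for (xyz in e$conformations) {
    bonds <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_equal(bonds, rep(3.8, length(bonds)), tolerance = 1e-9)
    d <- as.matrix(dist(xyz))
    sep <- abs(outer(seq_len(nrow(xyz)), seq_len(nrow(xyz)), "-"))
    expect_true(all(d[sep >= 2] >= 3.5 - 1e-9))
  }
})

test_that("synthetic proteomes plant composition and abundance biases", {
  pr <- gen_proteome_and_abundance(
    n_proteins = 60, planted_enriched = list(grpA = 1:10),
    planted_bias = c(R = 0.10), seed = 21)
  fr_R <- vapply(strsplit(pr$sequences, ""), function(a) mean(a == "R"),
                 numeric(1))
  expect_gt(mean(fr_R[1:10]), mean(fr_R[-(1:10)]) + 0.05)
  # planted proteins are more abundant in their group
  ga <- pr$groups == "grpA"
  ratio <- rowMeans(pr$abundance[1:10, ga]) / rowMeans(pr$abundance[1:10, !ga])
  expect_true(all(ratio > 2))
  # no Met or Trp patches by construction
  for (s in pr$sequences) {
    expect_equal(nrow(find_patches(s, "M")$intervals), 0L)
    expect_equal(nrow(find_patches(s, "W")$intervals), 0L)
  }
})
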