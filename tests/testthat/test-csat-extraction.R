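# Small helper: build a pixel table from explicit per-cell vectors.
pixel_table <- function(cells, max_intensity = 65535) {
  out <- do.call(rbind, lapply(names(cells), function(id) {
    data.frame(cell_id = id, pixel_id = seq_along(cells[[id]]$before),
               intensity_before = cells[[id]]$before,
               intensity_after = cells[[id]]$after)
  }))
  attr(out, "ground_truth") <- list(max_intensity = max_intensity)
  out
}

test_that("saturation filter removes cells only above the 25% rule", {
  mk <- function(n_sat, n = 200) {
    v <- c(rep(65535, n_sat), runif(n - n_sat, 900, 1100))
    list(before = v, after = v)
  }
  px <- pixel_table(list(over = mk(61), at = mk(50), clean = mk(0)))
  kept <- filter_cells(px)
  ids <- unique(kept$cell_id)
  expect_false("over" %in% ids)     # 30.5% saturated: removed
  expect_true("at" %in% ids)        # exactly 25%: rule is strictly greater
  expect_true("clean" %in% ids)
  expect_equal(attr(kept, "removed_cells")$cell_id, "over")
})

test_that("uniform-pixel screen drops bright tails and saturated pixels", {
  set.seed(1)
  # perfectly uniform cell: every non-saturated pixel is kept
  flat <- data.frame(cell_id = "c", pixel_id = 1:200,
                     intensity_before = rep(1500, 200),
                     intensity_after = rep(1500, 200))
  expect_length(select_uniform_pixels(flat, max_intensity = 65535), 200)
  # 5% bright-outlier tail: tail pixels excluded, bulk retained
  bulk <- exp(rnorm(950, log(1000), 0.05))
  tail_px <- exp(rnorm(50, log(8000), 0.05))
  cell <- data.frame(cell_id = "c", pixel_id = 1:1000,
                     intensity_before = c(bulk, tail_px),
                     intensity_after = 1)
  idx <- select_uniform_pixels(cell, max_intensity = 65535)
  expect_true(all(idx <= 950))
  expect_gt(length(idx), 800)
  # all pixels saturated before activation: nothing to use
  sat <- data.frame(cell_id = "c", pixel_id = 1:100,
                    intensity_before = rep(4095, 100),
                    intensity_after = rep(4095, 100))
  expect_length(select_uniform_pixels(sat, max_intensity = 4095), 0)
})

test_that("dilute/dense mixture fit recovers planted component means", {
  set.seed(2)
  n <- 1000
  before <- exp(rnorm(n, log(3000), 0.05))
  after <- c(exp(rnorm(600, log(1000), 0.05)), exp(rnorm(400, log(5000), 0.05)))
  cell <- data.frame(cell_id = "c", pixel_id = 1:n,
                     intensity_before = before, intensity_after = after)
  idx <- select_uniform_pixels(cell, max_intensity = 65535)
  fit <- fit_dilute_dense(cell, idx)
  expect_identical(fit$status, "kept")
  expect_equal(fit$I_dil_before, 3000, tolerance = 0.05)
  expect_equal(fit$I_dil_after, 1000, tolerance = 0.05)
  expect_equal(fit$I_den_after, 5000, tolerance = 0.05)
  expect_gte(fit$r2_after, 0.85)
})

test_that("one-to-one cells fit with a degenerate mixture and the dilute cap binds", {
  set.seed(3)
  n <- 600
  before <- exp(rnorm(n, log(2000), 0.04))
  cell <- data.frame(cell_id = "c", pixel_id = 1:n,
                     intensity_before = before,
                     intensity_after = exp(rnorm(n, log(2000), 0.04)))
  idx <- select_uniform_pixels(cell, max_intensity = 65535)
  fit <- fit_dilute_dense(cell, idx)
  expect_identical(fit$status, "kept")
  expect_lte(fit$I_dil_after, fit$I_dil_before + 1e-9)
  expect_equal(fit$I_dil_after, fit$I_dil_before, tolerance = 0.05)
  # after-distribution brighter than before: unconstrained fit would put the
  # dilute mean above I_dil_before; the constraint pins it at the cap
  cell2 <- data.frame(cell_id = "c", pixel_id = 1:n,
                      intensity_before = before,
                      intensity_after = exp(rnorm(n, log(2600), 0.04)))
  idx2 <- select_uniform_pixels(cell2, max_intensity = 65535)
  fit2 <- fit_dilute_dense(cell2, idx2)
  expect_lte(fit2$I_dil_after, fit2$I_dil_before + 1e-9)
})

test_that("cells with too few pixels or bins are discarded with reasons", {
  small <- data.frame(cell_id = "c", pixel_id = 1:50,
                      intensity_before = runif(50, 900, 1100),
                      intensity_after = runif(50, 900, 1100))
  f <- fit_dilute_dense(small, seq_len(50))
  expect_identical(f$status, "too_few_pixels")
  # plenty of pixels, but only 3 distinct values -> too few occupied bins
  vals <- rep(c(1000, 1010, 1020), each = 60)
  few <- data.frame(cell_id = "c", pixel_id = seq_along(vals),
                    intensity_before = vals, intensity_after = vals)
  f2 <- fit_dilute_dense(few, seq_along(vals))
  expect_identical(f2$status, "too_few_bins")
})

test_that("every kept cell fit satisfies the dilute-phase constraint", {
  px <- gen_optodroplet_cells(n_cells = 60, seed = 14)
  fits <- fit_all_cells(px)
  kept <- fits[fits$status == "kept", ]
  expect_gt(nrow(kept), 20)
  expect_true(all(kept$I_dil_after <= kept$I_dil_before + 1e-9))
  expect_true(all(kept$r2_after >= 0.85))
  expect_true(all(kept$I_dil_before > 0 & kept$I_dil_after > 0))
})

test_that("outlier pruning follows the three documented steps", {
  # all points exactly on the diagonal: nothing removed, steps 2-3 skipped
  diag_fits <- data.frame(
    cell_id = sprintf("c%02d", 1:20),
    I_dil_before = seq(500, 3000, length.out = 20),
    I_dil_after = seq(500, 3000, length.out = 20),
    I_den_after = NA_real_, r2_after = 0.99, n_pixels_used = 500L,
    status = "kept")
  out <- remove_outlier_cells(diag_fits)
  expect_equal(nrow(out), 20)
  expect_true(is.na(attr(out, "m")))
  # deviations all below x_1to1: still no off-diagonal set
  near <- diag_fits
  near$I_dil_after <- near$I_dil_before - runif(20, 0, 900)
  out2 <- remove_outlier_cells(near)
  expect_equal(nrow(out2), 20)
  expect_true(is.na(attr(out2, "m")))
})

test_that("Cook's-distance pruning matches a leave-one-out oracle", {
  set.seed(5)
  n <- 21
  x <- seq(1200, 3200, length.out = n)
  y <- x - 1500 + rnorm(n, 0, 15)   # off-diagonal branch, collinear
  y[7] <- y[7] - 900                # one gross outlier, still off-diagonal
  fits <- data.frame(cell_id = sprintf("c%02d", 1:n),
                     I_dil_before = x, I_dil_after = y,
                     I_den_after = NA_real_, r2_after = 0.99,
                     n_pixels_used = 500L, status = "kept")
  # oracle: leave-one-out Cook's distances flag exactly the planted point
  cd <- oracle_cooks(x, y)
  expect_identical(which(cd > 5 * mean(cd)), 7L)
  expect_equal(cd, unname(cooks.distance(lm(y ~ x))), tolerance = 1e-8)
  out <- remove_outlier_cells(fits)
  expect_false("c07" %in% out$cell_id)
  expect_equal(nrow(out), n - 1L)
})

test_that("estimate_csat recovers the planted threshold and calls non-separating populations", {
  px <- gen_optodroplet_cells(n_cells = 200, seed = 1)
  res <- extract_csat(px, seed = 1)
  expect_true(res$phase_separating)
  expect_equal(res$csat_mean, 1000, tolerance = 0.03)
  expect_lte(abs(res$csat_mean - 1000), res$csat_sd)
  expect_length(res$per_trial_splitVal, 50)
  # identical input and seed: identical result
  res2 <- extract_csat(px, seed = 1)
  expect_identical(res$per_trial_splitVal, res2$per_trial_splitVal)
  # purely one-to-one population
  low <- gen_optodroplet_cells(n_cells = 60, csat_true = 5000,
                               total_intensity_range = c(200, 3000), seed = 3)
  res3 <- extract_csat(low, seed = 1)
  expect_false(res3$phase_separating)
  expect_true(is.na(res3$csat_mean))
})

test_that("csat estimate is invariant to cell relabelling and order", {
  px <- gen_optodroplet_cells(n_cells = 120, seed = 9)
  res <- extract_csat(px, seed = 4)
  # shuffle rows and relabel cells (keeping pixels grouped per cell)
  ids <- unique(px$cell_id)
  relabel <- setNames(sprintf("z_%03d", seq_along(ids)), ids)
  px2 <- px
  px2$cell_id <- relabel[px2$cell_id]
  res2 <- extract_csat(px2, seed = 4)
  expect_equal(res2$csat_mean, res$csat_mean, tolerance = 1e-9)
  expect_equal(res2$csat_sd, res$csat_sd, tolerance = 1e-9)
})

test_that("bootstrap SD shrinks as the cell count grows", {
  r100 <- extract_csat(gen_optodroplet_cells(n_cells = 100, seed = 21), seed = 7)
  r400 <- extract_csat(gen_optodroplet_cells(n_cells = 400, seed = 21), seed = 7)
  expect_lt(r400$csat_sd, r100$csat_sd)
})
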