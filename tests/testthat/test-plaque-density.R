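# Channel subtraction, thresholding, label resampling, fractional-area
# mapping and hierarchy aggregation.

test_that("background subtraction follows the clamped additive model", {
  ch1 <- matrix(runif(100, 10, 50), 10, 10)
  expect_true(all(subtract_background(ch1, ch1, 1) == 0))
  discs <- matrix(0, 10, 10); discs[3:5, 3:5] <- 80
  expect_equal(subtract_background(ch1 + discs, ch1, 1), discs)
  expect_equal(subtract_background(ch1, ch1 * 100, 0), ch1)
  expect_error(subtract_background(ch1, matrix(0, 5, 5)), "shape")
})

test_that("thresholding is exact on clean discs and supports a size filter", {
  sig <- matrix(0, 20, 20)
  expect_true(!any(segment_plaques(sig + 5, 10)))
  disc <- matrix(0, 20, 20); disc[8:12, 8:12] <- 20
  expect_equal(segment_plaques(disc, 10), disc > 10)
  # one 25-px square and one isolated pixel; min-area removes the pixel
  disc[1, 1] <- 20
  m <- segment_plaques(disc, 10, min_area_px = 5)
  expect_false(m[1, 1])
  expect_equal(sum(m), 25)
})

test_that("label upsampling is nearest-neighbor and label-preserving", {
  one <- matrix(7L, 4, 4)
  expect_true(all(upsample_labels(one, c(8, 8)) == 7L))
  cb <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  up <- upsample_labels(cb, c(4, 4))
  expect_equal(up[1:2, 1:2], matrix(1L, 2, 2))
  expect_equal(up[3:4, 3:4], matrix(4L, 2, 2))
  expect_equal(sort(unique(as.integer(up))), 1:4)
  big <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  expect_equal(upsample_labels(upsample_labels(big, c(18, 18)), c(6, 6)), big)
})

test_that("region density pools counts over sections before dividing", {
  lab <- matrix(1L, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:5, ] <- TRUE
  expect_equal(region_density(mask, lab)$fractional_area, 0.5)
  expect_equal(region_density(matrix(FALSE, 10, 10), lab)$fractional_area, 0)
  # region areas 100 and 300 px across two sections, masked 10 and 0:
  # pooled 10/400 = 0.025, whereas a mean of ratios would give 0.05
  lab1 <- matrix(0L, 20, 20); lab1[1:10, 1:10] <- 5L
  lab2 <- matrix(0L, 20, 20); lab2[1:15, 1:20] <- 5L
  m1 <- matrix(FALSE, 20, 20); m1[1, 1:10] <- TRUE
  m2 <- matrix(FALSE, 20, 20)
  tab <- region_density(list(m1, m2), list(lab1, lab2))
  expect_equal(tab$fractional_area[tab$region_id == 5], 10 / 400)
  # a region with zero pixels is reported as missing, not zero
  tab2 <- region_density(m1, lab1, region_ids = c(5L, 9L))
  expect_true(is.na(tab2$fractional_area[tab2$region_id == 9]))
})

test_that("hierarchy aggregation pools counts and conserves the total", {
  hier <- data.frame(region_id = c(100L, 1L, 2L, 3L),
                     name = c("major", "a", "b", "c"),
                     parent_id = c(0L, 100L, 100L, 100L))
  tab <- data.frame(region_id = c(1L, 2L, 3L),
                    masked_pixels = c(100, 300, 0),
                    region_pixels = c(1000, 1000, 0))
  tab$fractional_area <- ifelse(tab$region_pixels > 0,
                                tab$masked_pixels / tab$region_pixels, NA)
  agg <- aggregate_to_major_regions(tab, hier, 100L)
  expect_equal(agg$fractional_area, 0.2)  # (100+300)/(1000+1000); c ignored
  # single child equal to parent keeps its density
  hier1 <- data.frame(region_id = c(10L, 1L), name = c("p", "c"),
                      parent_id = c(0L, 10L))
  tab1 <- data.frame(region_id = 1L, masked_pixels = 70, region_pixels = 700,
                     fractional_area = 0.1)
  expect_equal(aggregate_to_major_regions(tab1, hier1, 10L)$fractional_area, 0.1)
  # conservation: pooling to the forest root equals total masked / labeled
  atlas <- grid_atlas(c(48, 48), 2, 2)
  set.seed(3)
  mask <- matrix(runif(48 * 48) < 0.07, 48, 48)
  leaf <- region_density(mask, atlas$labels)
  roots <- unique(atlas$hierarchy$region_id[atlas$hierarchy$parent_id == 0])
  agg2 <- aggregate_to_major_regions(leaf, atlas$hierarchy, roots)
  expect_equal(sum(agg2$masked_pixels) / sum(agg2$region_pixels), mean(mask))
})

test_that("raising the threshold never increases any region density", {
  atlas <- grid_atlas(c(60, 60))
  dens <- stats::setNames(c(0.05, 0.02, 0.08, 0.01), 1:4)
  sim <- gen_sections(atlas$labels, dens, n_sections = 3, seed = 5)
  prev <- NULL
  for (thr in c(10, 20, 40, 80, 120)) {
    masks <- lapply(seq_along(sim$ch3), function(s)
      segment_plaques(subtract_background(sim$ch3[[s]], sim$ch1[[s]]), thr))
    fa <- region_density(masks, sim$labels)$fractional_area
    if (!is.null(prev)) expect_true(all(fa <= prev + 1e-12))
    prev <- fa
  }
})

test_that("the pipeline recovers generated densities and their age ordering", {
  atlas <- grid_atlas(c(80, 80))
  dens <- stats::setNames(c(0.02, 0.05, 0.008, 0.1), 1:4)
  sim <- gen_sections(atlas$labels, dens, n_sections = 10, seed = 11)
  masks <- lapply(seq_along(sim$ch3), function(s)
    segment_plaques(subtract_background(sim$ch3[[s]], sim$ch1[[s]]), 20))
  est <- region_density(masks, sim$labels)
  rel_err <- abs(est$fractional_area - sim$truth$fractional_area) /
    sim$truth$fractional_area
  expect_true(all(rel_err <= 0.10))
  # synthetic age cohorts at increasing density: estimated medians increase
  meds <- vapply(seq_along(c(2, 3, 4)), function(i) {
    d <- stats::setNames(rep(c(0.01, 0.03, 0.06)[i], 4), 1:4)
    s <- gen_sections(atlas$labels, d, n_sections = 3, seed = 20 + i)
    m <- lapply(seq_along(s$ch3), function(k)
      segment_plaques(subtract_background(s$ch3[[k]], s$ch1[[k]]), 20))
    median(region_density(m, s$labels)$fractional_area)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
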