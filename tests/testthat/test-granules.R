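test_that("connected-component labeling honors connectivity", {
  diag2 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(max(label_components(diag2, 8)), 1)
  expect_equal(max(label_components(diag2, 4)), 2)
  # agrees with the EBImage labeller in 4-connectivity mode
  set.seed(12)
  m <- matrix(runif(400) > 0.6, 20, 20)
  ours <- label_components(m, 4)
  ebi <- EBImage::bwlabel(matrix(as.integer(m), 20))
  expect_equal(max(ours), max(ebi))
  # same partition: component memberships agree up to relabeling
  expect_equal(length(unique(paste(ours[m], ebi[m]))), max(ours))
})

test_that("segmentation finds squares with exact centroids and areas", {
  img <- matrix(0, 40, 40)
  img[5:7, 5:7] <- 1       # 3x3 at rows/cols 5..7
  img[20:22, 30:32] <- 1
  seg <- segment_channel(img, pixel_size_um = 0.1, threshold = 0.5)
  expect_equal(nrow(seg), 2)
  expect_equal(sort(seg$area_px), c(9L, 9L))
  expect_equal(seg$x_px[1], 6)  # column center
  expect_equal(seg$y_px[1], 6)
  expect_equal(seg$area_um2, c(0.09, 0.09))
  # empty mask is not an error
  expect_equal(nrow(segment_channel(matrix(0, 10, 10), 0.1,
                                    threshold = 0.5)), 0)
})

test_that("size filtering uses inclusive 1..2000 px bounds", {
  img <- matrix(0, 60, 60)
  img[1:40, 1:50] <- 1                      # 2000 px exactly
  seg <- segment_channel(img, 0.1, threshold = 0.5)
  expect_equal(seg$area_px, 2000L)
  img2 <- matrix(0, 60, 60)
  img2[1:40, 1:50] <- 1
  img2[41, 1] <- 1                          # grow to 2001 px (connected)
  seg2 <- segment_channel(img2, 0.1, threshold = 0.5)
  expect_equal(nrow(seg2), 0)
  # single pixel (size 1) is kept
  img3 <- matrix(0, 10, 10); img3[5, 5] <- 1
  expect_equal(segment_channel(img3, 0.1, threshold = 0.5)$area_px, 1L)
})

test_that("segmentation is translation equivariant", {
  img <- matrix(0, 50, 50)
  img[10:14, 10:16] <- 0.8
  img[30:31, 40:42] <- 0.8
  seg <- segment_channel(img, 0.1, threshold = 0.4)
  sh <- matrix(0, 50, 50)
  sh[10:14 + 3, 10:16 + 5] <- 0.8
  sh[30:31 + 3, 40:42 + 5] <- 0.8
  seg_sh <- segment_channel(sh, 0.1, threshold = 0.4)
  expect_equal(seg_sh$x_px, seg$x_px + 5)
  expect_equal(seg_sh$y_px, seg$y_px + 3)
  expect_equal(seg_sh$area_px, seg$area_px)
})

test_that("otsu auto-threshold segments planted discs", {
  objs <- data.frame(channel = c(1, 2), x = c(20, 70), y = c(25, 75),
                     radius_px = c(4, 6))
  im <- simulate_images(granule_image_config(objects = objs))
  seg <- segment_channel(im$channels[[1]], 0.1)  # threshold = "auto"
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$x_px - 20), 1)
  expect_lt(abs(seg$y_px - 25), 1)
  expect_lt(abs(seg$area_px / im$truth$area_px[1] - 1), 0.05)
})

test_that("pair distances find the nearest opposite-channel center", {
  a <- data.frame(label = 1L, x_px = 10, y_px = 10)
  b <- data.frame(label = 1:2, x_px = c(13, 30), y_px = c(14, 30))
  pd <- pair_distances(a, b, pixel_size_um = 0.1)
  expect_equal(pd$distance_um, 0.5)     # 3-4-5 triangle
  expect_equal(pd$label_b, 1L)
  # coincident centroids -> 0
  pd0 <- pair_distances(a, data.frame(label = 9L, x_px = 10, y_px = 10),
                        pixel_size_um = 0.1)
  expect_equal(pd0$distance_um, 0)
  expect_error(pair_distances(a, b), "pixel size")
  # empty B flagged, not an error
  pde <- pair_distances(a, b[0, ], pixel_size_um = 0.1)
  expect_equal(nrow(pde), 0)
  expect_true(attr(pde, "empty_b"))
})

test_that("pair distances equal a brute-force all-pairs minimum", {
  set.seed(14)
  a <- data.frame(label = 1:8, x_px = runif(8, 1, 100),
                  y_px = runif(8, 1, 100))
  b <- data.frame(label = 1:6, x_px = runif(6, 1, 100),
                  y_px = runif(6, 1, 100))
  pd <- pair_distances(a, b, pixel_size_um = 0.25)
  for (i in seq_len(nrow(a))) {
    d_all <- sqrt((a$x_px[i] - b$x_px)^2 + (a$y_px[i] - b$y_px)^2) * 0.25
    expect_equal(pd$distance_um[i], min(d_all))
  }
  # pairing is directional: a constructed counterexample
  a2 <- data.frame(label = 1:2, x_px = c(0, 10), y_px = c(0, 0))
  b2 <- data.frame(label = 1L, x_px = 4, y_px = 0)
  ab <- pair_distances(a2, b2, pixel_size_um = 1)
  ba <- pair_distances(b2, a2, pixel_size_um = 1)
  expect_equal(sort(ab$distance_um), c(4, 6))
  expect_equal(ba$distance_um, 4)      # asymmetric by design
})

test_that("Z/P ratio test matches the hand-computed z and Holm steps", {
  counts <- data.frame(genotype = c("WT", "mutA", "mutB"),
                       n_z = c(2, 8, 3), n_p = c(8, 2, 7))
  out <- zp_ratio_test(counts, reference = "WT")
  mutA <- out[out$genotype == "mutA", ]
  expect_equal(mutA$z, 0.6 / sqrt(0.05), tolerance = 1e-12)
  expect_equal(mutA$ratio, 4)
  # reference row carries no statistics
  expect_true(is.na(out$z[out$genotype == "WT"]))
  # identical to reference -> z = 0, p = 1, ratio preserved
  same <- zp_ratio_test(data.frame(genotype = c("WT", "m"),
                                   n_z = c(30, 30), n_p = c(60, 60)),
                        "WT")
  expect_equal(same$z[2], 0)
  expect_equal(same$p[2], 1)
  expect_equal(same$ratio[2], 0.5)
  # Holm adjustment across non-reference genotypes
  expect_equal(out$p_adj[out$genotype != "WT"],
               adjust_pvalues(out$p[out$genotype != "WT"], "Holm"))
  expect_warning(
    zp_ratio_test(data.frame(genotype = c("WT", "x"), n_z = c(5, 0),
                             n_p = c(5, 0)), "WT"),
    "zero granules")
})

test_that("area comparison summarizes boxes and detects planted shifts", {
  box <- area_compare(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5)))
  expect_equal(box$summary$median, c(3, 3))
  expect_equal(box$summary$q1, c(2, 2))
  expect_equal(box$summary$q3, c(4, 4))
  expect_equal(box$pairwise$t, 0)
  expect_equal(box$pairwise$p, 1)
  # degenerate variance with different means -> missing p
  deg <- area_compare(list(a = c(2, 2), b = c(3, 3)))
  expect_true(is.na(deg$pairwise$p))
  # planted 1.5x shift at n = 100 detected at p < 0.01 in >= 95% of runs
  set.seed(15)
  hits <- replicate(40, {
    x <- rlnorm(100, log(0.5), 0.3)
    y <- 1.5 * rlnorm(100, log(0.5), 0.3)
    area_compare(list(wt = x, mut = y))$pairwise$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("pooled synthetic Z/P counts reproduce the planted ratio", {
  # 6 Z objects (channel 1) and 3 P objects (channel 2), noise-free
  zx <- c(20, 40, 60, 80, 100, 120)
  objs <- rbind(
    data.frame(channel = 1, x = zx, y = 20, radius_px = 3),
    data.frame(channel = 2, x = c(30, 60, 90), y = 100, radius_px = 4)
  )
  im <- simulate_images(granule_image_config(dim = c(140L, 140L),
                                             objects = objs))
  nz <- nrow(segment_channel(im$channels[[1]], 0.1))
  np <- nrow(segment_channel(im$channels[[2]], 0.1))
  expect_equal(nz / np, 2)
})
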