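# one shared noisy synthetic cell for the selection checks
geom_q <- default_cell_geometry(c(9L, 128L, 128L))
preset_q <- condition_preset("untreated", 0.63, free_peptide_density = 12)
gt_q <- sample_ground_truth(preset_q, geom_q, 10, seed = 21)
st_q <- render_stack(gt_q, geom_q, seed = 22)
spots_mrna_q <- detect_spots(st_q$mrna)
spots_prot_q <- detect_spots(st_q$protein)

test_that("free-peptide selection excludes translation sites, keeps peptides", {
  free <- select_free_peptides(spots_prot_q, spots_mrna_q,
                               geom_q$cyto_mask, 500, 107.5)
  # no selected spot sits near a translating mRNA
  trans <- gt_q$mrna[gt_q$mrna$k > 0, ]
  for (i in seq_len(nrow(free))) {
    d <- sqrt((trans$y - free$y0[i])^2 + (trans$x - free$x0[i])^2)
    expect_gt(min(d), 500 / 107.5)
  }
  # every selected spot matches a true free peptide to within a voxel
  for (i in seq_len(nrow(free))) {
    d <- sqrt((gt_q$free$y - free$y0[i])^2 + (gt_q$free$x - free$x0[i])^2)
    expect_lt(min(d), 1)
  }
  # with no mRNA spots the exclusion is vacuous
  all_cyto <- select_free_peptides(spots_prot_q, spots_prot_q[0, ],
                                   geom_q$cyto_mask, 500, 107.5)
  expect_gte(nrow(all_cyto), nrow(free))
})

test_that("the lateral exclusion radius is honored", {
  mrna <- data.frame(z0 = 3, y0 = 20, x0 = 20)
  near <- data.frame(z0 = 3, y0 = 20, x0 = 20 + 50 / 107.5)  # 50 nm away
  far <- data.frame(z0 = 3, y0 = 20, x0 = 30)
  mask <- matrix(TRUE, 40, 40)
  kept <- select_free_peptides(rbind(near, far), mrna, mask,
                               exclusion_radius_nm = 300, pixel_nm = 107.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x0, 30)
})

test_that("single-peptide calibration averages after robust outlier removal", {
  mk <- function(I) data.frame(I_int = I, sigma_xy = rep(1, length(I)),
                               sigma_z = rep(1.2, length(I)))
  cal <- calibrate_single_peptide(mk(c(98, 100, 102)), min_spots = 3)
  expect_equal(cal$I_single, 100)
  expect_equal(cal$n_spots_used, 3)
  # the median +/- 3 MAD rule drops the gross outlier
  cal2 <- calibrate_single_peptide(mk(c(98, 100, 102, 1000)), min_spots = 3)
  expect_equal(cal2$I_single, 100)
  expect_equal(cal2$n_spots_used, 3)
  expect_error(calibrate_single_peptide(mk(numeric(0))), "calibration failed")
  expect_error(calibrate_single_peptide(NULL), "calibration failed")
})

test_that("a noiseless k = 6 translation site is counted to within 5%", {
  cal <- noiseless_calibration(i_single = 800)
  geom <- small_geometry(c(9L, 40L, 40L))
  gt <- manual_ground_truth(
    mrna = data.frame(id = 1L, z = 5, y = 20.4, x = 19.7,
                      translating = TRUE, k = 6L, mrna_intensity = 800))
  st <- render_stack(gt, geom, noise = no_noise(10), i_single_true = 800,
                     seed = 1)
  mspot <- detect_spots(st$mrna)
  expect_equal(nrow(mspot), 1)
  site <- quantify_translation_site(st$protein, mspot[1, ], cal)
  expect_lt(abs(site$N - 6) / 6, 0.05)
  expect_true(site$associated)
})

test_that("an mRNA with no protein signal gets a zero site", {
  cal <- noiseless_calibration(i_single = 800)
  geom <- small_geometry(c(9L, 40L, 40L))
  gt <- manual_ground_truth(
    mrna = data.frame(id = 1L, z = 5, y = 20, x = 20,
                      translating = FALSE, k = 0L, mrna_intensity = 800))
  st <- render_stack(gt, geom, noise = no_noise(10), seed = 1)
  mspot <- detect_spots(st$mrna)
  site <- quantify_translation_site(st$protein, mspot[1, ], cal)
  expect_equal(site$I_ts, 0)
  expect_equal(site$N, 0)
  expect_false(site$associated)
})

test_that("the mRNA-distance filter zeroes displaced protein spots", {
  cal <- noiseless_calibration(i_single = 800)
  geom <- small_geometry(c(9L, 40L, 40L))
  # a bright protein spot 5 px from the mRNA: inside the 11 x 11 box but
  # beyond the 3 px association distance
  gt <- manual_ground_truth(
    mrna = data.frame(id = 1L, z = 5, y = 20, x = 20,
                      translating = FALSE, k = 0L, mrna_intensity = 800),
    free = data.frame(id = 1L, z = 5, y = 20, x = 25, intensity = 4))
  st <- render_stack(gt, geom, noise = no_noise(10), i_single_true = 800,
                     seed = 1)
  mspot <- detect_spots(st$mrna)
  site <- quantify_translation_site(st$protein, mspot[1, ], cal,
                                    site_fit_params(max_distance_px = 3))
  expect_equal(site$I_ts, 0)
  expect_false(site$associated)
  expect_gt(site$distance_px, 3)
})

test_that("association uses the one-peptide threshold", {
  expect_false(classify_association(data.frame(N = 0.99)))
  expect_false(classify_association(data.frame(N = 0)))
  expect_true(classify_association(data.frame(N = 1)))
  expect_true(classify_association(data.frame(N = 5)))
})

test_that("nascent counts are linear in k for k = 1..20 (noiseless)", {
  cal <- noiseless_calibration(i_single = 800)
  geom <- small_geometry(c(9L, 96L, 96L))
  pos <- grid_positions(20, c(9, 96, 96), spacing = 16, margin = 12)
  gt <- manual_ground_truth(
    mrna = data.frame(id = 1:20, z = pos$z, y = pos$y + 0.2,
                      x = pos$x - 0.3, translating = TRUE, k = 1:20,
                      mrna_intensity = 800))
  st <- render_stack(gt, geom, noise = no_noise(10), i_single_true = 800,
                     seed = 1)
  mspots <- detect_spots(st$mrna)
  expect_equal(nrow(mspots), 20)
  for (i in seq_len(20)) {
    sp <- mspots[i, ]
    k_true <- gt$mrna$k[which.min((gt$mrna$y - sp$y0)^2 +
                                    (gt$mrna$x - sp$x0)^2)]
    site <- quantify_translation_site(st$protein, sp, cal)
    expect_lt(abs(site$N - k_true) / k_true, 0.05)
  }
})

test_that("estimated N is monotone in true load under noise", {
  ks <- c(1, 3, 6, 12)
  geom <- small_geometry(c(9L, 180L, 180L))
  n_each <- 100
  meanN <- numeric(length(ks))
  cal <- noiseless_calibration(i_single = 800)
  for (j in seq_along(ks)) {
    pos <- grid_positions(n_each, c(9, 180, 180), spacing = 16, margin = 12)
    gt <- manual_ground_truth(
      mrna = data.frame(id = seq_len(n_each), z = pos$z, y = pos$y,
                        x = pos$x, translating = TRUE, k = ks[j],
                        mrna_intensity = 800))
    st <- render_stack(gt, geom, noise = noise_model(), i_single_true = 800,
                       seed = 100 + j)
    Ns <- vapply(seq_len(n_each), function(i) {
      sp <- data.frame(z0 = gt$mrna$z[i], y0 = gt$mrna$y[i],
                       x0 = gt$mrna$x[i])
      quantify_translation_site(st$protein, sp, cal)$N
    }, numeric(1))
    meanN[j] <- mean(Ns)
  }
  expect_true(all(diff(meanN) > 0))
  # and roughly unbiased at the top end
  expect_lt(abs(meanN[4] - 12) / 12, 0.15)
})

test_that("quantification is scale-equivariant in the stack intensities", {
  geom <- small_geometry(c(9L, 48L, 96L))
  xs <- seq(12, by = 14, length.out = 6)
  gt <- manual_ground_truth(
    mrna = data.frame(id = 1L, z = 5, y = 36, x = 48, translating = TRUE,
                      k = 4L, mrna_intensity = 800),
    free = data.frame(id = 1:6, z = 5, y = 12, x = xs, intensity = 1))
  st <- render_stack(gt, geom, noise = no_noise(0), i_single_true = 800,
                     seed = 1)
  quantify_at_scale <- function(c_mult) {
    prot <- image_stack(st$protein$data * c_mult, geom$voxel_nm)
    pspots <- detect_spots(prot)
    mspot <- detect_spots(st$mrna)
    free <- select_free_peptides(pspots, mspot, geom$cyto_mask, 500, 107.5)
    cal <- calibrate_single_peptide(free, min_spots = 5)
    list(cal = cal, site = quantify_translation_site(prot, mspot[1, ], cal))
  }
  r1 <- quantify_at_scale(1)
  r3 <- quantify_at_scale(2.5)
  expect_equal(r3$cal$I_single / r1$cal$I_single, 2.5, tolerance = 1e-3)
  expect_equal(r3$site$I_ts / r1$site$I_ts, 2.5, tolerance = 1e-3)
  expect_equal(r3$site$N, r1$site$N, tolerance = 1e-3)
})
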