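test_that("configuration invariants are enforced", {
  expect_error(fjord_config(break_depth_m = 5, halocline_depth_m = 7),
               "exceed")
  expect_error(fjord_config(abundance_drop_factor = 0.5), ">= 1")
  expect_error(fjord_config(substrate_fraction_mean = 1.2), "\\[0, 1\\]")
  expect_error(fjord_config(echo_distance_mean_m = 0), "positive")
  expect_error(fjord_config(echo_distance_mean_m = -2), "positive")
  expect_s3_class(fjord_config(), "fjord_config")
})

test_that("water-mass presets must tile the column without gaps or overlaps", {
  p <- water_mass_presets()
  expect_silent(validate_presets(p, 480))
  gap <- p
  gap$depth_min_m[3] <- 30  # leaves 22-30 m uncovered
  expect_error(validate_presets(gap, 480), "gap")
  over <- p
  over$depth_min_m[3] <- 15
  expect_error(validate_presets(over, 480), "overlap")
  expect_error(validate_presets(p, 1000), "cover")
})

test_that("profile lookup is piecewise with boundaries going to the deeper layer", {
  p <- tibble::tibble(
    layer_id = 1:2, depth_min_m = c(0, 7), depth_max_m = c(7, 100),
    salinity = c(20, 32), salinity_grad = 0,
    temperature_C = 12, temperature_C_grad = 0,
    pH = 8, pH_grad = 0, oxygen_umol_l = 200, oxygen_umol_l_grad = 0,
    fluorescence = 1, fluorescence_grad = 0)
  prof <- water_mass_profile(p, c(3, 7, 50))
  expect_equal(prof$salinity, c(20, 32, 32))
  expect_equal(prof$layer_id, c(1L, 2L, 2L))
})

test_that("zero-noise casts reproduce the preset exactly", {
  cfg <- tiny_config(noise_sd = zero_noise)
  ctd <- generate_ctd_casts(cfg, flat_presets(pH = 8))
  expect_true(all(ctd$pH == 8))
  expect_true(all(ctd$salinity == 30))
  # depth monotone non-decreasing within each cast, at >= 1 record per metre
  for (s in unique(ctd$site)) {
    d <- ctd$depth_m[ctd$site == s]
    expect_true(all(diff(d) > 0))
    expect_gte(length(d), max(d) - min(d))
  }
})

test_that("generated pH honours preset ranges within sensor noise", {
  # two layers spanning 8.30 down to 7.86 at 198 m, like a mouth-of-fjord
  # station's observed pH envelope
  p <- tibble::tibble(
    layer_id = 1:2, depth_min_m = c(0, 7), depth_max_m = c(7, 200),
    salinity = c(24, 32), salinity_grad = 0,
    temperature_C = c(15, 11), temperature_C_grad = 0,
    pH = c(8.30, 7.90), pH_grad = c(0, -0.0002),
    oxygen_umol_l = c(230, 150), oxygen_umol_l_grad = 0,
    fluorescence = c(2, 0.2), fluorescence_grad = 0)
  cfg <- fjord_config(n_sites = 1, max_depths_m = 198,
                      noise_sd = c(salinity = 0.05, temperature_C = 0.05,
                                   pH = 0.01, oxygen_umol_l = 2,
                                   fluorescence = 0.05),
                      seed = 7)
  ctd <- generate_ctd_casts(cfg, p)
  expect_gte(min(ctd$pH), 7.86 - 3 * 0.01)
  expect_lte(max(ctd$pH), 8.33 + 3 * 0.01)
})

test_that("surveys are byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 9)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$ctd, s2$ctd)
  # and a different seed changes the draws
  s3 <- generate_survey(tiny_config(seed = 10))
  expect_false(identical(s1$annotations, s3$annotations))
})

test_that("survey structure matches the design: two transects per site, depths bounded", {
  cfg <- tiny_config()
  sv <- generate_survey(cfg)
  tab <- table(sv$frames$site, sv$frames$transect)
  expect_true(all(tab > 0))
  for (i in seq_along(cfg$sites)) {
    d <- sv$frames$ctd_depth_m[sv$frames$site == cfg$sites[i]]
    expect_lte(max(d), cfg$max_depths_m[i])
    expect_gte(min(d), 0)
  }
  expect_true(all(sv$frames$echo_distance_m > 0))
})

test_that("annotation area and count invariants hold by construction", {
  sv <- generate_survey(tiny_config(seed = 3))
  a <- sv$annotations
  expect_true(all(a$coral_covered_m2 <= a$available_substrate_m2 + 1e-12))
  expect_true(all(a$available_substrate_m2 <= a$analysed_area_m2 + 1e-12))
  expect_true(all(a$coral_covered_m2[a$coral_count == 0] == 0))
  expect_true(all(a$coral_count[a$coral_covered_m2 > 0] >= 1))
  m <- sv$measurements
  expect_true(all(m$length_m > 0) && all(m$width_m > 0))
})

test_that("zero occupancy yields a coral-free world end to end", {
  cfg <- tiny_config(occupancy_mean = 0)
  sv <- generate_survey(cfg)
  expect_true(all(sv$annotations$coral_count == 0))
  expect_true(all(sv$annotations$coral_covered_m2 == 0))
  geo <- exclude_overlaps(place_frames(sv$frames, cfg$camera, cfg$sites))
  ann <- sv$annotations[sv$annotations$frame_id %in%
                          geo$frame_id[geo$retained], ]
  patches <- collect_patches(ann, geo)
  expect_equal(nrow(patches), 0)
  expect_equal(nrow(detect_banks(patches, geo)), 0)
})

test_that("a unit drop factor leaves abundance flat across depth", {
  slopes <- vapply(1:20, function(s) {
    cfg <- fjord_config(n_sites = 1, max_depths_m = 100,
                        frames_per_metre = 1, abundance_drop_factor = 1,
                        break_depth_m = 50, measurable_fraction = 0,
                        seed = s)
    sv <- generate_survey(cfg)
    keep <- sv$frames$ctd_depth_m > cfg$halocline_depth_m + 3
    coef(lm(sv$annotations$coral_count[keep] ~
              sv$frames$ctd_depth_m[keep]))[2]
  }, numeric(1))
  tstat <- mean(slopes) / (sd(slopes) / sqrt(length(slopes)))
  expect_lt(abs(tstat), 3.5)
})

test_that("Monte-Carlo per-bin abundance matches the recorded ground truth", {
  cfg0 <- fjord_config(n_sites = 1, max_depths_m = 60, frames_per_metre = 1,
                       measurable_fraction = 0, seed = 1)
  gt <- generate_survey(cfg0)$ground_truth
  res <- sapply(1:200, function(s) {
    cfg <- fjord_config(n_sites = 1, max_depths_m = 60,
                        frames_per_metre = 1, measurable_fraction = 0,
                        seed = s)
    sv <- generate_survey(cfg)
    bin <- floor(sv$frames$ctd_depth_m / 10) * 10
    tapply(sv$annotations$coral_count, bin, mean)
  })
  mc <- rowMeans(res)
  se <- apply(res, 1, sd) / sqrt(ncol(res))
  expected <- gt$expected_bins$expected_abundance[
    match(as.numeric(rownames(res)), gt$expected_bins$bin_lower_m)]
  expect_true(all(abs(mc - expected) <= 3 * se))
})

test_that("withheld salinity propagates as missing values", {
  cfg <- tiny_config(salinity_na_sites = "LL")
  ctd <- generate_ctd_casts(cfg)
  expect_true(all(is.na(ctd$salinity[ctd$site == "LL"])))
  expect_true(all(!is.na(ctd$salinity[ctd$site != "LL"])))
})

test_that("write_survey emits the delimited tables and ground-truth sidecar", {
  dir <- withr::local_tempdir()
  sv <- generate_survey(tiny_config())
  write_survey(sv, dir)
  expect_true(all(file.exists(file.path(
    dir, c("ctd.csv", "frames.csv", "annotations.csv", "measured.csv",
           "ground_truth.json")))))
  back <- readr::read_csv(file.path(dir, "annotations.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sv$annotations))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$break_depth_m, sv$ground_truth$break_depth_m)
})
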