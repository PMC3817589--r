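make_frames <- function(n_per = 3, sites = c("A", "B")) {
  grid <- expand.grid(i = seq_len(n_per), transect = c("down", "up"),
                      site = sites, stringsAsFactors = FALSE)
  tibble::tibble(
    frame_id = sprintf("%s_%s_%02d", grid$site, grid$transect, grid$i),
    site = grid$site, transect = grid$transect,
    timestamp_s = 10 * seq_len(nrow(grid)),
    echo_distance_m = 1, ctd_depth_m = 5 * grid$i)
}

test_that("frames are placed with depth on y and one lane per site-transect", {
  fr <- make_frames()
  geo <- place_frames(fr, camera_model(60, 40), site_order = c("A", "B"))
  expect_equal(geo$y_m, fr$ctd_depth_m)
  lanes <- unique(geo[, c("site", "transect", "lane", "x_m")])
  lanes <- lanes[order(lanes$lane), ]
  expect_equal(lanes$site, c("A", "A", "B", "B"))
  expect_equal(lanes$transect, c("down", "up", "down", "up"))
  expect_true(all(diff(lanes$x_m) > 0))
  # a frame recorded at 124 m plots at exactly y = 124
  fr124 <- fr
  fr124$ctd_depth_m[1] <- 124
  expect_equal(place_frames(fr124, site_order = c("A", "B"))$y_m[1], 124)
})

test_that("unknown sites and empty inputs are handled", {
  fr <- make_frames()
  expect_error(place_frames(fr, site_order = "A"), "Unknown site")
  empty <- place_frames(fr[0, ], camera_model())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("x_m", "y_m", "retained") %in% names(empty)))
})

test_that("lanes never intersect and widths follow pixel bookkeeping", {
  fr <- make_frames(n_per = 10)
  fr$echo_distance_m <- runif(nrow(fr), 0.5, 2)
  cam <- camera_model(60, 40, 1920, 1080)
  geo <- place_frames(fr, cam, site_order = c("A", "B"))
  expect_equal(geo$width_m, geo$pixel_size_x_m * cam$pixel_width)
  expect_equal(geo$height_m, geo$pixel_size_y_m * cam$pixel_height)
  # rectangles from different lanes are disjoint in x
  by_lane <- split(geo, geo$lane)
  lims <- t(vapply(by_lane, function(g) {
    c(min(g$x_m - g$width_m / 2), max(g$x_m + g$width_m / 2))
  }, numeric(2)))
  lims <- lims[order(lims[, 1]), ]
  expect_true(all(lims[-1, 1] >= lims[-nrow(lims), 2] - 1e-12))
})

test_that("overlap exclusion retains by greedy zero-tolerance rule", {
  # two identical rectangles: first kept, second dropped
  geo <- tibble::tibble(
    frame_id = c("f1", "f2"), site = "A", transect = "down",
    timestamp_s = c(0, 10), lane = 1L, x_m = 0, y_m = 10,
    width_m = 1, height_m = 1)
  out <- exclude_overlaps(geo)
  expect_equal(out$retained, c(TRUE, FALSE))
  # disjoint rectangles 10 m apart are both kept
  geo$y_m <- c(10, 20)
  expect_equal(exclude_overlaps(geo)$retained, c(TRUE, TRUE))
  # touching rectangles (zero-area intersection) are both kept
  geo$y_m <- c(10, 11)
  expect_equal(exclude_overlaps(geo)$retained, c(TRUE, TRUE))
})

test_that("unit-height frames every 0.4 m retain every third frame", {
  n <- 30
  geo <- tibble::tibble(
    frame_id = sprintf("f%02d", 1:n), site = "A", transect = "down",
    timestamp_s = 10 * (1:n), lane = 1L, x_m = 0,
    y_m = 5 + 0.4 * (0:(n - 1)), width_m = 1, height_m = 1)
  out <- exclude_overlaps(geo)
  expect_equal(which(out$retained), seq(1, n, by = 3))
})

test_that("a positive tolerance admits bounded overlap", {
  geo <- tibble::tibble(
    frame_id = c("f1", "f2"), site = "A", transect = "down",
    timestamp_s = c(0, 10), lane = 1L, x_m = 0, y_m = c(10, 10.9),
    width_m = 2, height_m = 1)
  # intersection is 2 wide x 0.1 tall = 0.2 m^2
  expect_equal(exclude_overlaps(geo, tolerance = 0.1)$retained,
               c(TRUE, FALSE))
  expect_equal(exclude_overlaps(geo, tolerance = 0.25)$retained,
               c(TRUE, TRUE))
})

test_that("retained area within a lane never exceeds span times width", {
  cfg <- tiny_config(frames_per_metre = 2, seed = 5)
  sv <- generate_survey(cfg)
  geo <- exclude_overlaps(place_frames(sv$frames, cfg$camera, cfg$sites))
  ret <- geo[geo$retained, ]
  for (ln in unique(ret$lane)) {
    g <- ret[ret$lane == ln, ]
    span <- max(g$y_m + g$height_m / 2) - min(g$y_m - g$height_m / 2)
    expect_lte(sum(g$width_m * g$height_m), span * max(g$width_m) + 1e-9)
  }
})

test_that("greedy retention agrees with the interval-union oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- 40
    depths <- 5 + cumsum(runif(n, 0.2, 1.5))
    heights <- runif(n, 0.4, 1.2)
    geo <- tibble::tibble(
      frame_id = sprintf("f%02d", 1:n), site = "A", transect = "down",
      timestamp_s = 10 * (1:n), lane = 1L, x_m = 0, y_m = depths,
      width_m = runif(n, 0.8, 1.2), height_m = heights)
    out <- exclude_overlaps(geo)
    expect_equal(out$retained,
                 oracle_retain_1d(depths - heights / 2, depths + heights / 2))
  }
})

test_that("worldfiles encode scale and upper-left pixel centre", {
  geo <- tibble::tibble(frame_id = "f1", x_m = 10, y_m = 124, width_m = 2,
                        height_m = 1, pixel_size_x_m = 0.5,
                        pixel_size_y_m = 0.5)
  p <- worldfile_params(geo)
  expect_equal(p$A, 0.5)
  expect_equal(p$E, -0.5)
  expect_equal(p$B, 0)
  expect_equal(p$D, 0)
  expect_equal(p$C, 10 - 1 + 0.25)     # left edge + half pixel
  expect_equal(p$F, -124 + 0.5 - 0.25) # y-up map space, E negative
  txt <- worldfile_text(geo)
  expect_length(txt, 6)
  expect_equal(txt[2:3], c("0.0", "0.0"))
})

test_that("pixel size follows from width over pixel count", {
  cam <- camera_model(60, 40, 1920, 1080)
  fr <- tibble::tibble(frame_id = "f", site = "A", transect = "down",
                       timestamp_s = 0, echo_distance_m = 1,
                       ctd_depth_m = 50)
  geo <- place_frames(fr, cam, "A")
  expect_equal(geo$pixel_size_x_m, 1.1547005 / 1920, tolerance = 1e-6)
  expect_equal(worldfile_params(geo)$A, 0.000601407, tolerance = 1e-6)
})

test_that("worldfiles survive a write-parse round trip at emitted precision", {
  dir <- withr::local_tempdir()
  geo <- tibble::tibble(frame_id = "frame_x", site = "A",
                        transect = "down", timestamp_s = 0,
                        x_m = 3.14159, y_m = 271.828, width_m = 1.23,
                        height_m = 0.87, pixel_size_x_m = 1.23 / 1920,
                        pixel_size_y_m = 0.87 / 1080, retained = TRUE)
  paths <- write_worldfiles(geo, dir)
  expect_true(file.exists(file.path(dir, "frame_x.pgw")))
  parsed <- read_worldfile(paths[1])
  txt1 <- readLines(paths[1])
  txt2 <- rovcoral:::fmt_worldfile_num(unlist(parsed))
  expect_identical(txt1, unname(txt2))
  expect_lt(abs(parsed$A - 1.23 / 1920), 1e-12)
})
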