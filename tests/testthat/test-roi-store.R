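# Region-store data model, file round trips and acquisition utilities.

test_that("region store survives a write/read round trip", {
  fix <- sim_store(duration_s = 4, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_store(fix$store, path)
  back <- read_region_store(path)
  expect_identical(names(back$regions), names(fix$store$regions))
  for (rg in names(fix$store$regions)) {
    for (ch in names(fix$store$regions[[rg]])) {
      expect_equal(back$regions[[rg]][[ch]]$values,
                   fix$store$regions[[rg]][[ch]]$values,
                   tolerance = 1e-9)
      expect_equal(back$regions[[rg]][[ch]]$timestamps,
                   fix$store$regions[[rg]][[ch]]$timestamps,
                   tolerance = 1e-9)
    }
  }
  expect_equal(back$distance$metres, fix$store$distance$metres,
               tolerance = 1e-9)
  # row count = header + one row per (region, channel, frame)
  n_expected <- sum(vapply(fix$store$regions, function(chans) {
    sum(vapply(chans, function(cs) length(cs$values), integer(1)))
  }, integer(1)))
  expect_length(readLines(path), n_expected + 1L)
})

test_that("reader synthesizes the grey channel when absent", {
  fix <- sim_store(duration_s = 4, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_store(fix$store, path)
  df <- read.csv(path, colClasses = c(region = "character",
                                      channel = "character"))
  write.csv(df[df$channel != "Gy", ], path, row.names = FALSE)
  back <- read_region_store(path)
  for (rg in names(back$regions)) {
    expect_equal(back$regions[[rg]]$Gy$values,
                 fix$store$regions[[rg]]$Gy$values, tolerance = 1e-9)
  }
})

test_that("malformed region-store files are rejected with clear errors", {
  fix <- sim_store(duration_s = 4, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_store(fix$store, path)
  df <- read.csv(path, colClasses = c(region = "character",
                                      channel = "character"))

  bad <- df
  bad$channel[1] <- "X"
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p1, row.names = FALSE)
  expect_error(read_region_store(p1), "unknown channel")

  bad <- df[df$region == "forehead" & df$channel == "R", ][1:3, ]
  bad$timestamp_ms <- c(0, 10, 5)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_region_store(p2), "strictly increasing")

  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "value")], p3, row.names = FALSE)
  expect_error(read_region_store(p3), "missing column: value")

  expect_error(
    write_region_store(structure(list(participant_id = "x",
                                      state = "resting1",
                                      regions = list(),
                                      distance = NULL),
                                 class = "region_store"),
                       withr::local_tempfile()),
    "no regions")
})

test_that("ground-truth files validate contiguity and ranges", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(second = 0:59, hr_bpm = 70, spo2_pct = 97), p,
            row.names = FALSE)
  gt <- read_ground_truth(p)
  expect_length(gt$seconds, 60)

  write.csv(data.frame(second = c(0, 1, 3), hr_bpm = 70,
                       spo2_pct = 97), p, row.names = FALSE)
  expect_error(read_ground_truth(p), "contiguous")

  write.csv(data.frame(second = 0:2, hr_bpm = c(70, 500, 70),
                       spo2_pct = 97), p, row.names = FALSE)
  expect_error(read_ground_truth(p), "HR outside")

  write.csv(data.frame(second = 0:2, hr_bpm = 70,
                       spo2_pct = c(97, 101, 97)), p, row.names = FALSE)
  expect_error(read_ground_truth(p), "SpO2 outside")
})

test_that("grey channel is the RGB mean, permutation-invariant and bounded", {
  expect_equal(compute_grey(1, 1, 1), 1)
  expect_equal(compute_grey(0, 0, 3), 1)
  expect_equal(compute_grey(10, 20, 40), 70 / 3)
  set.seed(42)
  for (i in 1:20) {
    v <- runif(3, 0, 255)
    g <- compute_grey(v[1], v[2], v[3])
    expect_equal(g, compute_grey(v[3], v[1], v[2]))
    expect_gte(g, min(v))
    expect_lte(g, max(v))
  }
  expect_error(compute_grey(1, Inf, 1), "finite")
})

test_that("spatial pooling equals the brute-force pixel mean", {
  expect_equal(spatial_pool(matrix(c(2, 4, 6, 8), 2)), 5)
  expect_equal(spatial_pool(matrix(7.5, 3, 3)), 7.5)
  set.seed(7)
  patch <- matrix(runif(256), 16, 16)
  acc <- 0
  for (i in seq_len(nrow(patch))) {
    for (j in seq_len(ncol(patch))) acc <- acc + patch[i, j]
  }
  expect_equal(spatial_pool(patch), acc / 256)
  expect_error(spatial_pool(matrix(numeric(0), 0, 0)), "empty")
})

test_that("fps estimation counts frames per wall-clock second", {
  expect_equal(estimate_fps(seq(0, 999, length.out = 30)), 30L)
  expect_equal(estimate_fps(c(0, 500, 1000, 1500)), c(2L, 2L))
  expect_identical(estimate_fps(numeric(0)), integer(0))
  set.seed(9)
  ts <- sort(unlist(lapply(0:9, function(k) {
    k * 1000 + (0:11) * 1000 / 12 + runif(12, -20, 20)
  })))
  ts <- pmax(ts, 0)
  counts <- estimate_fps(ts)
  expect_equal(sum(counts), length(ts))
  expect_true(all(counts[1:10] %in% 11:13))
})

test_that("colour-to-IR box mapping scales, floors and clips", {
  expect_equal(map_colour_box_to_ir(c(0, 0, 1920, 1080)),
               c(0L, 0L, 512L, 424L))
  expect_equal(map_colour_box_to_ir(c(960, 540, 0, 0)),
               c(256L, 212L, 0L, 0L))
  expect_equal(map_colour_box_to_ir(c(3.75 * 100, 0, 0, 0))[1], 100L)
  expect_error(map_colour_box_to_ir(c(1900, 0, 100, 10)), "outside")
  # composing with exact inverse scaling recovers the box within 1 px
  set.seed(3)
  for (i in 1:20) {
    box <- c(runif(1, 0, 1000), runif(1, 0, 500),
             runif(1, 0, 800), runif(1, 0, 400))
    ir <- map_colour_box_to_ir(box)
    back <- c(ir[1] * 3.75, ir[2] * 1080 / 424,
              ir[3] * 3.75, ir[4] * 1080 / 424)
    expect_true(all(abs(back - box) <= c(3.75, 1080 / 424,
                                         3.75, 1080 / 424) + 1e-9))
  }
})
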