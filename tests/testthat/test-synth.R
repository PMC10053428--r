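test_that("a closed population keeps a constant cell count", {
  sim <- simulate_cells(synth_config(
    seed = 4, n_steps = 20, n_initial_cells = 12,
    division_prob = 0, disappearance_prob = 0, appearance_rate = 0
  ))
  st <- derive_statistics(sim$dataset)
  expect_equal(st$n_cells, rep(12L, 20))
  expect_equal(nrow(sim$dataset$tracks), 12L)
})

test_that("the same seed reproduces the simulation field-for-field", {
  cfg <- synth_config(seed = 31, n_steps = 15, n_initial_cells = 10,
                      division_prob = 0.05, disappearance_prob = 0.02,
                      appearance_rate = 0.8)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_equal(as.data.frame(a$dataset$observations),
               as.data.frame(b$dataset$observations))
  expect_equal(as.data.frame(a$events), as.data.frame(b$events))
  c2 <- simulate_cells(synth_config(seed = 32, n_steps = 15,
                                    n_initial_cells = 10))
  expect_false(isTRUE(all.equal(as.data.frame(a$dataset$observations),
                                as.data.frame(c2$dataset$observations))))
})

test_that("derived statistics equal the emitted table across many configs", {
  withr::local_seed(2024)
  for (rep in 1:50) {
    cfg <- synth_config(
      seed = sample.int(10000, 1), n_steps = sample(5:20, 1),
      n_initial_cells = sample(3:20, 1),
      division_prob = runif(1, 0, 0.08),
      disappearance_prob = runif(1, 0, 0.05),
      appearance_rate = runif(1, 0, 1.5)
    )
    sim <- simulate_cells(cfg)
    if (nrow(sim$dataset$tracks) == 0L) next
    expect_equal(as.data.frame(derive_statistics(sim$dataset)),
                 as.data.frame(sim$stats))
  }
})

test_that("divisions terminate the parent and produce exactly 2 daughters", {
  sim <- simulate_cells(synth_config(seed = 6, n_steps = 25,
                                     n_initial_cells = 20,
                                     division_prob = 0.06))
  ev <- sim$events
  div <- ev[ev$event == "division", ]
  expect_gt(nrow(div), 0L)
  by_parent <- split(div$track_id, paste(div$parent_id, div$time_step))
  expect_true(all(lengths(by_parent) == 2L))
  tr <- sim$dataset$tracks
  for (key in names(by_parent)) {
    p <- as.integer(strsplit(key, " ")[[1]][1])
    t <- as.integer(strsplit(key, " ")[[1]][2])
    expect_equal(tr$end_time[tr$track_id == p], t - 1L)
    expect_equal(tr$parent_id[tr$track_id %in% by_parent[[key]]],
                 c(p, p))
  }
  # event-log parent links match the dataset's parent column everywhere
  logged <- div$parent_id
  names(logged) <- as.character(div$track_id)
  from_tracks <- tr$parent_id[match(as.integer(names(logged)),
                                    tr$track_id)]
  expect_equal(unname(logged), from_tracks)
})

test_that("reflection keeps every center inside the field", {
  sim <- simulate_cells(synth_config(
    seed = 14, n_steps = 40, n_initial_cells = 15, step_sigma = 60,
    field_width = 300, field_height = 200, cell_box_size = 10
  ))
  ctr <- box_center(sim$dataset$observations)
  expect_true(all(ctr$x >= 0 & ctr$x <= 300))
  expect_true(all(ctr$y >= 0 & ctr$y <= 200))
  expect_true(all(sim$dataset$observations$left >= 0))
  expect_true(all(sim$dataset$observations$top <= 200))
})

test_that("zero-drift walks recover mean zero and the step scale", {
  sim <- simulate_cells(synth_config(
    seed = 100, n_steps = 51, n_initial_cells = 200, step_sigma = 5,
    division_prob = 0, disappearance_prob = 0, appearance_rate = 0
  ))
  v <- direction_vectors(sim$dataset)
  n <- nrow(v)
  expect_gte(n, 1e4)
  bound <- 4 * 5 / sqrt(n)
  expect_lt(abs(mean(v$dx)), bound)
  expect_lt(abs(mean(v$dy)), bound)
  expect_lt(abs(stats::sd(v$dx) - 5) / 5, 0.1)
  expect_lt(abs(stats::sd(v$dy) - 5) / 5, 0.1)
})

test_that("durotaxis bias shifts in-region vectors by the configured drift", {
  sigma <- 5
  b <- 2 * sigma
  band <- list(x0 = 0, y0 = 350, x1 = 1000, y1 = 650)
  sim <- durotaxis_scenario(
    synth_config(seed = 200, n_steps = 21, n_initial_cells = 150,
                 step_sigma = sigma, division_prob = 0,
                 disappearance_prob = 0, appearance_rate = 0),
    stiff_region = band, bias = c(0, b)
  )
  v <- direction_vectors(sim$dataset)
  inside <- v$y >= band$y0 & v$y < band$y1
  n_in <- sum(inside)
  expect_gte(n_in, 200)
  expect_lt(abs(mean(v$dy[inside]) - b), 4 * sigma / sqrt(n_in))
  # upward sign test: overwhelming majority of in-region steps go up
  p <- stats::binom.test(sum(v$dy[inside] > 0), n_in,
                         alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # regional histogram mass sits on the positive side, global is balanced
  part <- split_region(new_partition(1000, 1000), 1L, "horizontal", 350)
  part <- split_region(part, 3L, "horizontal", 650)
  lv <- partition_leaves(part)
  mid <- lv$region_id[lv$y0 == 350 & lv$y1 == 650]
  part <- select_region(part, mid)
  hs <- regional_histograms(part, sim$dataset)
  edges <- hs$regional$vertical$bin_edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  reg_counts <- hs$regional$vertical$counts
  expect_gt(sum(reg_counts[mids > 0]), sum(reg_counts[mids < 0]))
  expect_equal(mids[which.max(reg_counts)] > 0, TRUE)
})

test_that("zero bias reproduces the base simulation exactly", {
  cfg <- synth_config(seed = 300, n_steps = 10, n_initial_cells = 20)
  base <- simulate_cells(cfg)
  zero <- durotaxis_scenario(cfg,
    stiff_region = list(x0 = 0, y0 = 0, x1 = 1000, y1 = 1000),
    bias = c(0, 0))
  expect_equal(as.data.frame(base$dataset$observations),
               as.data.frame(zero$dataset$observations))
})

test_that("rasterized masks import back to the exact source boxes", {
  withr::local_seed(88)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    # non-overlapping integer boxes on a small field
    lefts <- seq(2, by = 12, length.out = n)
    obs <- dplyr::bind_rows(lapply(1:2, function(t) {
      box_observations(
        time_step = t, track_id = seq_len(n),
        left = lefts + t - 1, top = sample(20:60, n),
        height = sample(3:8, n, replace = TRUE),
        width = sample(3:9, n, replace = TRUE),
        img_height = 64, img_width = 64
      )
    }))
    ds <- build_trackset(obs)
    dir <- withr::local_tempdir()
    out <- rasterize_masks(ds, dir)
    back <- import_ctc(out$track_file, dir)
    expect_equal(as.data.frame(back), as.data.frame(ds$observations))
    # oracle cross-check on one mask
    mask <- celltracks:::read_label_mask(out$mask_paths[1])
    for (id in seq_len(n)) {
      bb <- brute_force_bbox(mask, id)
      row <- ds$observations[ds$observations$time_step == 1L &
                               ds$observations$track_id == id, ]
      expect_equal(bb$left, row$left)
      expect_equal(bb$top, row$top)
      expect_equal(bb$height, row$height)
      expect_equal(bb$width, row$width)
    }
  }
})

test_that("rasterization warns when boxes are snapped to the pixel grid", {
  obs <- box_observations(1, 1, 2.4, 10.2, 4, 4, 32, 32)
  ds <- build_trackset(obs)
  expect_warning(rasterize_masks(ds, withr::local_tempdir()), "snapped")
})

test_that("a static cell produces the documented track file", {
  obs <- box_observations(
    time_step = 1:2, track_id = 1, left = 3, top = 10, height = 4,
    width = 5, img_height = 20, img_width = 20
  )
  out <- rasterize_masks(build_trackset(obs), withr::local_tempdir())
  expect_equal(readLines(out$track_file), "1 0 1 0")
  expect_equal(length(out$mask_paths), 2L)
  # empty dataset -> empty track file, no masks
  empty <- build_trackset(box_observations(
    integer(), integer(), double(), double(), double(), double(),
    double(), double()))
  out0 <- rasterize_masks(empty, withr::local_tempdir())
  expect_equal(length(readLines(out0$track_file)), 0L)
})

test_that("the synth bundle emits every input format readably", {
  sim <- simulate_cells(synth_config(seed = 55, n_steps = 5,
                                     n_initial_cells = 6,
                                     field_width = 200,
                                     field_height = 200,
                                     cell_box_size = 8))
  dir <- withr::local_tempdir()
  # continuous centers get snapped to the mask pixel grid, with notice
  expect_warning(bundle <- write_synth_bundle(sim, dir, masks = TRUE),
                 "snapped")
  expect_warning(obs <- read_track_csv(bundle$tracks_csv), NA)
  expect_equal(nrow(obs), nrow(sim$dataset$observations))
  st <- read_statistic_csv(bundle$stats_csv)
  expect_equal(st$n_cells, sim$stats$n_cells)
  frames <- load_image_sequence(file.path(dir, "frames"))
  expect_equal(nrow(frames), 5L)
  imported <- suppressWarnings(
    import_ctc(bundle$ctc$track_file, file.path(dir, "ctc")))
  expect_setequal(unique(imported$track_id),
                  sim$dataset$tracks$track_id)
})
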