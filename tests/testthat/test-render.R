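test_that("view_config validates its controls", {
  cfg <- view_config()
  expect_equal(names(cfg$toggles),
               c("cell_point", "all_points", "cell_label", "cell_vector",
                 "cell_trajectory", "all_trajectories", "map_grid"))
  expect_true(cfg$toggles[["cell_point"]])
  expect_true(cfg$toggles[["cell_trajectory"]])
  expect_false(any(cfg$toggles[c("all_points", "cell_label", "map_grid")]))
  expect_error(view_config(image_alpha = 1.2), "image_alpha")
  expect_error(view_config(circle_radius = 0), "positive")
})

test_that("circle count equals the number of cells alive at the cursor", {
  withr::local_seed(1)
  for (seed in 1:20) {
    sim <- simulate_cells(synth_config(
      seed = seed + 500, n_steps = 12, n_initial_cells = 10,
      division_prob = 0.03, disappearance_prob = 0.03, appearance_rate = 0.5
    ))
    ds <- sim$dataset
    t <- sample(ds$t_min:ds$t_max, 1)
    svg <- render_trajectory_frame(ds, config = view_config(time_cursor = t))
    n_alive <- sum(ds$observations$time_step == t)
    expect_equal(
      count_svg_elements(svg, "//svg:circle[@class='cell-point']"),
      n_alive
    )
  }
})

test_that("dotted circles count the disappeared cells", {
  sim <- simulate_cells(synth_config(
    seed = 77, n_steps = 20, n_initial_cells = 15,
    division_prob = 0.02, disappearance_prob = 0.05
  ))
  ds <- sim$dataset
  t <- ds$t_max
  svg <- render_trajectory_frame(
    ds, config = view_config(time_cursor = t, all_points = TRUE)
  )
  n_gone <- sum(ds$tracks$end_time < t)
  expect_equal(
    count_svg_elements(svg, "//svg:circle[@class='gone-point']"),
    n_gone
  )
})

test_that("red elements belong exactly to the highlighted family", {
  ds <- toy_division_dataset()
  forest <- build_lineage_forest(ds)
  svg <- render_trajectory_frame(
    ds, forest,
    view_config(time_cursor = 3, highlight_ids = 4L,
                cell_trajectory = TRUE)
  )
  doc <- xml2::read_xml(svg)
  ns <- c(svg = "http://www.w3.org/2000/svg")
  red_circles <- xml2::xml_find_all(
    doc, "//svg:circle[@fill='#ff0000']", ns)
  fam <- family_of(forest, 4L) # {1, 4, 5}
  alive_fam <- intersect(fam, ds$observations$track_id[
    ds$observations$time_step == 3])
  expect_equal(length(red_circles), length(alive_fam))
  red_paths <- xml2::xml_find_all(
    doc, "//svg:polyline[@stroke='#ff0000']", ns)
  expect_setequal(
    as.integer(xml2::xml_attr(red_paths, "data-track")),
    intersect(fam, ds$tracks$track_id[ds$tracks$end_time >= 3 &
                                        ds$tracks$n_obs >= 2]))
})

test_that("toggles control exactly their element classes", {
  ds <- toy_division_dataset()
  blank <- render_trajectory_frame(ds, config = view_config(
    time_cursor = 2, cell_point = FALSE, cell_trajectory = FALSE
  ))
  doc <- xml2::read_xml(blank)
  expect_equal(length(xml2::xml_children(doc)), 0L)
  # alpha 0 suppresses the background element even when a file is given
  bg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), bg)
  svg0 <- render_trajectory_frame(ds, config = view_config(
    time_cursor = 2, image_alpha = 0), background = bg)
  expect_equal(count_svg_elements(svg0, "//svg:image"), 0L)
  svg1 <- render_trajectory_frame(ds, config = view_config(
    time_cursor = 2, image_alpha = 0.5), background = bg)
  expect_equal(count_svg_elements(svg1, "//svg:image"), 1L)
  # missing background warns and renders without it
  expect_warning(
    svg2 <- render_trajectory_frame(ds, config = view_config(
      time_cursor = 2), background = file.path(tempdir(), "nope.png")),
    "missing")
  expect_equal(count_svg_elements(svg2, "//svg:image"), 0L)
  # labels are id(birth)
  svg3 <- render_trajectory_frame(ds, config = view_config(
    time_cursor = 3, cell_label = TRUE))
  doc3 <- xml2::read_xml(svg3)
  labels <- xml2::xml_text(xml2::xml_find_all(
    doc3, "//svg:text[@class='cell-label']",
    c(svg = "http://www.w3.org/2000/svg")))
  expect_true("3(1)" %in% labels)
  expect_true("8(3)" %in% labels)
})

test_that("lineage layout obeys the leaf-row and mean rules", {
  single <- build_trackset(box_observations(
    time_step = 1:5, track_id = 1, left = 10, top = 40, height = 10,
    width = 10, img_height = 100, img_width = 100
  ))
  lay1 <- layout_lineage_forest(build_lineage_forest(single))
  expect_equal(lay1$segments$row, 0)
  expect_equal(c(lay1$segments$t0, lay1$segments$t1), c(1L, 5L))
  ds <- toy_division_dataset()
  lay <- layout_lineage_forest(build_lineage_forest(ds))
  s <- lay$segments
  # root 1's children sit on consecutive integer rows, root midway
  expect_setequal(s$row[s$track_id %in% c(4L, 5L)], c(0, 1))
  expect_equal(s$row[s$track_id == 1L], 0.5)
  leaf_ids <- setdiff(s$track_id, c(1L, 2L))
  expect_equal(sort(s$row[s$track_id %in% leaf_ids]),
               as.double(0:(lay$n_leaves - 1L)))
})

test_that("random forests lay out without segment overlap", {
  withr::local_seed(31)
  for (rep in 1:10) {
    ds <- random_forest_dataset(sample(10:60, 1))
    lay <- layout_lineage_forest(build_lineage_forest(ds))
    s <- lay$segments
    # same-row segments never overlap in time
    for (r in unique(s$row)) {
      seg <- s[s$row == r, ]
      if (nrow(seg) < 2L) next
      seg <- seg[order(seg$t0), ]
      expect_true(all(seg$t0[-1] > seg$t1[-nrow(seg)]))
    }
    # leaves occupy 0..n_leaves-1
    n_kids <- lengths(build_lineage_forest(ds)$children)
    expect_equal(length(unique(s$row[!(s$track_id %in%
      as.integer(names(n_kids)))])), lay$n_leaves)
  }
})

test_that("lineage view draws segments, connectors, cursor and highlights", {
  ds <- toy_division_dataset()
  forest <- build_lineage_forest(ds)
  lay <- layout_lineage_forest(forest)
  svg <- render_lineage_view(lay, time_cursor = 1,
                             highlight_ids = family_of(forest, 2L))
  expect_equal(count_svg_elements(svg, "//svg:line[@class='lineage-segment']"),
               nrow(lay$segments) - 3L)
  expect_equal(
    count_svg_elements(svg,
                       "//svg:line[@class='lineage-segment highlight']"),
    3L) # family {2, 6, 7}
  expect_equal(count_svg_elements(svg, "//svg:line[@class='time-cursor']"),
               1L)
  expect_error(render_lineage_view(lay, 99), "span")
  empty <- layout_lineage_forest(build_lineage_forest(build_trackset(
    box_observations(integer(), integer(), double(), double(), double(),
                     double(), double(), double()))))
  svg0 <- render_lineage_view(empty, 1)
  expect_equal(count_svg_elements(svg0, "//svg:line[@class='time-cursor']"),
               1L)
})

test_that("statistic view plots one polyline per visible column", {
  tab <- read_statistic_csv(
    system.file("extdata", "table1_stats.csv", package = "celltracks"))
  svg <- render_statistic_view(tab, time_cursor = 2)
  expect_equal(count_svg_elements(svg, "//svg:polyline[@class='stat-line']"),
               4L)
  svg2 <- render_statistic_view(tab, time_cursor = 2,
                                visible_columns = c("n_cells", "mse"))
  expect_equal(count_svg_elements(svg2, "//svg:polyline[@class='stat-line']"),
               2L)
  expect_error(render_statistic_view(tab, visible_columns = "bogus"),
               "unknown statistic column")
  # cursor annotation carries that row's exact values
  doc <- xml2::read_xml(svg)
  vals <- xml2::xml_text(xml2::xml_find_all(
    doc, "//svg:text[@class='cursor-value']",
    c(svg = "http://www.w3.org/2000/svg")))
  expect_true("n_cells = 5" %in% vals)
  expect_true("n_mitosis = 2" %in% vals)
  expect_true("mse = 4" %in% vals)
})

test_that("statistic view renders the four-histogram block", {
  sim <- simulate_cells(synth_config(seed = 12, n_steps = 8,
                                     n_initial_cells = 20))
  part <- select_region(new_partition(1000, 1000), 1L)
  hs <- regional_histograms(part, sim$dataset, t = 4)
  svg <- render_statistic_view(NULL, hs)
  for (cls in c("global-h", "global-v", "regional-h", "regional-v")) {
    expect_gt(count_svg_elements(
      svg, sprintf("//svg:rect[@class='hist-bar %s']", cls)), 0L)
  }
  # histograms only when no statistics are given
  expect_equal(count_svg_elements(svg, "//svg:polyline"), 0L)
})

test_that("animation export writes one deterministic frame per step", {
  sim <- simulate_cells(synth_config(seed = 8, n_steps = 3,
                                     n_initial_cells = 6))
  ds <- sim$dataset
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  frames <- export_animation(ds, out_dir = dir1)
  expect_equal(nrow(frames), ds$t_max - ds$t_min + 1L)
  expect_equal(basename(frames$path),
               sprintf("frame_%04d.svg", 1:3))
  export_animation(ds, out_dir = dir2)
  for (i in seq_len(nrow(frames))) {
    expect_identical(
      readBin(frames$path[i], "raw", file.size(frames$path[i])),
      readBin(file.path(dir2, basename(frames$path[i])), "raw",
              file.size(frames$path[i]))
    )
  }
  # frame t's trajectory panel embeds render_trajectory_frame at cursor t
  cfg <- view_config(time_cursor = 2L)
  traj <- render_trajectory_frame(ds, config = cfg)
  frame2 <- readChar(frames$path[2], file.size(frames$path[2]))
  expect_true(grepl(traj, frame2, fixed = TRUE))
})

test_that("family colors are a pure function of the root id", {
  expect_equal(family_color(1), family_color(21))
  expect_equal(length(unique(family_color(1:20))), 20L)
  ds <- toy_division_dataset()
  s1 <- render_trajectory_frame(ds, config = view_config(time_cursor = 2))
  s2 <- render_trajectory_frame(ds, config = view_config(time_cursor = 2))
  expect_identical(s1, s2)
})
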