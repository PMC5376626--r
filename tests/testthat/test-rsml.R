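# RSML serialization and ground-truth trait extraction.

test_that("write/read round-trips a simulated system", {
  s <- simulate(sample_parameters("fibrous", 21))
  f <- tempfile(fileext = ".rsml")
  write_rsml(s, f)
  s2 <- read_rsml(f)
  expect_length(s2$roots, length(s$roots))
  for (i in seq_along(s$roots)) {
    expect_equal(unname(s2$roots[[i]]$nodes), unname(s$roots[[i]]$nodes),
                 tolerance = 1e-9)
    expect_identical(s2$roots[[i]]$order, s$roots[[i]]$order)
  }
  g1 <- compute_ground_truth(s)
  g2 <- compute_ground_truth(s2)
  num <- setdiff(names(g1), "plant_type")
  expect_equal(as.numeric(g1[num]), as.numeric(g2[num]), tolerance = 1e-6)
})

test_that("XML nesting mirrors topology", {
  s <- axis_with_laterals(lat_positions = 50)
  f <- tempfile(fileext = ".rsml")
  write_rsml(s, f)
  doc <- xml2::xml_ns_strip(xml2::read_xml(f))
  top <- xml2::xml_find_all(doc, "./scene/plant/root")
  expect_length(top, 1)
  expect_length(xml2::xml_find_all(top[[1]], "./root"), 1)
})

test_that("writer rejects empty systems and unwritable paths", {
  expect_error(write_rsml(make_system(list()), tempfile()), "no roots")
  s <- straight_system()
  expect_error(write_rsml(s, "/nonexistent-dir-xyz/out.rsml"),
               "/nonexistent-dir-xyz/out.rsml")
})

test_that("missing diameter annotations fall back to the default", {
  s <- straight_system(diam = 0.5)
  f <- tempfile(fileext = ".rsml")
  write_rsml(s, f)
  txt <- readLines(f)
  txt <- txt[!grepl("<functions>|</functions>|<function |</function>|<sample ",
                    txt)]
  f2 <- tempfile(fileext = ".rsml")
  writeLines(txt, f2)
  expect_warning(s2 <- read_rsml(f2, default_diameter_mm = 0.123),
                 "diameter")
  expect_true(all(s2$roots[[1]]$nodes[, "diam"] == 0.123))
})

test_that("multi-plant files follow the multiple= flag", {
  s <- straight_system()
  f <- tempfile(fileext = ".rsml")
  write_rsml(s, f)
  txt <- readLines(f)
  i0 <- grep("<plant ", txt); i1 <- grep("</plant>", txt)
  plant_block <- txt[i0:i1]
  txt2 <- append(txt, plant_block, after = i1)
  f2 <- tempfile(fileext = ".rsml")
  writeLines(txt2, f2)
  expect_error(read_rsml(f2), "2 plants")
  expect_silent(s2 <- read_rsml(f2, multiple = "first"))
  expect_length(s2$roots, 1)
})

test_that("malformed XML and geometry-less roots are rejected", {
  f <- tempfile(fileext = ".rsml")
  writeLines("<rsml><scene><plant><root id='r1'", f)
  expect_error(read_rsml(f))
  writeLines(c("<rsml><metadata><unit>mm</unit></metadata><scene><plant>",
               "<root id='r7'></root></plant></scene></rsml>"), f)
  expect_error(read_rsml(f), "r7")
})

test_that("ground truth matches hand arithmetic on a built system", {
  s <- axis_with_laterals(d = 0.5)
  g <- compute_ground_truth(s)
  expect_equal(g$tot_root_length, 150)
  expect_equal(g$tot_1_order_length, 100)
  expect_equal(g$tot_2plus_order_length, 50)
  expect_identical(g$n_1_orders, 1L)
  expect_identical(g$n_2plus_orders, 5L)
  expect_equal(g$mean_2plus_order_density, 0.05)
  expect_equal(g$mean_2plus_order_length, 10)
  # perpendicular laterals on a vertical parent
  expect_equal(g$mean_2plus_order_angle, 90)
  expect_equal(g$width, 20)
  expect_equal(g$depth, 100)
})

test_that("systems without laterals report missing lateral traits", {
  g <- compute_ground_truth(straight_system())
  expect_identical(g$n_2plus_orders, 0L)
  expect_equal(g$tot_2plus_order_length, 0)
  expect_true(is.na(g$mean_2plus_order_length))
  expect_true(is.na(g$mean_2plus_order_diam))
  expect_true(is.na(g$mean_2plus_order_angle))
})

test_that("trait additivity and scale equivariance hold", {
  s <- simulate(sample_parameters("fibrous", 33))
  g <- compute_ground_truth(s)
  expect_equal(g$tot_root_length,
               g$tot_1_order_length + g$tot_2plus_order_length,
               tolerance = 1e-6)
  # delete laterals: total drops exactly by the lateral total
  axes <- Filter(function(r) r$order == 1L, s$roots)
  g_ax <- compute_ground_truth(make_system(axes, s$plant_type))
  expect_equal(g_ax$tot_root_length,
               g$tot_root_length - g$tot_2plus_order_length,
               tolerance = 1e-9)
  # scale all coordinates by k
  k <- 2.5
  scaled <- s
  scaled$roots <- lapply(s$roots, function(r) {
    r$nodes[, c("x", "y")] <- r$nodes[, c("x", "y")] * k
    r$insertion_position_mm <- r$insertion_position_mm * k
    r
  })
  gs <- compute_ground_truth(scaled)
  for (v in c("tot_root_length", "width", "depth", "mean_2plus_order_length"))
    expect_equal(gs[[v]], k * g[[v]], tolerance = 1e-9)
  expect_equal(gs$mean_2plus_order_density, g$mean_2plus_order_density / k,
               tolerance = 1e-9)
  expect_identical(gs$n_2plus_orders, g$n_2plus_orders)
  expect_equal(gs$mean_2plus_order_angle, g$mean_2plus_order_angle,
               tolerance = 1e-9)
})
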