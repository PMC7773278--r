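test_that("triangle_grid counts cells exactly and conserves totals", {
  empty <- triangle_grid(analyze_sequence(c(s = "QQ"), wl = 10), wl = 10)
  expect_equal(empty$total, 0L)
  expect_equal(dim(empty$counts), c(10L, 6L))
  expect_error(triangle_grid(analyze_sequence(c(s = "QQ"), wl = 10)),
               "wl must be given")

  m3 <- measures_of(rep("QQQQQQQQQQ", 3))
  g3 <- triangle_grid(m3)
  expect_equal(g3$total, 3L)
  expect_equal(sum(g3$counts > 0), 1L)
  expect_equal(g3$counts["10", "0"], 3L)

  m <- measures_of(random_windows(500, 20, seed = 2))
  g <- triangle_grid(m)
  expect_equal(g$total, 500L)
  expect_equal(sum(g$counts), 500L)
  expect_equal(sum(tidy(g)$count), 500L)
})

test_that("grids are additive over concatenated measure sets", {
  a <- measures_of(random_windows(200, 20, seed = 4))
  b <- measures_of(random_windows(300, 20, seed = 5))
  merged <- triangle_grid(dplyr::bind_rows(a, b))
  expect_equal(merged$counts,
               triangle_grid(a)$counts + triangle_grid(b)$counts)
  expect_equal(merged$total, 500L)
})

test_that("mixed window lengths are rejected", {
  a <- measures_of(random_windows(5, 20, seed = 1))
  b <- measures_of(random_windows(5, 10, seed = 1))
  expect_error(triangle_grid(dplyr::bind_rows(a, b)), "mix window lengths")
  expect_error(triangle_grid(a, wl = 10), "not 10")
})

test_that("occupied cells always satisfy the triangle shape constraint", {
  for (fix in list(polyq_atx1(), collagen_like(20, seed = 6),
                   generate_sequence("random_uniform", 300, seed = 6))) {
    wl <- if (fix$length < 40) 10L else 20L
    g <- triangle_grid(analyze_sequence(fix, wl = wl))
    cells <- dplyr::filter(tidy(g), count > 0)
    expect_true(all(cells$x <= wl * (1 - cells$y) + 1e-9))
  }
})

test_that("odd window lengths can exceed floor(wl/2) and extend the x axis", {
  distinct15 <- paste(aa_alphabet(strict = TRUE)[1:15], collapse = "")
  m <- analyze_sequence(c(s = distinct15), wl = 15)
  expect_equal(m$mmpr, 8L)
  g <- triangle_grid(m)
  expect_true(g$x_exceeds_half)
  expect_equal(g$x_max, 8L)
})

test_that("region occupancy applies strict thresholds as printed", {
  mk <- function(x, k, n = 1) tibble::tibble(
    id = "m", start = seq_len(n), wl = 20L, mmpr = as.integer(x),
    best_period = 1L, max_fraction = k / 20, mode_residue = "A",
    mode_count = as.integer(k))

  inside_all <- region_occupancy(triangle_grid(mk(10, 4)))
  expect_equal(inside_all$percent, c(100, 100, 100))
  expect_equal(attr(inside_all, "outside_percent"), 0)

  orange_only <- region_occupancy(triangle_grid(mk(7, 6)))
  expect_equal(orange_only$percent[orange_only$region == "orange"], 100)
  expect_equal(orange_only$percent[orange_only$region == "green"], 0)
  expect_equal(orange_only$percent[orange_only$region == "red"], 0)

  corner <- region_occupancy(triangle_grid(mk(0, 20)))
  expect_equal(corner$percent, c(0, 0, 0))
  expect_equal(attr(corner, "outside_percent"), 100)
  expect_equal(attr(corner, "outside_of"), "orange")

  expect_error(region_occupancy(triangle_grid(mk(0, 20)[0, ], wl = 20)),
               "no windows")
})

test_that("default regions are nested on every fixture dataset", {
  fixtures <- list(
    homo = generate_sequence("homorepeat", 60),
    di = generate_sequence("direpeat", 60),
    tandem = generate_sequence("tandem", 120, unit = "QLNAP",
                               mutation_rate = 0.2, seed = 31),
    collagen = collagen_like(40, seed = 31),
    random = generate_sequence("random_uniform", 300, seed = 31)
  )
  for (fix in fixtures) {
    occ <- region_occupancy(triangle_grid(analyze_sequence(fix, wl = 20)))
    pct <- stats::setNames(occ$percent, occ$region)
    expect_lte(pct["red"], pct["green"])
    expect_lte(pct["green"], pct["orange"])
    expect_equal(attr(occ, "outside_percent"), round(100 - pct[["orange"]], 2))
  }
})

test_that("thresholds calibrated at wl = 20 flag reports at other lengths", {
  g <- triangle_grid(analyze_sequence(polyq_atx1(), wl = 10))
  expect_warning(occ <- region_occupancy(g), "calibrated for wl = 20")
  expect_true(attr(occ, "wl_calibration_warning"))
  occ20 <- region_occupancy(triangle_grid(measures_of("QQQQQQQQQQQQQQQQQQQQ")))
  expect_false(attr(occ20, "wl_calibration_warning"))
})

test_that("grid TSV has y rows descending, x columns ascending, counts conserved", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- triangle_grid(analyze_sequence(c(s = "QQ"), wl = 10), wl = 10)
  write_grid_tsv(empty, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(dim(tab), c(10L, 7L))
  expect_equal(names(tab), c("y", as.character(0:5)))
  expect_true(all(tab[, -1] == 0))
  expect_equal(tab$y[1], 1)
  expect_equal(tab$y[10], 0.1)

  g <- triangle_grid(measures_of("QQQQQQQQQQ"))
  write_grid_tsv(g, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(tab$`0`[1], 1)
  expect_equal(sum(tab[, -1]), g$total)

  gr <- triangle_grid(measures_of(random_windows(100, 10, seed = 3)))
  write_grid_tsv(gr, f)
  expect_equal(sum(readr::read_tsv(f, show_col_types = FALSE)[, -1]), 100)
})

test_that("occupancy JSON carries regions, outside percentage and totals", {
  f <- withr::local_tempfile(fileext = ".json")
  occ <- region_occupancy(triangle_grid(measures_of(
    random_windows(50, 20, seed = 12))))
  write_occupancy_json(occ, f)
  obj <- jsonlite::read_json(f)
  expect_named(obj, c("red", "green", "orange", "outside_orange",
                      "total_windows", "wl"))
  expect_equal(obj$total_windows, 50)
  expect_equal(obj$outside_orange, 100 - obj$orange)
})

test_that("identical inputs produce byte-identical grid and report files", {
  out <- replicate(2, {
    m <- analyze_sequence(generate_sequence("tandem", 100, unit = "QN",
                                            mutation_rate = 0.3, seed = 77),
                          wl = 20)
    g <- triangle_grid(m)
    f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".json")
    write_grid_tsv(g, f1)
    write_occupancy_json(region_occupancy(g), f2)
    c(paste(readLines(f1), collapse = "\n"), paste(readLines(f2), collapse = "\n"))
  })
  expect_identical(out[, 1], out[, 2])
})
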