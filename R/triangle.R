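#' Aggregate window measures into the low complexity triangle grid
#'
#' Pools windows (across proteins, with no per-protein normalisation) into a
#' discrete count grid over all attainable (x, y) coordinates: x is the
#' integer MMPR, y the max-residue fraction, stored by its integer mode
#' count `k` (`y = k/wl`) so grid keys stay exact. The x axis spans
#' `0..floor(wl/2)`; for odd window lengths a window can exceed
#' `floor(wl/2)` (e.g. all-distinct residues at wl = 15 cost 8), in which
#' case the axis is extended to the observed maximum and the grid is
#' flagged.
#'
#' @param measures Measure tibble from [analyze_sequence()]; all rows must
#'   share one window length.
#' @param wl Window length; defaults to the one found in `measures`
#'   (required for an empty measure list).
#' @return An object of class `lct_grid`: window length `wl`, integer
#'   `counts` matrix (rows `k = 1..wl`, columns `x = 0..x_max`), `total`
#'   window count, `x_max`, and logical `x_exceeds_half`.
#' @export
#' @examples
#' triangle_grid(analyze_sequence(polyq_atx1(), wl = 10))
triangle_grid <- function(measures, wl = NULL) {
  wl_seen <- unique(measures$wl)
  if (length(wl_seen) > 1) {
    abort(paste0("measures mix window lengths: ",
                 paste(wl_seen, collapse = ", ")))
  }
  if (is.null(wl)) {
    if (length(wl_seen) == 0) abort("wl must be given for an empty measure list")
    wl <- wl_seen
  } else if (length(wl_seen) == 1 && wl_seen != wl) {
    abort(paste0("measures were computed at wl = ", wl_seen, ", not ", wl))
  }
  wl <- as.integer(wl)
  half <- wl %/% 2L
  x_obs <- if (nrow(measures)) max(measures$mmpr) else 0L
  x_max <- max(half, x_obs)
  counts <- matrix(0L, nrow = wl, ncol = x_max + 1L,
                   dimnames = list(k = as.character(seq_len(wl)),
                                   x = as.character(0:x_max)))
  if (nrow(measures)) {
    k <- as.integer(round(measures$max_fraction * wl))
    tab <- table(factor(k, levels = seq_len(wl)),
                 factor(measures$mmpr, levels = 0:x_max))
    counts[] <- as.integer(tab)
  }
  structure(
    list(wl = wl, counts = counts, total = as.integer(sum(counts)),
         x_max = as.integer(x_max), x_exceeds_half = x_obs > half),
    class = "lct_grid"
  )
}

#' @export
print.lct_grid <- function(x, ...) {
  cat("Low complexity triangle grid (wl = ", x$wl, ")\n", sep = "")
  cat("  windows: ", x$total, "; x axis 0..", x$x_max,
      "; occupied cells: ", sum(x$counts > 0), "\n", sep = "")
  if (x$x_exceeds_half) {
    cat("  note: observed MMPR exceeds floor(wl/2); x axis extended\n")
  }
  invisible(x)
}

#' Tidy a triangle grid into one row per cell
#'
#' @param x An `lct_grid`.
#' @param ... Unused.
#' @return Tibble with columns `x` (MMPR), `k` (mode count), `y` (`k/wl`)
#'   and `count`, covering every grid cell including empty ones.
#' @export
tidy.lct_grid <- function(x, ...) {
  wl <- x$wl
  grid <- tidyr::expand_grid(k = seq_len(wl), x_ = 0:x$x_max)
  counts <- as.integer(x$counts[cbind(grid$k, grid$x_ + 1L)])
  tibble::tibble(x = grid$x_, k = grid$k, y = grid$k / wl, count = counts)
}

#' One-row summary of a triangle grid
#'
#' @param x An `lct_grid`.
#' @param ... Unused.
#' @export
glance.lct_grid <- function(x, ...) {
  tibble::tibble(wl = x$wl, total_windows = x$total, x_max = x$x_max,
                 occupied_cells = sum(x$counts > 0),
                 max_count = if (x$total) max(x$counts) else 0L,
                 x_exceeds_half = x$x_exceeds_half)
}

#' Default nested triangle regions
#'
#' The three overlapping bottom-right regions used to summarise how much of
#' a dataset behaves like globular, non-biased sequence: red
#' (x > 8.5, y < 0.275) inside green (x > 7.5, y < 0.325) inside orange
#' (x > 6.5, y < 0.375). Both inequalities are strict. The thresholds are
#' absolute (x, y) values calibrated for window length 20.
#'
#' @return Tibble with columns `name`, `x_gt`, `y_lt`.
#' @export
#' @examples
#' lct_regions()
lct_regions <- function() {
  tibble::tibble(name = c("red", "green", "orange"),
                 x_gt = c(8.5, 7.5, 6.5),
                 y_lt = c(0.275, 0.325, 0.375))
}

#' Region occupancy of a triangle grid
#'
#' For each region, the percentage of windows with `x > x_gt` and
#' `y < y_lt` (strict, as the thresholds fall between attainable grid
#' values at wl = 20). The default regions are nested, so red% <= green% <=
#' orange% always holds. Also reported: the percentage of windows outside
#' the widest region. Percentages carry 2 decimal places.
#'
#' Thresholds were calibrated at window length 20; for any other window
#' length the occupancy is still computed with the same absolute thresholds
#' but the report is flagged (and a warning raised), since rescaled region
#' semantics are not defined.
#'
#' @param grid An `lct_grid`, or a measure tibble (aggregated on the fly).
#' @param regions Region tibble (`name`, `x_gt`, `y_lt`); defaults to
#'   [lct_regions()].
#' @return An `lct_occupancy` tibble: `region`, `windows`, `percent`, with
#'   attributes `total_windows`, `wl`, `outside_percent`, `outside_of` and
#'   `wl_calibration_warning`.
#' @export
#' @examples
#' g <- triangle_grid(analyze_sequence(generate_sequence("random_uniform",
#'   length = 200, seed = 1), wl = 20))
#' region_occupancy(g)
region_occupancy <- function(grid, regions = lct_regions()) {
  if (is.data.frame(grid)) grid <- triangle_grid(grid)
  stopifnot(inherits(grid, "lct_grid"))
  if (grid$total == 0) abort("no windows: the grid is empty")
  stopifnot(all(c("name", "x_gt", "y_lt") %in% names(regions)))
  cells <- tidy(grid)
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    sum(cells$count[cells$x > regions$x_gt[i] & cells$y < regions$y_lt[i]])
  }, numeric(1))
  pct <- round(100 * counts / grid$total, 2)
  # "outside" refers to the widest region: most windows, ties broken by the
  # most permissive thresholds (largest y_lt, then smallest x_gt)
  ord <- order(-counts, -regions$y_lt, regions$x_gt)
  widest <- ord[1]
  warn_flag <- grid$wl != 20L
  if (warn_flag) {
    warn(paste0("region thresholds are calibrated for wl = 20 but the grid",
                " uses wl = ", grid$wl,
                "; occupancy computed with the absolute thresholds"))
  }
  structure(
    tibble::tibble(region = regions$name, windows = as.integer(counts),
                   percent = pct),
    total_windows = grid$total,
    wl = grid$wl,
    outside_percent = round(100 - pct[widest], 2),
    outside_of = regions$name[widest],
    wl_calibration_warning = warn_flag,
    class = c("lct_occupancy", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.lct_occupancy <- function(x, ...) {
  cat("Triangle region occupancy (", attr(x, "total_windows"),
      " windows, wl = ", attr(x, "wl"), ")\n", sep = "")
  NextMethod()
  cat("outside ", attr(x, "outside_of"), ": ",
      sprintf("%.2f", attr(x, "outside_percent")), "%\n", sep = "")
  invisible(x)
}

#' One-row summary of an occupancy report
#'
#' @param x An `lct_occupancy`.
#' @param ... Unused.
#' @export
glance.lct_occupancy <- function(x, ...) {
  wide <- stats::setNames(as.list(x$percent), x$region)
  tibble::as_tibble(c(wide,
                      list(outside = attr(x, "outside_percent"),
                           total_windows = attr(x, "total_windows"),
                           wl = attr(x, "wl"))))
}

#' Write the triangle grid as a TSV matrix
#'
#' Rows are y values in descending order (1 down to 1/wl), columns are x
#' (MMPR) ascending; cells hold raw window counts. The first column labels
#' y (4 decimal places), the header row labels x.
#'
#' @param grid An `lct_grid`.
#' @param file Output path or connection.
#' @return `file`, invisibly.
#' @export
write_grid_tsv <- function(grid, file) {
  stopifnot(inherits(grid, "lct_grid"))
  m <- grid$counts[rev(seq_len(grid$wl)), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE))
  names(out) <- as.character(0:grid$x_max)
  out <- dplyr::bind_cols(
    tibble::tibble(y = sprintf("%.4f", rev(seq_len(grid$wl)) / grid$wl)),
    out
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Write an occupancy report as JSON
#'
#' Emits `{region: percent, ..., outside_<widest>: percent,
#' total_windows: n, wl: n}`.
#'
#' @param occupancy An `lct_occupancy`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_occupancy_json <- function(occupancy, file) {
  stopifnot(inherits(occupancy, "lct_occupancy"))
  obj <- c(stats::setNames(as.list(occupancy$percent), occupancy$region),
           stats::setNames(list(attr(occupancy, "outside_percent")),
                           paste0("outside_", attr(occupancy, "outside_of"))),
           list(total_windows = attr(occupancy, "total_windows"),
                wl = attr(occupancy, "wl")))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
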