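#' Decompose sequences into overlapping windows
#'
#' Windows of length `wl` start at positions `1, 1 + step, ...` while they
#' fit entirely inside the sequence; short terminal fragments are discarded,
#' so a sequence shorter than `wl` yields no windows (and no error). With
#' `step = 1` a sequence of length L yields `L - wl + 1` windows.
#'
#' @param records Tibble of protein records ([read_fasta()]), or a plain
#'   character vector of sequences (ids are then invented).
#' @param wl Window length (>= 2).
#' @param step Step between window starts (>= 1); the method's definition
#'   uses 1.
#' @return Tibble with columns `id`, `start` (1-based) and `window`.
#' @export
#' @examples
#' slide_windows(polyq_atx1(), wl = 10)
slide_windows <- function(records, wl, step = 1L) {
  records <- as_records(records)
  wl <- as.integer(wl); step <- as.integer(step)
  if (is.na(wl) || wl < 2) abort("wl must be an integer >= 2")
  if (is.na(step) || step < 1) abort("step must be an integer >= 1")
  purrr::map2_dfr(records$id, records$sequence, function(id, s) {
    L <- nchar(s)
    if (L < wl) {
      return(tibble::tibble(id = character(), start = integer(),
                            window = character()))
    }
    starts <- seq.int(1L, L - wl + 1L, by = step)
    tibble::tibble(id = id, start = starts,
                   window = substring(s, starts, starts + wl - 1L))
  })
}

# Accept either a record tibble or a bare character vector of sequences.
as_records <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    return(tibble::tibble(id = ids, desc = "", sequence = toupper(records),
                          length = nchar(records)))
  }
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  records
}

# Shared dispatch into the compiled scan: windows -> n x 4 integer matrix.
scan_windows <- function(windows) {
  stopifnot(is.character(windows))
  if (length(windows) == 0) {
    return(matrix(integer(), ncol = 4))
  }
  L <- unique(nchar(windows))
  if (length(L) != 1) abort("all windows must have the same length")
  if (L < 2) abort("windows must have length >= 2 (no admissible repeat period)")
  codes <- matrix(utf8ToInt(paste(windows, collapse = "")) - 65L,
                  ncol = L, byrow = TRUE)
  if (any(codes < 0L | codes > 25L)) {
    abort("windows must contain only uppercase letters A-Z")
  }
  repeat_scan(codes, 26L)
}

#' Minimum number of mutations to a perfect repeat (MMPR)
#'
#' For each candidate repeat period p in `1..floor(wl/2)`, window positions
#' are partitioned into modulo classes; the cost of period p is the number
#' of positions that would have to be substituted so that every class
#' carries a single residue (partial final repeat units allowed). MMPR is
#' the minimum cost over all periods; ties go to the smallest period.
#'
#' A perfect homorepeat scores 0 at period 1; a window of all-distinct
#' residues is as far from repetition as possible. Because the period-1
#' solution is always available, `mmpr <= wl * (1 - max_fraction)` — the
#' constraint that makes the (x, y) diagram a triangle.
#'
#' @param windows Character vector of equal-length windows (length >= 2).
#' @return Tibble with columns `window`, `mmpr`, `best_period`.
#' @export
#' @examples
#' mmpr(c("QQQQQQQQQQ", "QQQQHQHQQQ", "ACDEFGHIKL"))
mmpr <- function(windows) {
  m <- scan_windows(windows)
  tibble::tibble(window = windows, mmpr = m[, 1], best_period = m[, 2])
}

#' Fraction of the most frequent amino acid
#'
#' The highest single-residue multiplicity in the window divided by the
#' window length; ties between residues are broken alphabetically. This is
#' the y coordinate of the triangle, ranging from `1/wl` (all residues
#' distinct) to 1 (homorepeat).
#'
#' @inheritParams mmpr
#' @return Tibble with columns `window`, `max_fraction`, `mode_residue`.
#' @export
#' @examples
#' max_aa_fraction("QQQQHQHQQQ")
max_aa_fraction <- function(windows) {
  m <- scan_windows(windows)
  L <- if (length(windows)) nchar(windows[1]) else NA_integer_
  tibble::tibble(window = windows,
                 max_fraction = m[, 3] / L,
                 mode_residue = intToUtf8(m[, 4] + 65L, multiple = TRUE))
}

#' Per-window repeatability and composition measures
#'
#' Slides windows over every record and computes, for each window, the MMPR
#' (x axis) and the fraction of the most frequent amino acid (y axis).
#' Measures are pure functions of window content: identical windows always
#' score identically, wherever they occur.
#'
#' @inheritParams slide_windows
#' @return Tibble with one row per window: `id`, `start`, `wl`, `mmpr`,
#'   `best_period`, `max_fraction`, `mode_residue`, `mode_count`. Empty (but
#'   well-formed) when every record is shorter than `wl`.
#' @export
#' @examples
#' analyze_sequence(polyq_atx1(), wl = 10)
analyze_sequence <- function(records, wl = 20L, step = 1L) {
  win <- slide_windows(records, wl = wl, step = step)
  m <- scan_windows(win$window)
  tibble::tibble(
    id = win$id,
    start = win$start,
    wl = as.integer(wl),
    mmpr = as.integer(m[, 1]),
    best_period = as.integer(m[, 2]),
    max_fraction = as.numeric(m[, 3]) / as.integer(wl),
    mode_residue = intToUtf8(m[, 4] + 65L, multiple = TRUE),
    mode_count = as.integer(m[, 3])
  )
}
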