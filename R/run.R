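#' Run a full triangle analysis, mirroring the original server's rules
#'
#' End-to-end driver behind the command-line interface: reads one or more
#' FASTA inputs, enforces the server's input restrictions, analyses every
#' record at the chosen window length, pools the windows into one triangle
#' grid, and writes the requested outputs. The three server rules are:
#' at least one sequence; every sequence a valid amino-acid sequence; every
#' sequence at least 5 residues longer than the window length (applied per
#' record).
#'
#' @param input FASTA path(s), a literal FASTA string, or a record tibble.
#' @param wl Window length; restricted to the server menu
#'   `c(10, 15, 20, 25, 30)` unless `any_wl = TRUE` (the library functions
#'   themselves accept any `wl >= 2`).
#' @param step Window step (default 1).
#' @param regions Region tibble for occupancy; defaults to [lct_regions()].
#' @param out_dir Output directory; created if needed. `NULL` writes no
#'   files (results are still returned).
#' @param prefix File name prefix for outputs.
#' @param write_windows,write_grid,write_occupancy Which tables to emit
#'   (per-window TSV, grid TSV, occupancy JSON).
#' @param plot Also render the heatmap.
#' @param plot_format `"png"` or `"svg"`.
#' @param split Optional character vector of `"ID:START-END"` region specs
#'   (or one comma-separated string); each named record is replaced by the
#'   given sub-region(s), analysed separately.
#' @param strict_alphabet Reject the extended residue codes X/B/Z/U/O.
#' @param skip_invalid Drop records that fail the length rule (with a
#'   warning) instead of rejecting the whole run.
#' @param any_wl Lift the server's window-length menu restriction.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `records`, `measures`, `grid`,
#'   `occupancy` and the written `files`.
#' @export
#' @examples
#' res <- lct_run(polyq_atx1(), wl = 10, quiet = TRUE)
#' glance(res$occupancy)
lct_run <- function(input, wl = 20, step = 1, regions = lct_regions(),
                    out_dir = NULL, prefix = "lct",
                    write_windows = TRUE, write_grid = TRUE,
                    write_occupancy = TRUE, plot = FALSE,
                    plot_format = "png", split = NULL,
                    strict_alphabet = FALSE, skip_invalid = FALSE,
                    any_wl = FALSE, quiet = FALSE) {
  wl <- as.integer(wl)
  menu <- c(10L, 15L, 20L, 25L, 30L)
  if (!any_wl && !wl %in% menu) {
    abort(paste0("wl = ", wl, " is not in the supported menu (",
                 paste(menu, collapse = ", "),
                 "); use any_wl = TRUE to override"))
  }
  say <- function(...) if (!quiet) message(...)

  records <- if (is.data.frame(input)) {
    for (i in seq_len(nrow(input))) {
      validate_sequence(input$sequence[i], input$id[i],
                        strict_alphabet = strict_alphabet)
    }
    input
  } else {
    dplyr::bind_rows(lapply(input, read_fasta,
                            strict_alphabet = strict_alphabet))
  }
  if (nrow(records) == 0) abort("no sequences found in input")
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s) across inputs: ",
                 paste(dup, collapse = ", ")))
  }

  if (!is.null(split)) {
    records <- apply_splits(records, split)
  }

  # Server rule 3: every record at least 5 residues longer than the window.
  short <- records$id[nchar(records$sequence) < wl + 5L]
  if (length(short) > 0) {
    msg <- paste0("record '", short, "' is shorter than wl + 5 = ", wl + 5L,
                  " residues", collapse = "\n")
    if (skip_invalid) {
      warn(paste0("skipping records failing the length rule:\n", msg))
      records <- records[!records$id %in% short, , drop = FALSE]
      if (nrow(records) == 0) abort("no sequences left after skipping invalid records")
    } else {
      abort(msg)
    }
  }

  measures <- analyze_sequence(records, wl = wl, step = step)
  per_record <- dplyr::count(measures, .data$id)
  for (i in seq_len(nrow(per_record))) {
    say("  ", per_record$id[i], ": ", per_record$n[i], " windows")
  }
  grid <- triangle_grid(measures, wl = wl)
  occupancy <- region_occupancy(grid, regions = regions)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- function(ext) file.path(out_dir, paste0(prefix, ext))
    if (write_windows) {
      files["windows"] <- write_measures(measures, path("_windows.tsv"))
    }
    if (write_grid) {
      files["grid"] <- write_grid_tsv(grid, path("_grid.tsv"))
    }
    if (write_occupancy) {
      files["occupancy"] <- write_occupancy_json(occupancy, path("_occupancy.json"))
    }
    if (plot) {
      files["plot"] <- save_triangle(grid, path(paste0("_triangle.", plot_format)),
                                     format = plot_format, regions = regions)
    }
    say("wrote ", length(files), " file(s) to ", out_dir)
  }
  invisible(list(records = records, measures = measures, grid = grid,
                 occupancy = occupancy, files = files))
}

# Replace records named in "ID:START-END" specs by their sliced regions.
apply_splits <- function(records, split) {
  specs <- unlist(strsplit(split, ",", fixed = TRUE))
  parsed <- regmatches(specs, regexec("^(.+):([0-9]+)-([0-9]+)$", specs))
  bad <- vapply(parsed, function(p) length(p) == 0, logical(1))
  if (any(bad)) {
    abort(paste0("malformed split spec '", specs[bad][1],
                 "' (expected ID:START-END)"))
  }
  out <- list()
  replaced <- character(0)
  for (p in parsed) {
    out[[length(out) + 1]] <- slice_region(records, as.integer(p[3]),
                                           as.integer(p[4]), id = p[2])
    replaced <- c(replaced, p[2])
  }
  dplyr::bind_rows(records[!records$id %in% replaced, , drop = FALSE],
                   dplyr::bind_rows(out))
}
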