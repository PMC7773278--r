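#' Read protein sequences from FASTA
#'
#' Parses a (multi-record) FASTA file into a tibble with one row per
#' sequence. The record id is the first whitespace-delimited token of the
#' header; the remainder of the header is kept in `desc`. Sequences are
#' normalised to upper case, a single trailing `*` terminator is stripped
#' with a warning, and every residue is validated against [aa_alphabet()].
#'
#' @param file Path to a FASTA file, a connection, or a literal FASTA string
#'   (recognised when it contains a newline or starts with `>`).
#' @param strict_alphabet If `TRUE`, only the 20 standard residues are
#'   accepted; the default also admits `X`, `B`, `Z`, `U`, `O` as ordinary
#'   distinct symbols.
#' @return A tibble with columns `id`, `desc`, `sequence`, `length`, in file
#'   order.
#' @export
#' @examples
#' read_fasta(">p1\nQQQQQ\n>p2 ataxin fragment\nacdefg\n")
read_fasta <- function(file, strict_alphabet = FALSE) {
  if (is.character(file) && length(file) == 1 &&
      (grepl("\n", file) || startsWith(file, ">"))) {
    file <- textConnection(file)
    on.exit(close(file), add = TRUE)
  }
  recs <- tryCatch(
    seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                       whole.header = TRUE),
    error = function(e) abort(paste0("no sequences found in input (", conditionMessage(e), ")"))
  )
  if (length(recs) == 0) abort("no sequences found in input")
  headers <- vapply(recs, function(r) attr(r, "Annot"), character(1))
  headers <- sub("^>", "", headers)
  ids <- unname(sub("\\s.*$", "", headers))
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(vapply(recs, as.character, character(1)))

  if (any(!nzchar(ids))) {
    abort(paste0("record ", which(!nzchar(ids))[1], " has an empty id"))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }

  stripped <- grepl("\\*$", seqs)
  if (any(stripped)) {
    warn(paste0("stripped trailing '*' terminator from: ",
                paste(ids[stripped], collapse = ", ")))
    seqs[stripped] <- sub("\\*$", "", seqs[stripped])
  }
  for (i in seq_along(seqs)) {
    validate_sequence(seqs[i], ids[i], strict_alphabet = strict_alphabet)
  }
  tibble::tibble(id = ids, desc = unname(descs), sequence = unname(seqs),
                 length = nchar(unname(seqs)))
}

# One-record residue validation with positional diagnostics.
validate_sequence <- function(seq, id, strict_alphabet = FALSE) {
  if (!nzchar(seq)) abort(paste0("record '", id, "' has an empty sequence"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("-", "."))) {
    pos <- which(chars %in% c("-", "."))[1]
    abort(paste0("record '", id, "' contains gap character '", chars[pos],
                 "' at position ", pos,
                 ": the method is defined on ungapped sequences"))
  }
  ok <- chars %in% aa_alphabet(strict = strict_alphabet)
  if (!all(ok)) {
    pos <- which(!ok)[1]
    abort(paste0("record '", id, "' contains invalid character '",
                 chars[pos], "' at position ", pos))
  }
  invisible(TRUE)
}

#' Write protein records to FASTA
#'
#' @param records Tibble with at least `id` and `sequence` columns (as
#'   produced by [read_fasta()]); a non-empty `desc` is appended to the
#'   header after a space.
#' @param file Output path or connection.
#' @param width Sequence line wrap width.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(records, file, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  lines <- unlist(purrr::pmap(
    list(records$id, desc, records$sequence),
    function(id, d, s) {
      header <- if (nzchar(d)) paste0(">", id, " ", d) else paste0(">", id)
      starts <- seq(1, nchar(s), by = width)
      c(header, substring(s, starts, pmin(starts + width - 1, nchar(s))))
    }))
  writeLines(lines, file)
  invisible(file)
}

#' Extract a sub-region of each record
#'
#' Slices `start..end` (1-based, inclusive, the UniProt convention) out of
#' each selected record, returning new records whose ids carry the
#' coordinates as a suffix (`id/start-end`).
#'
#' @param records Tibble of protein records.
#' @param start,end 1-based inclusive coordinates; must satisfy
#'   `1 <= start <= end <= length` for every selected record.
#' @param id Optional id (or vector of ids) restricting which records are
#'   sliced; by default all records are.
#' @return A tibble of sliced records with the same columns.
#' @export
#' @examples
#' recs <- read_fasta(">p1\nABCDEFG\n")
#' slice_region(recs, 2, 4)
slice_region <- function(records, start, end, id = NULL) {
  if (!is.null(id)) {
    missing <- setdiff(id, records$id)
    if (length(missing) > 0) {
      abort(paste0("id(s) not found: ", paste(missing, collapse = ", ")))
    }
    records <- records[records$id %in% id, , drop = FALSE]
  }
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1 || length(end) != 1 || is.na(start) || is.na(end)) {
    abort("start and end must be single integers")
  }
  bad <- start < 1 | end < start | end > nchar(records$sequence)
  if (any(bad)) {
    abort(paste0("region ", start, "-", end, " out of range for record '",
                 records$id[which(bad)[1]], "' (length ",
                 nchar(records$sequence[which(bad)[1]]), ")"))
  }
  dplyr::mutate(records,
                id = paste0(.data$id, "/", start, "-", end),
                sequence = substr(.data$sequence, start, end),
                length = end - start + 1L)
}

#' Write per-window measures to a TSV table
#'
#' One row per window: source id, 1-based window start, window length, MMPR,
#' max-residue fraction (4 decimal places) and the most frequent residue.
#' Rows keep input order.
#'
#' @param measures Tibble from [analyze_sequence()].
#' @param file Output path or connection.
#' @return `file`, invisibly.
#' @export
write_measures <- function(measures, file) {
  out <- tibble::tibble(
    id = measures$id,
    start = measures$start,
    wl = measures$wl,
    mmpr = measures$mmpr,
    max_fraction = sprintf("%.4f", measures$max_fraction),
    mode_residue = measures$mode_residue
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Read a per-window measure table written by [write_measures()]
#'
#' @param file Path to the TSV table.
#' @return Tibble with columns `id`, `start`, `wl`, `mmpr`, `max_fraction`,
#'   `mode_residue`.
#' @export
read_measures <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    id = readr::col_character(),
    start = readr::col_integer(),
    wl = readr::col_integer(),
    mmpr = readr::col_integer(),
    max_fraction = readr::col_double(),
    mode_residue = readr::col_character()
  ), progress = FALSE)
}
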