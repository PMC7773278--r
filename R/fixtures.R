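#' Generate synthetic protein sequences with known complexity structure
#'
#' Seeded generators for the sequence classes whose triangle signatures are
#' known a priori, used to benchmark and test the analysis without external
#' data:
#'
#' * `homorepeat` — one residue repeated; every window lands at (0, 1).
#' * `direpeat` — two residues strictly alternating; even-length windows
#'   land at (0, 0.5).
#' * `tandem` — a unit tiled to `length`, then mutated at a per-position
#'   substitution rate (a mutated position never keeps its residue, so
#'   `mutation_rate` is an effective substitution rate); degeneracy moves
#'   windows toward the centre of the triangle.
#' * `random_uniform` — i.i.d. uniform over the 20 standard residues;
#'   windows concentrate in the bottom-right (high x, low y).
#' * `biased` — i.i.d. from a given residue composition.
#'
#' @param kind One of `"homorepeat"`, `"direpeat"`, `"tandem"`,
#'   `"random_uniform"`, `"biased"`.
#' @param length Sequence length.
#' @param residue Residue for `homorepeat` (single letter).
#' @param residues Two letters for `direpeat`; the sampling set for
#'   `random_uniform` and for substitutions in `tandem` (default: the 20
#'   standard residues).
#' @param unit Repeat unit string for `tandem`.
#' @param mutation_rate Per-position substitution probability in `[0, 1]`
#'   (`tandem` only).
#' @param composition Named residue frequency vector summing to 1
#'   (`biased` only).
#' @param seed Integer seed; a fixed seed makes the output byte-for-byte
#'   reproducible without touching the global RNG state.
#' @param id Record id; a descriptive default is built from the config.
#' @return A one-row record tibble (`id`, `desc`, `sequence`, `length`).
#' @export
#' @examples
#' generate_sequence("homorepeat", length = 30)
#' generate_sequence("tandem", length = 60, unit = "GAY", mutation_rate = 0.1,
#'                   seed = 42)
generate_sequence <- function(kind = c("homorepeat", "direpeat", "tandem",
                                       "random_uniform", "biased"),
                              length, residue = "Q", residues = NULL,
                              unit = NULL, mutation_rate = 0,
                              composition = NULL, seed = NULL, id = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (is.na(length) || length < 1) abort("length must be a positive integer")
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("mutation_rate must be in [0, 1]")
  }
  gen <- function() {
    switch(kind,
      homorepeat = {
        stopifnot(nchar(residue) == 1)
        strrep(residue, length)
      },
      direpeat = {
        if (is.null(residues)) residues <- c("A", "B")
        stopifnot(base::length(residues) == 2, residues[1] != residues[2])
        substr(strrep(paste0(residues[1], residues[2]),
                      ceiling(length / 2)), 1, length)
      },
      tandem = {
        if (is.null(unit) || !nzchar(unit)) abort("tandem needs a unit string")
        s <- substr(strrep(unit, ceiling(length / nchar(unit))), 1, length)
        mutate_sequence(s, mutation_rate,
                        if (is.null(residues)) .aa_standard else residues)
      },
      random_uniform = {
        pool <- if (is.null(residues)) .aa_standard else residues
        paste(sample(pool, length, replace = TRUE), collapse = "")
      },
      biased = {
        if (is.null(composition) || is.null(names(composition))) {
          abort("biased needs a named composition vector")
        }
        if (abs(sum(composition) - 1) > 1e-8) {
          abort("composition must sum to 1")
        }
        paste(sample(names(composition), length, replace = TRUE,
                     prob = composition), collapse = "")
      }
    )
  }
  s <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  if (is.null(id)) {
    id <- paste0(kind, "_", length,
                 if (kind == "homorepeat") paste0("_", residue) else "",
                 if (kind == "tandem") paste0("_", unit) else "",
                 if (!is.null(seed)) paste0("_s", seed) else "")
  }
  tibble::tibble(id = id, desc = paste0("synthetic ", kind),
                 sequence = toupper(s), length = nchar(s))
}

# Substitute each position independently with probability `rate`; the
# replacement is drawn from `pool` excluding the current residue, so every
# mutation is a real substitution.
mutate_sequence <- function(s, rate, pool) {
  if (rate == 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(pool, chars[i])
    chars[i] <- if (length(alt)) sample(alt, 1) else chars[i]
  }
  paste(chars, collapse = "")
}

#' The ataxin-1 polyQ region worked example
#'
#' The wild-type human ataxin-1 (ATX1) polyglutamine tract at positions
#' 197-225: 27 glutamines with two inserted histidines, `[Q]12 H Q H [Q]14`
#' (29 residues). A classic homorepeat whose windows sit in the top-left
#' corner of the triangle: at window length 10, MMPR is 0 for all-glutamine
#' windows and rises to 2 when both histidines fall inside a window.
#'
#' @return A one-row record tibble.
#' @export
#' @examples
#' polyq_atx1()
polyq_atx1 <- function() {
  s <- paste0(strrep("Q", 12), "HQH", strrep("Q", 14))
  tibble::tibble(id = "ATX1_polyQ_197-225",
                 desc = "human ataxin-1 polyglutamine region, [Q]12 H Q H [Q]14",
                 sequence = s, length = nchar(s))
}

#' A collagen-like Gly-X-Y tandem region
#'
#' Emulates the statistical structure of a collagen triple-helical region:
#' every third residue is glycine and the X/Y positions are drawn at random
#' per unit. At window length 20 at least `floor(20/3) = 6` glycines fall in
#' every window, so the max-residue fraction sits mostly in 0.3-0.4 while
#' imperfect periodicity keeps MMPR moderate.
#'
#' @param n_units Number of Gly-X-Y units (>= 7, so that at least one full
#'   window of length 20 exists).
#' @param seed Integer seed for the X/Y draws.
#' @return A one-row record tibble of length `3 * n_units`.
#' @export
#' @examples
#' collagen_like(10, seed = 1)
collagen_like <- function(n_units, seed = NULL) {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 7) abort("n_units must be >= 7")
  gen <- function() {
    xy <- matrix(sample(.aa_standard, 2 * n_units, replace = TRUE), nrow = 2)
    paste(paste0("G", xy[1, ], xy[2, ]), collapse = "")
  }
  s <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tibble::tibble(id = paste0("collagen_like_", n_units, "u",
                             if (!is.null(seed)) paste0("_s", seed) else ""),
                 desc = "synthetic Gly-X-Y tandem region",
                 sequence = s, length = nchar(s))
}
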