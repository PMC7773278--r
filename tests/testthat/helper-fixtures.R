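# Equal-length random windows over an alphabet, reproducible under `seed`.
random_windows <- function(n, wl, alphabet = aa_alphabet(strict = TRUE),
                           seed = NULL) {
  gen <- function() {
    m <- matrix(sample(alphabet, n * wl, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Wrap windows in a measure-tibble shape for triangle_grid() tests.
measures_of <- function(windows, wl = nchar(windows[1])) {
  analyze_sequence(stats::setNames(windows, paste0("w", seq_along(windows))),
                   wl = wl)
}
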