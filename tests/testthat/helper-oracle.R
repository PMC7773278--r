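# Independent brute-force oracle for the repeatability score: the minimum
# Hamming distance from `window` to any string obtained by tiling any unit
# of length <= floor(L/2) over `alphabet`. Enumerates units explicitly and
# never touches the modulo-class implementation it checks.
#
# Restricting `alphabet` to the letters present in the window is lossless:
# a unit letter absent from the window matches zero positions, so swapping
# it for any letter that does occur can only lower the distance.
mmpr_oracle <- function(window,
                        alphabet = sort(unique(strsplit(window, "")[[1]]))) {
  chars <- strsplit(window, "")[[1]]
  L <- length(chars)
  best <- L
  for (p in seq_len(L %/% 2)) {
    units <- as.matrix(do.call(
      expand.grid, c(rep(list(alphabet), p), stringsAsFactors = FALSE)))
    for (i in seq_len(nrow(units))) {
      tiled <- rep(units[i, ], length.out = L)
      best <- min(best, sum(tiled != chars))
    }
  }
  best
}

# Vectorised form of the same oracle: minimum tiling distance for every
# string of length L over `alphabet`, returned in expand.grid order
# together with the windows themselves.
oracle_exhaustive <- function(L, alphabet) {
  strs <- as.matrix(do.call(
    expand.grid, c(rep(list(alphabet), L), stringsAsFactors = FALSE)))
  tiled <- NULL
  for (p in seq_len(L %/% 2)) {
    units <- as.matrix(do.call(
      expand.grid, c(rep(list(alphabet), p), stringsAsFactors = FALSE)))
    tiled <- rbind(tiled,
                   t(apply(units, 1, function(u) rep(u, length.out = L))))
  }
  best <- rep(L, nrow(strs))
  for (j in seq_len(nrow(tiled))) {
    d <- rowSums(strs != matrix(tiled[j, ], nrow(strs), L, byrow = TRUE))
    best <- pmin(best, d)
  }
  list(windows = do.call(paste0, as.data.frame(strs)),
       mmpr = as.integer(best))
}
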