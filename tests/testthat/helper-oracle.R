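# Independent exhaustive oracle for formula enumeration: materialises the
# whole C/H/N/O/S lattice (default assignment ranges), filters it by the
# validity rules written out directly, and answers candidate queries by a
# plain mass-window scan.  Deliberately brute force and independent of the
# package's H-solving enumeration path.

.oracle_cache <- new.env(parent = emptyenv())

oracle_lattice <- function() {
  if (!is.null(.oracle_cache$lattice)) {
    return(.oracle_cache$lattice)
  }
  g <- expand.grid(C = 1:60, H = 1:120, N = 0:5, O = 0:30, S = 0:2,
                   KEEP.OUT.ATTRS = FALSE)
  hc <- g$H / g$C
  oc <- g$O / g$C
  nc <- g$N / g$C
  sc <- g$S / g$C
  dbe <- 1 + g$C - g$H / 2 + g$N / 2
  keep <- hc >= 0.3 & hc <= 2.25 & oc <= 1.2 & nc <= 0.5 & sc <= 0.2 &
    dbe >= 0 & dbe <= 40 & (g$H + g$N) %% 2L == 0L
  g <- g[keep, , drop = FALSE]
  mass <- g$C * 12 + g$H * 1.00782503207 + g$N * 14.0030740048 +
    g$O * 15.9949146196 + g$S * 31.97207100
  g$mz <- mass - 1.00782503207 + 0.00054857990946
  g$key <- paste(g$C, g$H, g$N, g$O, g$S, 0L, sep = ".")
  .oracle_cache$lattice <- g
  g
}

oracle_candidates <- function(mz, tolerance_ppm) {
  g <- oracle_lattice()
  hit <- abs(g$mz - mz) / mz * 1e6 <= tolerance_ppm
  sort(g$key[hit])
}
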