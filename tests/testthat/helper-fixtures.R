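# Small in-code fixtures shared across the suite.

# Build a DartSet from a character layout: "1", "0", "?" per cell.
makeDart <- function(rows, genotypes = NULL, markers = NULL,
                     missingCap = 1, ...) {
  cells <- strsplit(rows, "")
  m <- do.call(rbind, lapply(cells, function(r) {
    r[r == "?"] <- NA
    as.integer(r)
  }))
  rownames(m) <- genotypes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- markers %||% paste0("m", seq_len(ncol(m)))
  DartSet(m, missingCap = missingCap, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A structureless binary matrix (single panmictic population).
randomCalls <- function(n, L, p = 0.5) {
  m <- matrix(rbinom(n * L, 1, p), n, L,
              dimnames = list(paste0("g", seq_len(n)),
                              paste0("m", seq_len(L))))
  m
}

# Write a small delimited grid file for the IO tests.
writeGridFile <- function(cells, path, delim = "\t",
                          genotypes = paste0("g", seq_len(nrow(cells))),
                          markers = paste0("m", seq_len(ncol(cells)))) {
  lines <- c(paste(c("id", markers), collapse = delim),
             vapply(seq_len(nrow(cells)), function(i)
               paste(c(genotypes[i], cells[i, ]), collapse = delim), ""))
  writeLines(lines, path)
  path
}

# Independent AMOVA oracle: literal evaluation of the sums-of-squares
# definitions with explicit loops (no shared code with amova()).
amovaOracle <- function(d, pops) {
  n <- nrow(d)
  ss <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss <- ss + d[i, j]^2
  ssTotal <- ss / n
  ssWithin <- 0
  for (g in unique(pops)) {
    idx <- which(pops == g)
    sg <- 0
    if (length(idx) > 1)
      for (a in seq_along(idx)[-length(idx)])
        for (b in (a + 1):length(idx))
          sg <- sg + d[idx[a], idx[b]]^2
    ssWithin <- ssWithin + sg / length(idx)
  }
  G <- length(unique(pops))
  sizes <- as.numeric(table(pops))
  msA <- (ssTotal - ssWithin) / (G - 1)
  msW <- ssWithin / (n - G)
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  Vb <- msW
  Va <- (msA - msW) / n0
  list(ssAmong = ssTotal - ssWithin, ssWithin = ssWithin, ssTotal = ssTotal,
       Va = Va, Vb = Vb)
}
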