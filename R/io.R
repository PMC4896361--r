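## Tabular and tree I/O. Files are genotypes-in-rows: first row marker
## (or trait) ids, first column genotype ids. Delimiter auto-detected
## (tab/comma/semicolon) unless given.

detectDelim <- function(path) {
  first <- readLines(path, n = 1L)
  for (d in c("\t", ",", ";"))
    if (grepl(d, first, fixed = TRUE)) return(d)
  stop("cannot detect delimiter in ", path)
}

readGrid <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detectDelim(path)
  tab <- read.table(path, sep = delim, header = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
  rn <- tab[-1, 1]
  cn <- as.character(tab[1, -1])
  if (anyDuplicated(cn)) stop("duplicated marker/trait id(s): ",
                              paste(unique(cn[duplicated(cn)]), collapse = ", "))
  if (anyDuplicated(rn)) stop("duplicated genotype id(s): ",
                              paste(unique(rn[duplicated(rn)]), collapse = ", "))
  m <- as.matrix(tab[-1, -1, drop = FALSE])
  dimnames(m) <- list(rn, cn)
  m
}

#' Read a dominant marker matrix
#'
#' Reads a genotypes-by-markers table of ternary band calls: `1` (present),
#' `0` (absent) and a missing token (`?` by default; `NA` and the empty
#' string are always accepted). The first row holds marker ids, the first
#' column genotype ids. Markers whose missing fraction exceeds `missingCap`
#' are flagged with a warning (dropped if `dropOverCap`).
#'
#' @param path file path (TSV/CSV/;SV; delimiter auto-detected).
#' @param delim delimiter override, e.g. `"\t"`.
#' @param missingToken token(s) denoting a missing call.
#' @inheritParams DartSet
#' @return a [DartSet-class].
#' @export
readMarkerMatrix <- function(path, delim = NULL, missingToken = "?",
                             missingCap = 0.28, dropOverCap = FALSE) {
  m <- readGrid(path, delim)
  v <- m
  v[] <- trimws(m)
  miss <- array(v %in% c(missingToken, "NA", ""), dim(m))
  ok <- miss | array(v %in% c("0", "1"), dim(m))
  if (any(!ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown call token '%s' at genotype '%s', marker '%s'",
                 v[!ok][1], rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  calls <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  calls[!miss] <- as.integer(v[!miss])
  DartSet(calls, missingCap = missingCap, dropOverCap = dropOverCap)
}

#' Read a quantitative trait table
#'
#' Genotypes in rows, traits in columns; numeric cells, missing token
#' allowed. Non-numeric cells other than the missing token raise an error
#' with their coordinates. Per-trait validity (at least 3 non-missing
#' values) is enforced by the statistics that consume the table, not here.
#'
#' @inheritParams readMarkerMatrix
#' @return numeric matrix, genotypes x traits, with dimnames.
#' @export
readTraitTable <- function(path, delim = NULL, missingToken = "?") {
  m <- readGrid(path, delim)
  v <- m
  v[] <- trimws(m)
  miss <- array(v %in% c(missingToken, "NA", ""), dim(m))
  num <- suppressWarnings(as.numeric(v))
  bad <- !miss & array(is.na(num), dim(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at genotype '%s', trait '%s'",
                 v[bad][1], rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  out <- matrix(num, nrow(m), ncol(m), dimnames = dimnames(m))
  out[miss] <- NA_real_
  out
}

#' Read a hybridization-intensity matrix
#'
#' Same layout as [readTraitTable()]; returned as a plain numeric matrix to
#' be paired with calls via [DartSet()].
#' @inheritParams readTraitTable
#' @return numeric matrix, genotypes x markers.
#' @export
readIntensityMatrix <- function(path, delim = NULL, missingToken = "?")
  readTraitTable(path, delim, missingToken)

#' Write a DartSet or trait matrix back to disk
#'
#' `writeMarkerMatrix` serialises calls with `?` for missing;
#' `writeTraitTable` writes a numeric grid. Both emit UTF-8 TSV (or the
#' delimiter given) in the genotypes-in-rows layout the readers expect, so
#' read/write round-trips are lossless.
#'
#' @param x a [DartSet-class] (`writeMarkerMatrix`) or numeric matrix.
#' @param path output file path.
#' @param delim field delimiter.
#' @param missingToken token written for missing cells.
#' @return `path`, invisibly.
#' @export
writeMarkerMatrix <- function(x, path, delim = "\t", missingToken = "?") {
  m <- bandCalls(x)
  ch <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  ch[is.na(m)] <- missingToken
  writeGrid(ch, path, delim)
}

#' @rdname writeMarkerMatrix
#' @export
writeTraitTable <- function(x, path, delim = "\t", missingToken = "?") {
  ch <- matrix(formatC(x, digits = 12, format = "g"), nrow(x),
               dimnames = dimnames(x))
  ch[is.na(x)] <- missingToken
  writeGrid(ch, path, delim)
}

writeGrid <- function(ch, path, delim) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(ch)), collapse = delim), con)
  for (i in seq_len(nrow(ch)))
    writeLines(paste(c(rownames(ch)[i], ch[i, ]), collapse = delim), con)
  invisible(path)
}

#' PHYLIP-style square matrix I/O
#'
#' Writes a labelled symmetric matrix (similarity or distance) in the
#' PHYLIP square format: a count line, then one `label value ...` row per
#' entry, values at 12 significant digits. `readSquareMatrix` reverses it.
#'
#' @param m symmetric numeric matrix with dimnames (checked to 1e-10).
#' @param path file path.
#' @return `writeSquareMatrix`: `path` invisibly; `readSquareMatrix`: the
#'   matrix.
#' @export
writeSquareMatrix <- function(m, path) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-10) stop("matrix is asymmetric beyond 1e-10")
  if (is.null(rownames(m))) stop("matrix must carry ids")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(as.character(nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i],
                       sprintf("%.12g", m[i, ])), collapse = " "), con)
  invisible(path)
}

#' @rdname writeSquareMatrix
#' @export
readSquareMatrix <- function(path) {
  ln <- readLines(path)
  n <- as.integer(ln[1])
  parts <- strsplit(trimws(ln[1 + seq_len(n)]), "[ \t]+")
  ids <- vapply(parts, `[`, "", 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a tree in Newick format
#'
#' Thin validating wrapper over [ape::write.tree()]: leaf labels must be
#' present and non-empty; labels containing Newick metacharacters
#' (parentheses, commas, colons, semicolons, quotes or whitespace) are
#' single-quoted per the Newick convention; branch lengths are written at 6
#' significant digits and the string is `;`-terminated.
#'
#' @param tree an [ape::phylo] tree with labelled leaves.
#' @param path output file path.
#' @return the Newick string, invisibly.
#' @export
writeNewick <- function(tree, path) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0)
    stop("tree must be a non-empty 'phylo' object")
  if (any(is.na(tree$tip.label) | tree$tip.label == ""))
    stop("every leaf must be labelled")
  # serialise with placeholder leaf names, then splice the real labels in
  # (quoted when they contain Newick metacharacters) so they are written
  # verbatim rather than sanitised
  labels <- tree$tip.label
  needQuote <- grepl("[](),:;'\"[[:space:][]", labels)
  labels[needQuote] <- paste0("'", gsub("'", "''", labels[needQuote]), "'")
  tokens <- sprintf("zqTIPzq%dzq", seq_along(labels))
  tree$tip.label <- tokens
  txt <- ape::write.tree(tree, digits = 6)
  for (i in seq_along(tokens))
    txt <- sub(tokens[i], labels[i], txt, fixed = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(txt)
}

#' Align marker, trait and metadata inputs on shared genotype ids
#'
#' Intersects genotype ids (case-sensitive, by id not row order) and reports
#' dropped genotypes with a message.
#'
#' @param markers a [DartSet-class].
#' @param traits numeric trait matrix with genotype rownames.
#' @return list with the subsetted `markers` and `traits` in a common order.
#' @export
alignGenotypes <- function(markers, traits) {
  gm <- genotypeIds(markers)
  gt <- rownames(traits)
  common <- intersect(gm, gt)
  if (length(common) == 0) stop("no genotype ids in common")
  dropped <- setdiff(union(gm, gt), common)
  if (length(dropped))
    message("dropping ", length(dropped), " genotype(s) absent from one ",
            "input: ", paste(head(dropped, 5), collapse = ", "))
  list(markers = markers[, common], traits = traits[common, , drop = FALSE])
}
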