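## Internal helpers shared across modules.

## Named error conditions: each distinct failure mode gets its own class so
## callers (and tests) can condition on it.
vlError <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "volescapeError"),
                      call = call))
}

## Deterministic per-stage seed derived from a master seed and a label.
## Kept below 2^31 - 1 so it is a valid R integer.
deriveSeed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647L)
}

## Strict lower-triangle vector of a symmetric matrix.
lowerTri <- function(m) m[lower.tri(m)]

## Symmetric matrix from deme-pair values (fills both triangles).
pairMatrix <- function(n, dimnames = NULL, diag = 0) {
  m <- matrix(diag * 0, n, n)
  diag(m) <- diag
  if (!is.null(dimnames)) dimnames(m) <- list(dimnames, dimnames)
  m
}

## All unordered pairs of 1..n as a 2-row matrix.
allPairs <- function(n) if (n < 2) matrix(integer(), 2, 0) else combn(n, 2)

## p-value with the add-one rule (never 0).
addOneP <- function(n_as_extreme, n_perm) (1 + n_as_extreme) / (n_perm + 1)

## Run an expression with a local RNG state seeded from `seed`,
## restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## Genotypes of one locus as a 2-column matrix of allele codes.
locusCalls <- function(dataset, locus) {
  l <- if (is.character(locus)) match(locus, dataset@loci) else locus
  if (is.na(l) || l < 1 || l > nLoci(dataset))
    vlError("volescape_locus_error", paste("unknown locus:", locus))
  cbind(dataset@alleles[, l, 1], dataset@alleles[, l, 2])
}

## write a data.frame as a UTF-8, UNIX-newline TSV
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, trim = TRUE, digits = 10) else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

## matrix TSV with row/col labels
writeMatrixTsv <- function(m, path) {
  df <- data.frame(name = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  writeTsv(df, path)
}
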