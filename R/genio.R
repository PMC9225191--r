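## Genotype I/O: Genepop text format and the deme metadata CSV.
##
## Genepop files: a title line, one locus name per line (or a single
## comma-separated line), then "POP"-delimited sections of
##   "id , 0102 0304 ..." rows with a fixed digit width of 2 or 3 per allele.
## Allele code 0 (both positions) encodes a missing call.

#' Read a Genepop genotype file
#'
#' @param path path to a Genepop text file.
#' @param dialect digits per allele, 2 or 3; \code{NULL} (default) infers it
#'   from the first genotype token.
#' @param demes optional deme metadata data.frame (from
#'   \code{\link{readDemeTable}}). Its row order is authoritative: the file's
#'   POP sections must match it in number (and a named error is raised
#'   otherwise). Without it, demes are named \code{pop1..popN} with \code{NA}
#'   coordinates.
#' @return A \linkS4class{GenotypeDataset}.
#' @details Distinct failure modes raise distinct condition classes:
#'   \code{volescape_ploidy_error} (a genotype token of the wrong width, e.g.
#'   half-missing), \code{volescape_locus_count_error} (a row with the wrong
#'   number of genotypes), \code{volescape_empty_pop_error} (a POP section
#'   with no individuals), \code{volescape_pop_count_error} (sections do not
#'   match the deme table).
#' @export
readGenepop <- function(path, dialect = NULL, demes = NULL) {
  if (!file.exists(path))
    vlError("volescape_io_error", paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3)
    vlError("volescape_format_error", "not a Genepop file: too few lines")
  isPop <- toupper(trimws(lines)) == "POP"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop))
    vlError("volescape_format_error", "no POP separator found")
  lociLines <- lines[2:(firstPop - 1)]
  loci <- trimws(unlist(strsplit(lociLines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci))
    vlError("volescape_format_error", "no locus names found")

  popStarts <- which(isPop)
  popEnds <- c(popStarts[-1] - 1L, length(lines))
  ids <- character(); demeIdx <- integer()
  tokens <- list()
  for (p in seq_along(popStarts)) {
    block <- if (popEnds[p] >= popStarts[p] + 1L)
      lines[(popStarts[p] + 1L):popEnds[p]] else character()
    block <- block[nzchar(trimws(block))]
    if (!length(block))
      vlError("volescape_empty_pop_error",
              paste0("POP section ", p, " contains no individuals"))
    for (row in block) {
      parts <- strsplit(row, ",")[[1]]
      if (length(parts) < 2)
        vlError("volescape_format_error",
                paste("malformed genotype row (no comma):", row))
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
      gts <- gts[nzchar(gts)]
      if (length(gts) != length(loci))
        vlError("volescape_locus_count_error",
                sprintf("individual '%s' has %d genotypes for %d loci",
                        id, length(gts), length(loci)))
      ids <- c(ids, id); demeIdx <- c(demeIdx, p)
      tokens[[length(tokens) + 1L]] <- gts
    }
  }

  if (is.null(dialect)) {
    w <- nchar(tokens[[1]][1])
    if (!w %in% c(4L, 6L))
      vlError("volescape_ploidy_error",
              sprintf("cannot infer dialect from token '%s' (width %d)",
                      tokens[[1]][1], w))
    dialect <- w / 2L
  }
  dialect <- as.integer(dialect)
  if (!dialect %in% c(2L, 3L))
    vlError("volescape_format_error", "dialect must be 2 or 3 digits")

  n <- length(ids); L <- length(loci)
  all1 <- matrix(NA_integer_, n, L); all2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    gts <- tokens[[i]]
    bad <- nchar(gts) != 2L * dialect | grepl("[^0-9]", gts)
    if (any(bad))
      vlError("volescape_ploidy_error",
              sprintf("individual '%s': genotype '%s' is not %d+%d digits",
                      ids[i], gts[which(bad)[1]], dialect, dialect))
    a <- as.integer(substr(gts, 1L, dialect))
    b <- as.integer(substr(gts, dialect + 1L, 2L * dialect))
    halfMissing <- xor(a == 0L, b == 0L)
    if (any(halfMissing))
      vlError("volescape_ploidy_error",
              sprintf("individual '%s': half-missing call '%s' (a scored call needs both alleles)",
                      ids[i], gts[which(halfMissing)[1]]))
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    all1[i, ] <- a; all2[i, ] <- b
  }

  nPop <- max(demeIdx)
  if (is.null(demes)) {
    demes <- data.frame(name = paste0("pop", seq_len(nPop)),
                        easting = NA_real_, northing = NA_real_,
                        area = NA_real_, date = NA_character_)
    demes$easting <- 0; demes$northing <- 0   # finite placeholders
  } else if (nrow(demes) != nPop) {
    vlError("volescape_pop_count_error",
            sprintf("file has %d POP sections but deme table has %d rows",
                    nPop, nrow(demes)))
  }
  genotypeDataset(loci = loci, demes = demes,
                  indiv = data.frame(id = ids, deme = demeIdx,
                                     sex = NA_character_),
                  alleles = array(c(all1, all2), dim = c(n, L, 2)))
}

#' Write a Genepop genotype file
#'
#' Writes UNIX newlines, UTF-8; missing calls are encoded as all zeros.
#' Re-reading the file yields an equal dataset.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param path output path.
#' @param dialect digits per allele (2 or 3).
#' @param title title line (first line of the file).
#' @return \code{path}, invisibly.
#' @export
writeGenepop <- function(dataset, path, dialect = 2, title = "volescape export") {
  dialect <- as.integer(dialect)
  if (!dialect %in% c(2L, 3L))
    vlError("volescape_format_error", "dialect must be 2 or 3 digits")
  mx <- suppressWarnings(max(dataset@alleles, na.rm = TRUE))
  if (is.finite(mx) && mx > 10^dialect - 1)
    vlError("volescape_digit_error",
            sprintf("allele code %d does not fit in %d digits", mx, dialect))
  fmt <- function(x) sprintf(paste0("%0", dialect, "d"), ifelse(is.na(x), 0L, x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- c(title, dataset@loci)
  a <- dataset@alleles
  for (d in seq_len(nDemes(dataset))) {
    out <- c(out, "POP")
    for (i in which(dataset@indiv$deme == d)) {
      gts <- paste0(fmt(a[i, , 1]), fmt(a[i, , 2]))
      out <- c(out, paste0(dataset@indiv$id[i], " , ", paste(gts, collapse = " ")))
    }
  }
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read deme metadata
#'
#' CSV with named columns \code{name}, \code{easting}, \code{northing},
#' \code{area}, \code{date}. Row order is authoritative and defines the deme
#' indexing used throughout the package.
#'
#' @param path CSV path.
#' @return A data.frame of deme metadata ordered as in the file.
#' @export
readDemeTable <- function(path) {
  if (!file.exists(path))
    vlError("volescape_io_error", paste("file not found:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) vlError("volescape_deme_error", "no demes in table")
  need <- c("name", "easting", "northing", "area", "date")
  missing <- setdiff(need, names(df))
  if (length(missing))
    vlError("volescape_deme_error",
            paste("missing column(s):", paste(missing, collapse = ", ")))
  for (col in c("easting", "northing", "area")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (col %in% c("easting", "northing") && anyNA(v))
      vlError("volescape_deme_error", paste("non-numeric", col, "coordinate"))
    df[[col]] <- v
  }
  if (anyDuplicated(df$name))
    vlError("volescape_deme_error", "duplicate deme names")
  df[need]
}

#' Subset a dataset by loci or demes
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param loci locus names or indices to keep (default all).
#' @param demes deme names or indices to keep (default all).
#' @return A \linkS4class{GenotypeDataset}.
#' @export
subsetDataset <- function(dataset, loci = NULL, demes = NULL) {
  li <- if (is.null(loci)) seq_len(nLoci(dataset)) else {
    if (is.character(loci)) match(loci, dataset@loci) else loci
  }
  if (anyNA(li)) vlError("volescape_locus_error", "unknown locus in subset")
  di <- if (is.null(demes)) seq_len(nDemes(dataset)) else {
    if (is.character(demes)) match(demes, dataset@demes$name) else demes
  }
  if (anyNA(di)) vlError("volescape_deme_error", "unknown deme in subset")
  keepInd <- dataset@indiv$deme %in% di
  indiv <- dataset@indiv[keepInd, , drop = FALSE]
  indiv$deme <- match(indiv$deme, di)
  rownames(indiv) <- NULL
  demesDf <- dataset@demes[di, , drop = FALSE]
  demesDf$n <- tabulate(indiv$deme, nbins = length(di))
  rownames(demesDf) <- NULL
  genotypeDataset(loci = dataset@loci[li], demes = demesDf, indiv = indiv,
                  alleles = dataset@alleles[keepInd, li, , drop = FALSE])
}
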