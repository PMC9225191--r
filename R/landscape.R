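## Graph-based landscape model: categorical cost surfaces, least-cost paths
## on the 8-neighbour lattice, effective / resistance distances and the
## lens-buffer habitat-suitability statistic.

#' Default cost values for the nine land-cover categories
#'
#' Cost 1 for the suitable habitats (meadow, orchard, pasture/grassland),
#' 25 for annual crops and shrubs, 50 for settlements and roads, 1000 for
#' deciduous woodlots, eucalyptus plantations and water bodies.
#'
#' @return named numeric vector of length 9 (names are category codes).
#' @export
defaultCostValues <- function() {
  setNames(c(1, 1, 1, 25, 25, 1000, 1000, 50, 1000), as.character(1:9))
}

#' Category codes of the suitable habitats
#' @return integer vector (meadow, orchard, pasture/grassland).
#' @export
suitableCategories <- function() c(1L, 2L, 3L)

## ---------------------------------------------------------------------------
## ESRI ASCII grid I/O
## ---------------------------------------------------------------------------

#' Read / write ESRI ASCII grids
#'
#' Plain-text .asc rasters (ncols/nrows/xllcorner/yllcorner/cellsize header).
#' NODATA cells are rejected for category grids (the cost model has no masked
#' cells) and read as \code{NA} for elevation grids.
#'
#' @param path file path.
#' @param what "category" or "elevation".
#' @return a \linkS4class{CategoryGrid} or \linkS4class{ElevationGrid}.
#' @export
readAsciiGrid <- function(path, what = c("category", "elevation")) {
  what <- match.arg(what)
  if (!file.exists(path))
    vlError("volescape_io_error", paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]]))
      vlError("volescape_grid_error", paste("missing header field", k))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    vlError("volescape_grid_error", "cell count does not match header")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (what == "category") {
    if (anyNA(m))
      vlError("volescape_grid_error", "NODATA cells not allowed in category grids")
    categoryGrid(m, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner))
  } else
    elevationGrid(m, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner))
}

#' @rdname readAsciiGrid
#' @param grid a grid object.
#' @param nodata NODATA code written for \code{NA} cells.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  v[is.na(v)] <- nodata
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               paste("xllcorner", grid@origin[1]),
               paste("yllcorner", grid@origin[2]),
               paste("cellsize", grid@cellSize),
               paste("NODATA_value", nodata),
               apply(v, 1, paste, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Coordinates <-> cells
## ---------------------------------------------------------------------------

## Cell centres: row 1 is the grid's north edge (file order); origin is the
## lower-left corner. Returns easting/northing of given (row, col).
cellCentre <- function(grid, row, col) {
  nr <- nrow(grid@values); cs <- grid@cellSize
  cbind(easting = grid@origin[1] + (col - 0.5) * cs,
        northing = grid@origin[2] + (nr - row + 0.5) * cs)
}

## Nearest cell centre to a point; ties broken toward smaller indices.
snapToCell <- function(grid, easting, northing) {
  nr <- nrow(grid@values); nc <- ncol(grid@values); cs <- grid@cellSize
  col <- floor((easting - grid@origin[1]) / cs) + 1
  rowFromBottom <- floor((northing - grid@origin[2]) / cs) + 1
  row <- nr - rowFromBottom + 1
  if (row < 1 || row > nr || col < 1 || col > nc)
    vlError("volescape_grid_error", "point outside grid")
  c(row = row, col = col)
}

## ---------------------------------------------------------------------------
## Resistance surface and least-cost paths
## ---------------------------------------------------------------------------

#' Build a resistance surface from a category grid
#'
#' @param grid a \linkS4class{CategoryGrid}.
#' @param cv named numeric cost-value map (names = category codes, all >= 1).
#' @return a \linkS4class{ResistanceGrid}.
#' @export
buildResistance <- function(grid, cv = defaultCostValues()) {
  cats <- unique(as.vector(grid@values))
  unmapped <- setdiff(as.character(cats), names(cv))
  if (length(unmapped))
    vlError("volescape_cv_error",
            paste("no cost value for category:", paste(unmapped, collapse = ", ")))
  vals <- matrix(cv[as.character(grid@values)], nrow(grid@values))
  resistanceGrid(vals, grid@cellSize, grid@origin)
}

## igraph over the 8-neighbour lattice; edge weight between adjacent cells i,j
## is cellSize * d * (CV_i + CV_j)/2, d = 1 rook / sqrt(2) diagonal.
lcpGraph <- function(res) {
  v <- res@values; nr <- nrow(v); nc <- ncol(v); cs <- res@cellSize
  id <- function(r, c) (c - 1L) * nr + r    # column-major vertex ids
  rows <- rep(seq_len(nr), nc); cols <- rep(seq_len(nc), each = nr)
  edges <- list(); wts <- list(); k <- 0
  for (dd in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                  c(-1L, 1L, sqrt(2)))) {
    dr <- dd[1]; dc <- dd[2]; fac <- dd[3]
    ok <- rows + dr >= 1L & rows + dr <= nr & cols + dc <= nc
    from <- id(rows[ok], cols[ok]); to <- id(rows[ok] + dr, cols[ok] + dc)
    k <- k + 1
    edges[[k]] <- rbind(from, to)
    wts[[k]] <- cs * fac * (v[from] + v[to]) / 2
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, unlist(edges))
  igraph::E(g)$weight <- unlist(wts)
  g
}

#' Least-cost path between two cells
#'
#' Shortest path on the 8-neighbour lattice where moving between adjacent
#' cells costs the step length times the mean of the two cells' cost values
#' (step length = cell size, or cell size times sqrt(2) diagonally).
#'
#' @param res a \linkS4class{ResistanceGrid}.
#' @param src,dst length-2 integer vectors (row, col), 1-based, row 1 north.
#' @param graph optional pre-built graph from repeated queries (internal).
#' @return list of class \code{lcpPath}: \code{cells} (matrix of row, col),
#'   \code{cost} (accumulated cost), \code{cellSize}.
#' @export
leastCostPath <- function(res, src, dst, graph = NULL) {
  v <- res@values; nr <- nrow(v); nc <- ncol(v)
  chk <- function(p) if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc)
    vlError("volescape_grid_error", "cell outside grid")
  chk(src); chk(dst)
  if (all(src == dst)) {
    out <- list(cells = matrix(as.integer(src), 1, 2,
                               dimnames = list(NULL, c("row", "col"))),
                cost = 0, cellSize = res@cellSize)
    class(out) <- "lcpPath"
    return(out)
  }
  if (is.null(graph)) graph <- lcpGraph(res)
  id <- function(p) (p[2] - 1L) * nr + p[1]
  sp <- igraph::shortest_paths(graph, from = id(src), to = id(dst),
                               output = "both")
  vp <- as.integer(sp$vpath[[1]])
  cost <- sum(igraph::E(graph)$weight[as.integer(sp$epath[[1]])])
  cells <- cbind(row = ((vp - 1L) %% nr) + 1L, col = ((vp - 1L) %/% nr) + 1L)
  out <- list(cells = cells, cost = cost, cellSize = res@cellSize)
  class(out) <- "lcpPath"
  out
}

## step lengths along a path (metres); with a DEM each step is the 3-D
## hypotenuse using cell-centre elevations.
pathStepLengths <- function(path, dem = NULL) {
  cells <- path$cells
  if (nrow(cells) < 2) return(numeric())
  dr <- abs(diff(cells[, 1])); dc <- abs(diff(cells[, 2]))
  if (any(dr > 1 | dc > 1))
    vlError("volescape_path_error", "consecutive path cells must be 8-neighbours")
  planar <- path$cellSize * ifelse(dr + dc == 2, sqrt(2), 1)
  if (is.null(dem)) return(planar)
  ev <- dem@values
  if (nrow(ev) < max(cells[, 1]) || ncol(ev) < max(cells[, 2]))
    vlError("volescape_dem_error", "DEM shape does not cover the path")
  z <- ev[cbind(cells[, 1], cells[, 2])]
  sqrt(planar^2 + diff(z)^2)
}

#' Effective distance: metric length of a least-cost path
#'
#' Sum of planar step lengths; with a DEM each step becomes the 3-D
#' hypotenuse (orographic correction).
#'
#' @param path an \code{lcpPath}.
#' @param dem optional \linkS4class{ElevationGrid} (same lattice).
#' @return length in metres.
#' @export
effectiveDistance <- function(path, dem = NULL) sum(pathStepLengths(path, dem))

#' Resistance distance along a path
#'
#' The path is segmented into maximal runs of constant land-cover category;
#' each run contributes its metric length m_i in kilometres times the
#' category's cost value: sum(m_i * CV_i). Each step's length is split half
#' and half between its two end cells, so the run decomposition equals the
#' per-cell sum of cell length times cell cost.
#'
#' @param path an \code{lcpPath}.
#' @param grid the \linkS4class{CategoryGrid} the path crosses.
#' @param cv cost-value map.
#' @param dem optional \linkS4class{ElevationGrid} for 3-D step lengths.
#' @return dimensionless resistance distance.
#' @export
resistanceDistance <- function(path, grid, cv = defaultCostValues(),
                               dem = NULL) {
  cells <- path$cells
  cats <- grid@values[cbind(cells[, 1], cells[, 2])]
  cvCell <- cv[as.character(cats)]
  if (anyNA(cvCell))
    vlError("volescape_cv_error", "unmapped category on path")
  if (nrow(cells) == 1) return(0)
  steps <- pathStepLengths(path, dem)
  ## half of each step accrues to each end cell
  cellLen <- c(steps / 2, 0) + c(0, steps / 2)
  ## maximal runs of constant category
  runId <- cumsum(c(1, as.integer(cats[-1] != cats[-length(cats)])))
  mi <- tapply(cellLen, runId, sum) / 1000          # km
  cvi <- cvCell[!duplicated(runId)]
  sum(mi * cvi)
}

## ---------------------------------------------------------------------------
## Deme-level distances
## ---------------------------------------------------------------------------

#' Pairwise Euclidean distances between demes (km)
#'
#' @param demes deme data.frame with \code{easting}, \code{northing} in metres.
#' @return symmetric matrix in kilometres with deme names as dimnames.
#' @export
euclideanMatrix <- function(demes) {
  if (nrow(demes) < 2) vlError("volescape_deme_error", "need >= 2 demes")
  m <- as.matrix(dist(cbind(demes$easting, demes$northing))) / 1000
  dimnames(m) <- list(demes$name, demes$name)
  m
}

#' Lens-buffer landscape suitability between two demes
#'
#' Two discs are drawn, one around each deme, each with radius equal to the
#' inter-deme Euclidean distance; within the lens-shaped intersection the
#' fraction of cells (by cell centre) carrying a suitable category is the
#' SH/TL ratio. The statistic is (SH/TL) divided by the Euclidean distance
#' in km (per-km suitability).
#'
#' @param demeA,demeB length-2 numeric (easting, northing) in metres.
#' @param grid a \linkS4class{CategoryGrid}.
#' @param suitable integer category codes counted as suitable habitat.
#' @return per-km suitability, or \code{NA} if the lens misses the grid.
#' @export
suitabilityIndex <- function(demeA, demeB, grid,
                             suitable = suitableCategories()) {
  d <- sqrt(sum((demeA - demeB)^2))
  if (d == 0) vlError("volescape_geometry_error", "demes must be distinct")
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  ctr <- cellCentre(grid, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  inLens <- (ctr[, 1] - demeA[1])^2 + (ctr[, 2] - demeA[2])^2 <= d^2 &
            (ctr[, 1] - demeB[1])^2 + (ctr[, 2] - demeB[2])^2 <= d^2
  tot <- sum(inLens)
  if (tot == 0) return(NA_real_)
  sh <- sum(as.vector(grid@values)[inLens] %in% suitable)
  (sh / tot) / (d / 1000)
}

#' Compute all pairwise deme distance matrices
#'
#' Populates the four matrices of a \linkS4class{DistanceBundle}: Euclidean
#' (km, from raw coordinates), effective (least-cost-path length in km,
#' DEM-corrected when supplied), resistance (sum of patch length in km times
#' cost value along the least-cost path) and per-km lens suitability.
#' Deme locations are snapped to the nearest cell centre for the path-based
#' entries.
#'
#' @param demes deme data.frame (name, easting, northing).
#' @param grid a \linkS4class{CategoryGrid}.
#' @param cv cost-value map.
#' @param dem optional \linkS4class{ElevationGrid}.
#' @param suitable suitable category codes.
#' @return a \linkS4class{DistanceBundle}.
#' @export
distanceBundle <- function(demes, grid, cv = defaultCostValues(), dem = NULL,
                           suitable = suitableCategories()) {
  D <- nrow(demes)
  eu <- euclideanMatrix(demes)
  eff <- pairMatrix(D, demes$name)
  rs <- pairMatrix(D, demes$name)
  su <- pairMatrix(D, demes$name, diag = NA)
  diag(su) <- NA_real_
  res <- buildResistance(grid, cv)
  graph <- lcpGraph(res)
  cellsOf <- lapply(seq_len(D),
                    function(i) snapToCell(grid, demes$easting[i],
                                           demes$northing[i]))
  prs <- allPairs(D)
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    ok <- tryCatch({
      p <- leastCostPath(res, cellsOf[[i]], cellsOf[[j]], graph = graph)
      eff[i, j] <- eff[j, i] <- effectiveDistance(p, dem) / 1000
      rs[i, j] <- rs[j, i] <- resistanceDistance(p, grid, cv, dem)
      TRUE
    }, volescapeError = function(e) {
      warning("pair ", demes$name[i], "-", demes$name[j], ": ",
              conditionMessage(e))
      FALSE
    })
    if (!ok) { eff[i, j] <- eff[j, i] <- NA; rs[i, j] <- rs[j, i] <- NA }
    su[i, j] <- su[j, i] <- suitabilityIndex(
      c(demes$easting[i], demes$northing[i]),
      c(demes$easting[j], demes$northing[j]), grid, suitable)
  }
  new("DistanceBundle", euclidean = eu, effective = eff, resistance = rs,
      suitability = su)
}
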