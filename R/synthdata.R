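## Synthetic landscapes and forward-simulated microsatellite genotypes with
## known truth, so every pipeline stage is testable without downloads.
##
## The generator emulates the study conditions: ~10 demes of 11-18 diploid
## individuals, 11-12 microsatellite loci, differentiation in roughly
## 0-0.3 with isolation by distance, and a fine-grained multi-category
## mosaic with ~30% suitable habitat.

#' Simulation configuration
#'
#' Defaults are the package's standing study conditions; see the methods
#' vignette for the reasoning behind each value.
#'
#' @param nrows,ncols grid extent in cells.
#' @param cell_size cell edge, metres.
#' @param mixture named (by category code 1-9) probability vector of category
#'   cover; must sum to 1. Default gives 30\% suitable habitat (codes 1-3).
#' @param patch_scale expected patch diameter in cells.
#' @param n_demes number of demes.
#' @param sample_sizes individuals sampled per deme (recycled).
#' @param n_loci,n_alleles loci and initial allele count per locus.
#' @param mutation_rate stepwise mutation probability per copy per generation.
#' @param N_e diploid effective size per deme.
#' @param migration \code{"island"}, \code{"stepping_stone"} or
#'   \code{"cost_decay"}.
#' @param m0 base migration rate (total emigration bound per generation).
#' @param decay cost-decay constant c (per unit cost distance) for
#'   \code{"cost_decay"}.
#' @param n_generations forward generations simulated.
#' @param min_separation_m minimum deme separation for placement.
#' @param seed master seed.
#' @return list of class \code{volescapeSimConfig}.
#' @export
simConfig <- function(nrows = 300, ncols = 300, cell_size = 50,
                      mixture = c("1" = 0.15, "2" = 0.05, "3" = 0.10,
                                  "4" = 0.20, "5" = 0.12, "6" = 0.10,
                                  "7" = 0.15, "8" = 0.08, "9" = 0.05),
                      patch_scale = 6, n_demes = 10,
                      sample_sizes = c(18, 14, 14, 11, 12, 14, 14, 15, 14, 11),
                      n_loci = 11, n_alleles = 8, mutation_rate = 5e-4,
                      N_e = 150, migration = c("cost_decay", "island",
                                               "stepping_stone"),
                      m0 = 0.2, decay = 0.1, n_generations = 100,
                      min_separation_m = 1000, seed = 1) {
  migration <- match.arg(migration)
  if (abs(sum(mixture) - 1) > 1e-9)
    vlError("volescape_config_error", "mixture proportions must sum to 1")
  if (any(c(mutation_rate, m0) < 0) || any(c(mutation_rate, m0) > 1))
    vlError("volescape_config_error", "rates must be in [0, 1]")
  cfg <- list(nrows = nrows, ncols = ncols, cell_size = cell_size,
              mixture = mixture, patch_scale = patch_scale,
              n_demes = n_demes, sample_sizes = sample_sizes,
              n_loci = n_loci, n_alleles = n_alleles,
              mutation_rate = mutation_rate, N_e = N_e,
              migration = migration, m0 = m0, decay = decay,
              n_generations = n_generations,
              min_separation_m = min_separation_m, seed = seed)
  class(cfg) <- "volescapeSimConfig"
  cfg
}

#' Generate a multi-category mosaic landscape
#'
#' Seeded region growth: category seed points are dropped by a Poisson
#' process with intensity matched to \code{patch_scale} (expected patch
#' diameter), every cell takes the category of its nearest seed, and seed
#' categories are drawn from the mixture. Realized category proportions are
#' within a few percentage points of the mixture for grids >= 200 x 200.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{CategoryGrid}.
#' @export
generateLandscape <- function(config) {
  nr <- config$nrows; nc <- config$ncols
  cats <- as.integer(names(config$mixture))
  withSeed(deriveSeed(config$seed, "landscape"), {
    if (length(cats) == 1 || max(config$mixture) >= 1 - 1e-12) {
      cat1 <- cats[which.max(config$mixture)]
      return(categoryGrid(matrix(cat1, nr, nc), config$cell_size))
    }
    lambda <- 4 / (pi * config$patch_scale^2)    # seeds per cell
    nSeeds <- max(rpois(1, lambda * nr * nc), length(cats))
    sr <- runif(nSeeds, 0.5, nr + 0.5); sc <- runif(nSeeds, 0.5, nc + 0.5)
    scat <- sample(cats, nSeeds, replace = TRUE, prob = config$mixture)
    rows <- rep(seq_len(nr), nc); cols <- rep(seq_len(nc), each = nr)
    best <- rep(Inf, nr * nc); lab <- rep(cats[1], nr * nc)
    for (s in seq_len(nSeeds)) {
      d2 <- (rows - sr[s])^2 + (cols - sc[s])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; lab[upd] <- scat[s]
    }
    categoryGrid(matrix(lab, nr, nc), config$cell_size)
  })
}

#' Place demes on suitable habitat
#'
#' Rejection sampling of deme centres on suitable-category cell centres with
#' a minimum pairwise separation.
#'
#' @param grid a \linkS4class{CategoryGrid}.
#' @param n_demes demes to place.
#' @param min_separation_m minimum pairwise distance, metres.
#' @param seed RNG seed.
#' @param suitable suitable category codes.
#' @param max_tries rejection-sampling cap.
#' @return deme data.frame (name, easting, northing, area, date).
#' @export
placeDemes <- function(grid, n_demes, min_separation_m = 1000, seed = 1,
                       suitable = suitableCategories(), max_tries = 5000) {
  v <- gridValues(grid)
  cand <- which(matrix(v %in% suitable, nrow(v)), arr.ind = TRUE)
  if (!nrow(cand))
    vlError("volescape_placement_error", "no suitable cells in grid")
  withSeed(seed, {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < n_demes) {
      tries <- tries + 1
      if (tries > max_tries)
        vlError("volescape_placement_error",
                paste("could not place", n_demes, "demes; reduce",
                      "min_separation_m or enlarge the grid"))
      k <- cand[sample.int(nrow(cand), 1), ]
      xy <- cellCentre(grid, k[1], k[2])
      if (nrow(pts) == 0 ||
          all(sqrt((pts[, 1] - xy[1])^2 + (pts[, 2] - xy[2])^2) >=
              min_separation_m))
        pts <- rbind(pts, xy)
    }
    data.frame(name = paste0("deme", seq_len(n_demes)),
               easting = pts[, 1], northing = pts[, 2],
               area = NA_real_, date = NA_character_)
  })
}

## migration matrix (rows = destination deme, m[i,j] = prob a gene copy in i
## has its parent in j)
migrationMatrix <- function(config, costDist = NULL) {
  D <- config$n_demes
  m <- matrix(0, D, D)
  if (config$migration == "island") {
    if (D > 1) m[] <- config$m0 / (D - 1)
  } else if (config$migration == "stepping_stone") {
    for (i in seq_len(D)) {
      nb <- intersect(c(i - 1, i + 1), seq_len(D))
      m[i, nb] <- config$m0 / 2
    }
  } else {
    if (is.null(costDist))
      vlError("volescape_config_error", "cost_decay migration needs costDist")
    m <- config$m0 * exp(-config$decay * costDist)
  }
  diag(m) <- 0
  rs <- rowSums(m)
  over <- rs > config$m0 & rs > 0
  m[over, ] <- m[over, ] * (config$m0 / rs[over])
  if (any(rowSums(m) > 1 + 1e-9))
    vlError("volescape_config_error", "migration row sum exceeds 1")
  diag(m) <- 1 - rowSums(m)
  m
}

#' Forward Wright-Fisher simulation of deme genotypes
#'
#' Each deme holds 2 N_e gene copies per locus. Every generation each copy
#' picks a source deme from the migration matrix, then a uniformly random
#' parent copy within that deme, then mutates +-1 repeat unit with the
#' stepwise probability. All demes start from one common ancestral pool, so
#' differentiation accrues by drift against migration over
#' \code{n_generations}. Loci are independent.
#'
#' @param demes deme data.frame (from \code{\link{placeDemes}} or real
#'   metadata); row count must equal \code{config$n_demes}.
#' @param cost_distances symmetric matrix of cost distances (required for the
#'   \code{"cost_decay"} model).
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{dataset} (a \linkS4class{GenotypeDataset} of the
#'   configured sample sizes) and \code{truth} (migration matrix, expected
#'   island-model theta where defined, generations, seed).
#' @export
simulateGenotypes <- function(demes, cost_distances = NULL, config) {
  D <- config$n_demes
  if (nrow(demes) != D)
    vlError("volescape_config_error", "demes rows must equal n_demes")
  mig <- migrationMatrix(config, cost_distances)
  Ne2 <- 2L * config$N_e
  L <- config$n_loci
  withSeed(deriveSeed(config$seed, "wrightfisher"), {
    ## ancestral pool per locus: allele codes offset to fragment-size range
    pool <- lapply(seq_len(L), function(l) {
      base <- 100L + 10L * l
      codes <- base + seq_len(config$n_alleles) - 1L
      w <- rgamma(config$n_alleles, 1)   # Dirichlet(1) ancestral frequencies
      list(codes = codes, p = w / sum(w))
    })
    state <- lapply(seq_len(L), function(l)
      matrix(sample(pool[[l]]$codes, Ne2 * D, replace = TRUE,
                    prob = pool[[l]]$p), Ne2, D))
    for (gen in seq_len(config$n_generations)) {
      for (l in seq_len(L)) {
        cur <- state[[l]]
        nxt <- matrix(0L, Ne2, D)
        for (i in seq_len(D)) {
          src <- sample.int(D, Ne2, replace = TRUE, prob = mig[i, ])
          pick <- sample.int(Ne2, Ne2, replace = TRUE)
          nxt[, i] <- cur[cbind(pick, src)]
        }
        if (config$mutation_rate > 0) {
          mut <- runif(Ne2 * D) < config$mutation_rate
          if (any(mut))
            nxt[mut] <- nxt[mut] + sample(c(-1L, 1L), sum(mut), replace = TRUE)
        }
        state[[l]] <- nxt
      }
    }
    ## sample individuals: pairs of distinct gene copies per locus
    sizes <- rep_len(config$sample_sizes, D)
    n <- sum(sizes)
    all1 <- matrix(NA_integer_, n, L); all2 <- matrix(NA_integer_, n, L)
    demeIdx <- rep(seq_len(D), sizes)
    row0 <- 0L
    for (i in seq_len(D)) {
      ni <- sizes[i]
      for (l in seq_len(L)) {
        picks <- sample.int(Ne2, 2L * ni)
        all1[row0 + seq_len(ni), l] <- state[[l]][picks[seq_len(ni)], i]
        all2[row0 + seq_len(ni), l] <- state[[l]][picks[ni + seq_len(ni)], i]
      }
      row0 <- row0 + ni
    }
    demes$n <- sizes
    ds <- genotypeDataset(
      loci = paste0("L", sprintf("%02d", seq_len(L))),
      demes = demes,
      indiv = data.frame(id = paste0("ind", seq_len(n)), deme = demeIdx,
                         sex = NA_character_),
      alleles = array(c(all1, all2), dim = c(n, L, 2)))
    ## coalescent equilibrium for the finite island model as simulated
    ## (emigration prob m0, source uniform among the other demes):
    ## contrasting within- and between-deme pair coalescence times gives
    ## theta = 1 / (1 + 4 N_e m0 d/(d-1)).
    thetaIsland <- if (config$migration == "island" && D > 1) {
      Nm <- config$N_e * config$m0
      1 / (1 + 4 * Nm * D / (D - 1))
    } else NA_real_
    list(dataset = ds,
         truth = list(migration = mig, expected_theta_island = thetaIsland,
                      n_generations = config$n_generations,
                      seed = config$seed))
  })
}

#' Study-shaped synthetic fixture
#'
#' Ten demes with the study's sample sizes (18, 14, 14, 11, 12, 14, 14, 15,
#' 14, 11 -- total 137) at the study's printed UTM plot coordinates, 11 loci,
#' genotypes simulated under cost-decay migration over a generated landscape
#' that covers the deme extent.
#'
#' @param seed master seed.
#' @return list with \code{dataset}, \code{truth}, \code{grid} (the
#'   \linkS4class{CategoryGrid}) and \code{bundle} (the
#'   \linkS4class{DistanceBundle} used for migration).
#' @export
fixtureTable1 <- function(seed = 1) {
  demes <- table1Demes()
  pad <- 1000
  x0 <- min(demes$easting) - pad; y0 <- min(demes$northing) - pad
  cs <- 100
  nc <- ceiling((max(demes$easting) + pad - x0) / cs)
  nr <- ceiling((max(demes$northing) + pad - y0) / cs)
  ## patch diameter ~300 m (3 cells at 100 m): the bocage grain, where single
  ## plots span 1-7.6 ha
  cfg <- simConfig(nrows = nr, ncols = nc, cell_size = cs, patch_scale = 3,
                   seed = seed)
  grid <- generateLandscape(cfg)
  grid@origin <- c(x0, y0)
  ## demes sit at the printed coordinates whatever the category there
  bundle <- distanceBundle(demes, grid)
  sim <- simulateGenotypes(demes, distanceMatrix(bundle, "resistance"), cfg)
  list(dataset = sim$dataset, truth = sim$truth, grid = grid,
       bundle = bundle)
}

#' Printed deme metadata of the study area
#'
#' The ten apple-orchard demes with sampling date, UTM coordinates (metres),
#' plot area (ha), sample size and the published per-deme summary statistics,
#' shipped as a plain-text table in \code{inst/extdata}.
#'
#' @return data.frame with columns name, date, easting, northing, area, n,
#'   NA_, AR, HO, HE, FIS, HWE_p.
#' @export
table1Demes <- function() {
  path <- system.file("extdata", "table1_demes.csv", package = "volescape")
  df <- read.csv(path, stringsAsFactors = FALSE)
  df
}
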