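## Pipeline orchestration: run every analysis stage in dependency order from
## a single configuration, writing one table per stage plus a JSON report.

#' Read a pipeline run configuration
#'
#' YAML with any subset of the fields of \code{\link{runConfig}}; omitted
#' fields take the documented defaults (all defaults are echoed into the run
#' report for provenance).
#'
#' @param path YAML file.
#' @return a run-config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    vlError("volescape_io_error", paste("file not found:", path))
  do.call(runConfig, yaml::read_yaml(path))
}

#' Assemble a pipeline run configuration
#'
#' @param genepop path to a Genepop genotype file (or \code{NULL} to
#'   simulate a study-shaped dataset with \code{\link{fixtureTable1}}).
#' @param deme_csv path to the deme metadata CSV (required with
#'   \code{genepop}).
#' @param grid_asc optional ESRI ASCII category grid; without it the
#'   landscape-dependent stages degrade gracefully and the Mantel suite runs
#'   on Euclidean distance only.
#' @param dem_asc optional elevation grid.
#' @param cost_values named cost-value map.
#' @param suitable suitable category codes.
#' @param rarefaction_g rarefaction size (gene copies); \code{NULL} = data
#'   minimum.
#' @param ld_alpha locus-filter significance level.
#' @param k_max,k_reps,n_iter,burnin clustering settings.
#' @param n_perm,n_boot,n_mc resampling counts.
#' @param alpha migrant-flagging level.
#' @param autocorr_class_width metres.
#' @param seed master seed; every stage derives its own seed from it.
#' @param outdir output directory.
#' @return a run-config list of class \code{volescapeRunConfig}.
#' @export
runConfig <- function(genepop = NULL, deme_csv = NULL, grid_asc = NULL,
                      dem_asc = NULL, cost_values = defaultCostValues(),
                      suitable = suitableCategories(), rarefaction_g = NULL,
                      ld_alpha = 0.001, k_max = 5, k_reps = 3,
                      n_iter = 2000, burnin = 500, n_perm = 999,
                      n_boot = 1000, n_mc = 2000, alpha = 0.01,
                      autocorr_class_width = 100, seed = 1,
                      outdir = tempfile("volescape_run_")) {
  cfg <- as.list(environment())
  counts <- c(cfg$k_max, cfg$k_reps, cfg$n_iter, cfg$burnin, cfg$n_perm,
              cfg$n_boot, cfg$n_mc)
  if (any(counts < 1))
    vlError("volescape_config_error", "all counts must be >= 1")
  class(cfg) <- "volescapeRunConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input (read or simulate) -> LD locus filter
#' -> diversity table -> pairwise/overall theta -> clustering with K
#' selection -> AMOVA on the deme cluster labels -> distance matrices (when
#' a grid is supplied) -> Mantel / partial-Mantel suite on linearized theta
#' -> spatial autocorrelation -> migrant detection. Every stage writes one
#' file into \code{outdir} and registers it in the returned report; with the
#' same configuration and seed the outputs are byte-identical.
#'
#' @param config a \code{\link{runConfig}} (or \code{\link{readRunConfig}}).
#' @return invisible list (the run report): \code{files} registry,
#'   \code{log}, \code{seeds}, \code{config}. Also written as
#'   \code{report.json} in \code{outdir}.
#' @export
runPipeline <- function(config = runConfig()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list(); logs <- character(); seeds <- list()
  note <- function(...) {
    msg <- paste0(...)
    logs <<- c(logs, msg)
    message(msg)
  }
  reg <- function(stage, path) files[[stage]] <<- path
  stageSeed <- function(stage) {
    s <- deriveSeed(config$seed, stage)
    seeds[[stage]] <<- s
    s
  }

  ## --- input ---------------------------------------------------------------
  grid <- NULL; dem <- NULL
  if (is.null(config$genepop)) {
    note("input: simulating study-shaped dataset (fixtureTable1)")
    fx <- fixtureTable1(seed = stageSeed("simulate"))
    ds <- fx$dataset; grid <- fx$grid
    gpPath <- file.path(config$outdir, "simulated.gen")
    writeGenepop(ds, gpPath, dialect = 3)
    reg("simulate", gpPath)
  } else {
    if (is.null(config$deme_csv))
      vlError("volescape_config_error", "genepop input needs deme_csv")
    demes <- readDemeTable(config$deme_csv)
    ds <- readGenepop(config$genepop, demes = demes)
    note("input: ", nInd(ds), " individuals read")
  }
  if (!is.null(config$grid_asc)) grid <- readAsciiGrid(config$grid_asc)
  if (!is.null(config$dem_asc)) dem <- readAsciiGrid(config$dem_asc,
                                                     "elevation")

  ## --- locus filter --------------------------------------------------------
  filt <- ldFilter(ds, alpha = config$ld_alpha, n_perm = config$n_perm,
                   seed = stageSeed("ldfilter"))
  if (length(filt$dropped))
    note("filter: dropped ", paste(filt$dropped, collapse = ", "))
  ds <- filt$dataset
  p <- file.path(config$outdir, "ld_filter.tsv")
  writeTsv(filt$pairs, p); reg("filter", p)

  ## --- diversity -----------------------------------------------------------
  div <- diversityStats(ds, g = config$rarefaction_g, hwe = TRUE,
                        n_mc = config$n_mc, seed = stageSeed("diversity"))
  p <- file.path(config$outdir, "diversity.tsv")
  writeTsv(div, p); reg("diversity", p)

  ## --- F_ST ----------------------------------------------------------------
  pw <- fstMatrix(ds, n_perm = config$n_perm, seed = stageSeed("fst_pairs"))
  ov <- fstOverall(ds, n_boot = config$n_boot, seed = stageSeed("fst_boot"))
  p <- file.path(config$outdir, "fst_pairwise.tsv")
  writeMatrixTsv(pw$theta, p); reg("fst", p)
  note(sprintf("fst: overall theta %.3f (CI %.3f-%.3f)", ov$theta,
               ov$ci[1], ov$ci[2]))

  ## --- clustering ----------------------------------------------------------
  ks <- selectK(ds, Kmax = max(config$k_max, 3), n_reps = config$k_reps,
                n_iter = config$n_iter, burnin = config$burnin,
                seed = stageSeed("cluster"))
  bestK <- if (is.na(ks$bestK)) 2L else ks$bestK
  model <- ks$models[[bestK]]
  labels <- demeClusterLabels(model, ds)
  q <- data.frame(id = indInfo(ds)$id,
                  deme = demeNames(ds)[indInfo(ds)$deme],
                  assignmentProbs(model), check.names = FALSE)
  names(q)[-(1:2)] <- paste0("q_", seq_len(model@K))
  p <- file.path(config$outdir, "qmatrix.tsv")
  writeTsv(q, p); reg("cluster", p)
  note("cluster: selected K = ", bestK)

  ## --- AMOVA ---------------------------------------------------------------
  if (length(unique(labels)) >= 2) {
    am <- amova(ds, labels, n_perm = config$n_perm,
                seed = stageSeed("amova"))
    p <- file.path(config$outdir, "amova.tsv")
    writeTsv(am$table, p); reg("amova", p)
  } else note("amova: skipped, single inferred cluster")

  ## --- distances -----------------------------------------------------------
  bundle <- NULL
  if (!is.null(grid)) {
    bundle <- distanceBundle(demeInfo(ds), grid, cv = config$cost_values,
                             dem = dem, suitable = config$suitable)
    for (w in c("euclidean", "effective", "resistance", "suitability"))
      writeMatrixTsv(distanceMatrix(bundle, w),
                     file.path(config$outdir, paste0("distances_", w, ".tsv")))
    reg("distances", file.path(config$outdir, "distances_effective.tsv"))
  } else note("distances: no grid supplied, Euclidean only")

  ## --- Mantel suite --------------------------------------------------------
  lin <- linearizedFst(pw$theta)
  eu <- euclideanMatrix(demeInfo(ds))
  mrows <- list()
  addM <- function(test, correctedBy, res)
    mrows[[length(mrows) + 1L]] <<- data.frame(test = test,
                                               corrected_by = correctedBy,
                                               r = res$r, p = res$p)
  logm <- function(m) { d <- m; d[] <- log10(pmax(m, 1e-12)); diag(d) <- 0; d }
  ms <- stageSeed("mantel")
  addM("IBD", "none", mantelTest(lin, logm(eu), n_perm = config$n_perm,
                                 seed = deriveSeed(ms, "ibd")))
  memb <- membershipMatrix(labels)
  if (!is.null(bundle)) {
    rsm <- logm(distanceMatrix(bundle, "resistance"))
    sum_ <- distanceMatrix(bundle, "suitability"); diag(sum_) <- 1
    sm <- logm(sum_)
    addM("IBR", "none", mantelTest(lin, rsm, n_perm = config$n_perm,
                                   seed = deriveSeed(ms, "ibr")))
    addM("suitability", "none",
         mantelTest(lin, sm, n_perm = config$n_perm,
                    seed = deriveSeed(ms, "suit")))
    addM("IBD", "resistance",
         partialMantelTest(lin, logm(eu), rsm, n_perm = config$n_perm,
                           seed = deriveSeed(ms, "ibd.res")))
    addM("IBD", "suitability",
         partialMantelTest(lin, logm(eu), sm, n_perm = config$n_perm,
                           seed = deriveSeed(ms, "ibd.suit")))
    addM("IBR", "euclidean",
         partialMantelTest(lin, rsm, logm(eu), n_perm = config$n_perm,
                           seed = deriveSeed(ms, "ibr.eu")))
  }
  addM("IBD", "membership",
       partialMantelTest(lin, logm(eu), memb, n_perm = config$n_perm,
                         seed = deriveSeed(ms, "ibd.memb")))
  mt <- do.call(rbind, mrows)
  p <- file.path(config$outdir, "mantel.tsv")
  writeTsv(mt, p); reg("mantel", p)

  ## --- autocorrelation -----------------------------------------------------
  ac <- spatialAutocorr(ds, class_width = config$autocorr_class_width,
                        n_perm = min(config$n_perm, 999),
                        n_boot = config$n_boot,
                        seed = stageSeed("autocorr"))
  p <- file.path(config$outdir, "autocorr.tsv")
  writeTsv(ac, p); reg("autocorr", p)

  ## --- migrants ------------------------------------------------------------
  mg <- detectMigrants(ds, n_mc = config$n_mc, alpha = config$alpha,
                       seed = stageSeed("migrants"))
  p <- file.path(config$outdir, "migrants.tsv")
  writeTsv(mg, p); reg("migrants", p)
  note("migrants: ", sum(mg$flagged), " flagged at alpha = ", config$alpha)

  report <- list(files = files, log = logs, seeds = seeds,
                 config = lapply(unclass(config), function(x)
                   if (is.null(x)) NA else x))
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(report)
}
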