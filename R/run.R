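#' Run the standard analysis pipeline over one or more snapshots
#'
#' For each PDB snapshot: build the Laguerre tessellation, then run the
#' requested analyses and write one CSV report per analysis per snapshot,
#' plus a plain-text run manifest (configuration echo and seed) sufficient
#' to reproduce the reports.
#'
#' @param paths Character vector of PDB paths (each may contain multiple
#'   MODELs).
#' @param cfg A [GroupingConfig-class].
#' @param region Optional [BoundedRegion-class] shared by all snapshots
#'   (default: auto-fitted box per snapshot).
#' @param analyses Subset of `c("components", "genus", "paths", "widest",
#'   "moments")`.
#' @param outDir Output directory (created if missing).
#' @param seed Integer seed (stored in the manifest; the pipeline itself is
#'   deterministic).
#' @param nWidest Widest-path iterations per snapshot.
#' @param dp Overlap penalty scale for widest paths.
#' @return Invisibly, a list of per-snapshot result lists.
#' @export
runAnalysis <- function(paths, cfg = groupingConfig(), region = NULL,
                        analyses = c("components", "genus", "paths"),
                        outDir = ".", seed = 1, nWidest = 3, dp = 0.1) {
  if (!length(paths)) stop("no input files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input file not found: ", missing[1])
  if (!length(analyses)) stop("at least one analysis must be enabled")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  results <- list()
  for (p in paths) {
    for (sys in readStructure(p)) {
      lab <- sys@label
      res <- list(label = lab)
      sites <- prepareSites(sys, cfg)
      tess <- buildTessellation(sites, region)
      res$tess <- tess
      if ("components" %in% analyses) {
        census <- waterComponentCensus(tess)
        writeCensusReport(census, tess, file.path(outDir, paste0(lab, "_components.csv")),
                          snapshot = lab)
        res$census <- census
      }
      if ("genus" %in% analyses) {
        doms <- list(protein = siteSelect(tess, kind = "protein"))
        plug <- intersect(doms$protein,
                          siteSelect(tess, range = cfg@plugRange))
        if (length(plug) && length(plug) < length(doms$protein)) {
          doms$plug <- plug
          doms$periphery <- setdiff(doms$protein, plug)
        }
        rep <- domainGenus(tess, doms)
        write.csv(cbind(snapshot = lab, rep),
                  file.path(outDir, paste0(lab, "_genus.csv")), row.names = FALSE)
        res$genus <- rep
      }
      if (any(c("paths", "widest") %in% analyses)) {
        regions <- pathRegions(tess, cfg)
        if ("paths" %in% analyses) {
          dpRes <- shortestDisjointPaths(tess, regions)
          write.csv(cbind(snapshot = lab, dpRes$census),
                    file.path(outDir, paste0(lab, "_path_census.csv")),
                    row.names = FALSE)
          res$disjoint <- dpRes
        }
        if ("widest" %in% analyses) {
          wp <- widestPaths(tess, regions, cost = costModel(dp = dp),
                            nIter = nWidest)
          writePathReport(wp, tess, file.path(outDir, paste0(lab, "_widest.csv")))
          res$widest <- wp
        }
      }
      if ("moments" %in% analyses) {
        prot <- siteSelect(tess, kind = "protein")
        res$moments <- quadraticMoments(tess, prot)
        write.csv(data.frame(snapshot = lab, t(res$moments)),
                  file.path(outDir, paste0(lab, "_moments.csv")), row.names = FALSE)
      }
      results[[lab]] <- res
    }
  }
  manifest <- c(
    sprintf("hydrotopo %s", as.character(utils::packageVersion("hydrotopo"))),
    sprintf("inputs: %s", paste(paths, collapse = ", ")),
    sprintf("analyses: %s", paste(analyses, collapse = ", ")),
    sprintf("seed: %d", seed),
    sprintf("water_weight: %g", cfg@waterWeight),
    sprintf("plug_range: %d-%d", cfg@plugRange[1], cfg@plugRange[2]),
    sprintf("membrane_axis: %s", cfg@membraneAxis))
  writeLines(manifest, file.path(outDir, "manifest.txt"))
  invisible(results)
}
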