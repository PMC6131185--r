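#' Connected components of a contact graph
#'
#' Partition of the graph's vertices into maximal connected subsets,
#' returned in deterministic order (by smallest member id).
#'
#' @param graph An [igraph::graph] whose vertex `name`s are site ids (as
#'   produced by [contactGraph()]).
#' @return List of sorted integer site-id vectors.
#' @export
connectedComponents <- function(graph) {
  if (igraph::vcount(graph) == 0) return(list())
  memb <- igraph::components(graph)$membership
  ids <- as.integer(igraph::V(graph)$name)
  comps <- lapply(split(ids, memb), sort)
  comps[order(vapply(comps, min, 1L))]
}

#' Census of the water network's connected components
#'
#' Components of the contact graph restricted to water sites.  The most
#' populous component is the main network; all others are inclusions
#' (isolated waters or pockets inside/against the solute).  Population
#' statistics of the inclusions use the population rms (divide by n).
#'
#' @param tess A [LaguerreTessellation-class] containing water sites.
#' @return A [ComponentCensus-class].
#' @export
waterComponentCensus <- function(tess) {
  wat <- setdiff(siteSelect(tess, kind = "water"), tess@emptyCells)
  if (!length(wat)) stop("tessellation contains no water sites")
  comps <- connectedComponents(contactGraph(tess, wat))
  pops <- lengths(comps)
  biggest <- which(pops == max(pops))
  if (length(biggest) > 1L) {
    warning("tie for the main water component; picking the one with the lowest site id")
    biggest <- biggest[which.min(vapply(comps[biggest], min, 1L))]
  }
  inc <- pops[-biggest[1]]
  new("ComponentCensus", components = comps, populations = as.integer(pops),
      mainIndex = as.integer(biggest[1]),
      nInclusions = length(comps) - 1L,
      popMean = if (length(inc)) mean(inc) else NA_real_,
      popRms = if (length(inc)) sqrt(mean((inc - mean(inc))^2)) else NA_real_)
}

#' @describeIn ComponentCensus-class Compact display.
#' @param object A `ComponentCensus`.
#' @export
setMethod("show", "ComponentCensus", function(object) {
  cat(sprintf("ComponentCensus: %d components, main population %d, %d inclusion(s)\n",
              length(object@components),
              object@populations[object@mainIndex], object@nInclusions))
  if (object@nInclusions > 0)
    cat(sprintf("  inclusion population %.2f +- %.2f (mean +- rms)\n",
                object@popMean, object@popRms))
  invisible(object)
})

#' @rdname waterComponentCensus
#' @param census A [ComponentCensus-class].
#' @return `mainComponent`: the integer site ids of the main network.
#' @export
mainComponent <- function(census) census@components[[census@mainIndex]]

# residue tag strings for a set of site rows
residueTags <- function(sites, ids) {
  s <- sites[match(ids, sites$id), ]
  unique(paste(s$chain, s$resno, s$resname, sep = ":"))
}

#' Protein residues lining a water component
#'
#' Residues owning at least one atom whose Laguerre cell shares a face with
#' any member of the component.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param members Integer site ids of one water component.
#' @return Character vector of residue tags `"chain:resno:resname"`
#'   (possibly empty for bulk components).
#' @export
pocketLiningResidues <- function(tess, members) {
  members <- as.integer(members)
  a <- tess@adjacency
  touch <- a[, 1] %in% members | a[, 2] %in% members
  other <- unique(c(a[touch & a[, 2] %in% members, 1],
                    a[touch & a[, 1] %in% members, 2]))
  prot <- intersect(other, siteSelect(tess, kind = "protein"))
  residueTags(tess@sites, prot)
}

#' Residues permanently bordering water pockets across snapshots
#'
#' For each snapshot, the union of residues lining any non-main water
#' component; the result is the intersection of those unions over all
#' snapshots.
#'
#' @param tessList List of [LaguerreTessellation-class] (>= 2 snapshots; a
#'   single snapshot returns its own lining set).
#' @return Character vector of residue tags.
#' @export
persistentPocketResidues <- function(tessList) {
  if (!length(tessList)) stop("empty snapshot series")
  perSnap <- lapply(tessList, function(tess) {
    census <- waterComponentCensus(tess)
    pockets <- census@components[-census@mainIndex]
    unique(unlist(lapply(pockets, function(m) pocketLiningResidues(tess, m))))
  })
  Reduce(intersect, perSnap)
}

#' Write a component census as CSV
#'
#' One row per component: snapshot label, component index, population,
#' main-component flag and the lining residue tags.
#'
#' @param census A [ComponentCensus-class].
#' @param tess The tessellation the census came from.
#' @param path Output path.
#' @param snapshot Snapshot label stored in the first column.
#' @return Invisibly, the data.frame written.
#' @export
writeCensusReport <- function(census, tess, path, snapshot = "") {
  df <- data.frame(
    snapshot = snapshot,
    component = seq_along(census@components),
    population = census@populations,
    is_main = seq_along(census@components) == census@mainIndex,
    lining = vapply(census@components, function(m)
      paste(pocketLiningResidues(tess, m), collapse = ";"), ""))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
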