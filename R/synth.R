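#' Generate a synthetic network with planted labeled neighborhoods
#'
#' Builds a background random graph with \code{kCliques} disjoint planted
#' cliques: clique members are fully interconnected with similarities drawn
#' uniformly from \code{simHigh}, every other entity pair is connected with
#' probability \code{backgroundDensity} at a similarity drawn uniformly from
#' \code{simBackground}, and within each clique
#' \code{ceiling(labelFraction * cliqueSize)} members receive a context
#' label. The high range must lie strictly above the background range: the
#' generator guarantees the ordinal structure the neighborhood algorithm
#' relies on, not any particular empirical similarity distribution (real
#' inputs range from STRING confidence scores to Tanimoto coefficients to
#' shared-gene counts). Fully reproducible from \code{rngSeed}.
#'
#' @param n total number of entities.
#' @param kCliques number of planted cliques.
#' @param cliqueSize entities per clique (\code{kCliques * cliqueSize <= n}).
#' @param labelFraction fraction of each clique that carries a label, in
#'   (0, 1].
#' @param simHigh length-2 range of within-clique similarities.
#' @param simBackground length-2 range of background similarities; must lie
#'   strictly below \code{simHigh}.
#' @param backgroundDensity probability of each non-clique pair being
#'   connected, in [0, 1].
#' @param weightedLabels if TRUE, labeled entities get scores uniform in
#'   [0.5, 1.5] instead of 1.
#' @param rngSeed integer RNG seed.
#'
#' @return list with components \code{graph} ([SimilarityGraph-class]),
#'   \code{labels} ([LabelMap-class]) and \code{truth}
#'   ([PlantedTruth-class]).
#' @examples
#' fx <- generatePlantedNetwork(n = 30, kCliques = 2, cliqueSize = 5,
#'                              labelFraction = 1, backgroundDensity = 0,
#'                              rngSeed = 7)
#' runHoods(fx$graph, fx$labels)
#' @export
generatePlantedNetwork <- function(n = 60, kCliques = 3, cliqueSize = 8,
                                   labelFraction = 0.75,
                                   simHigh = c(0.7, 0.95),
                                   simBackground = c(0.05, 0.4),
                                   backgroundDensity = 0.05,
                                   weightedLabels = FALSE, rngSeed = 42) {
  if (kCliques < 1 || cliqueSize < 2 || kCliques * cliqueSize > n)
    hoodsArgumentError("infeasible sizes: need kCliques >= 1, cliqueSize >= 2, kCliques * cliqueSize <= n")
  if (labelFraction <= 0 || labelFraction > 1)
    hoodsArgumentError("'labelFraction' must be in (0, 1]")
  if (backgroundDensity < 0 || backgroundDensity > 1)
    hoodsArgumentError("'backgroundDensity' must be in [0, 1]")
  if (length(simHigh) != 2L || length(simBackground) != 2L ||
      any(c(simHigh, simBackground) <= 0) ||
      min(simHigh) <= max(simBackground))
    hoodsArgumentError("'simHigh' must be a positive range strictly above 'simBackground'")
  simHigh <- sort(simHigh)
  simBackground <- sort(simBackground)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rngSeed)

  ents <- sprintf("E%03d", seq_len(n))
  cliques <- lapply(seq_len(kCliques), function(c)
    ents[((c - 1L) * cliqueSize + 1L):(c * cliqueSize)])
  cliqueOf <- integer(n)
  for (c in seq_len(kCliques))
    cliqueOf[match(cliques[[c]], ents)] <- c

  # all pairs i < j; within-clique pairs always present at high similarity
  pairs <- utils::combn(n, 2L)
  sameClique <- cliqueOf[pairs[1L, ]] != 0L &
    cliqueOf[pairs[1L, ]] == cliqueOf[pairs[2L, ]]
  nHigh <- sum(sameClique)
  bg <- which(!sameClique)
  bgKeep <- bg[stats::runif(length(bg)) < backgroundDensity]

  a <- ents[c(pairs[1L, sameClique], pairs[1L, bgKeep])]
  b <- ents[c(pairs[2L, sameClique], pairs[2L, bgKeep])]
  sim <- c(stats::runif(nHigh, simHigh[1L], simHigh[2L]),
           stats::runif(length(bgKeep), simBackground[1L], simBackground[2L]))
  graph <- SimilarityGraph(
    data.frame(a = a, b = b, sim = sim, stringsAsFactors = FALSE),
    entities = ents)

  nLab <- ceiling(labelFraction * cliqueSize)
  labeled <- unlist(lapply(cliques, function(cl) sort(sample(cl, nLab))))
  scores <- if (weightedLabels)
    stats::runif(length(labeled), 0.5, 1.5) else rep(1, length(labeled))
  labels <- LabelMap(setNames(scores, labeled))

  truth <- new("PlantedTruth", cliques = cliques, labeled = labeled,
               background = setdiff(ents, unlist(cliques)),
               params = list(n = n, kCliques = kCliques,
                             cliqueSize = cliqueSize,
                             labelFraction = labelFraction,
                             simHigh = simHigh,
                             simBackground = simBackground,
                             backgroundDensity = backgroundDensity,
                             weightedLabels = weightedLabels,
                             rngSeed = rngSeed))
  list(graph = graph, labels = labels, truth = truth)
}

#' Components of a planted ground truth
#'
#' @param x a [PlantedTruth-class].
#' @return the planted cliques (list), labeled entities (character), or
#'   generator parameters (list).
#' @export
setGeneric("plantedCliques", function(x) standardGeneric("plantedCliques"))

#' @rdname plantedCliques
#' @export
setMethod("plantedCliques", "PlantedTruth", function(x) x@cliques)

#' @rdname plantedCliques
#' @export
setGeneric("plantedLabeled", function(x) standardGeneric("plantedLabeled"))

#' @rdname plantedCliques
#' @export
setMethod("plantedLabeled", "PlantedTruth", function(x) x@labeled)

#' @rdname plantedCliques
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))

#' @rdname plantedCliques
#' @export
setMethod("truthParams", "PlantedTruth", function(x) x@params)

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@cliques), "cliques of sizes",
      paste(lengths(object@cliques), collapse = ", "), "|",
      length(object@labeled), "labeled entities |",
      length(object@background), "background entities\n")
})

#' Score recovery of planted cliques by a ranked neighborhood set
#'
#' For each planted clique, takes the best Jaccard index between the clique
#' and any kept neighborhood's member set, and averages over cliques. 1
#' means every clique was recovered exactly by some neighborhood; 0 means no
#' overlap at all (an empty ranked set scores 0).
#'
#' @param ranked a ranked [NeighborhoodSet-class].
#' @param truth a [PlantedTruth-class].
#' @return numeric in [0, 1].
#' @export
recoveryMetric <- function(ranked, truth) {
  if (!is(ranked, "NeighborhoodSet") || !is(truth, "PlantedTruth"))
    hoodsArgumentError("'ranked' must be a NeighborhoodSet and 'truth' a PlantedTruth")
  if (length(truth@cliques) == 0L)
    hoodsArgumentError("the truth contains no planted cliques")
  members <- ranked@table$members
  if (length(members) == 0L) return(0)
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  mean(vapply(truth@cliques, function(cl)
    max(vapply(members, jac, numeric(1), y = cl)), numeric(1)))
}

#' Write a generated fixture to TSV files
#'
#' Writes \code{<prefix>matrix.tsv} (edge list), \code{<prefix>labels.tsv}
#' and \code{<prefix>truth.tsv} (clique id, entity) for a fixture produced
#' by [generatePlantedNetwork()].
#'
#' @param fixture list as returned by [generatePlantedNetwork()].
#' @param outPrefix path prefix for the three output files.
#' @return invisibly, the three paths.
#' @export
writePlantedFixture <- function(fixture, outPrefix) {
  paths <- paste0(outPrefix, c("matrix.tsv", "labels.tsv", "truth.tsv"))
  writeSimilarityTsv(fixture$graph, paths[1L])
  writeLabelsTsv(fixture$labels, paths[2L])
  cl <- fixture$truth@cliques
  rows <- unlist(lapply(seq_along(cl), function(c)
    paste(c, cl[[c]], sep = "\t")))
  writeLines(c("clique\tentity", rows), paths[3L])
  invisible(paths)
}
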