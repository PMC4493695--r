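#' @import methods
NULL

#' SimilarityGraph: a symmetric weighted entity graph
#'
#' Holds the similarity "matrix" input: a set of opaque entity identifiers
#' and symmetric, strictly positive pairwise similarities (larger = more
#' similar). Typical sources are STRING confidence scores between proteins,
#' Tanimoto coefficients between chemical fingerprints, or shared-gene
#' counts between diseases. Edges are stored canonically with
#' \code{a < b} (lexicographic) and no self-edges.
#'
#' @slot entities character vector of unique entity identifiers.
#' @slot edges data.frame with columns \code{a}, \code{b} (character) and
#'   \code{sim} (positive numeric), one row per unordered pair.
#'
#' @seealso [SimilarityGraph()] for construction,
#'   [readSimilarityTsv()] to read one from a TSV edge list.
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
  representation(entities = "character", edges = "data.frame"),
  prototype(
    entities = character(0),
    edges = data.frame(a = character(0), b = character(0),
                       sim = numeric(0), stringsAsFactors = FALSE)
  )
)

setValidity("SimilarityGraph", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (!identical(colnames(e), c("a", "b", "sim")))
    return("edges must have columns a, b, sim")
  if (anyDuplicated(object@entities))
    msgs <- c(msgs, "entity identifiers must be unique")
  if (nrow(e) > 0) {
    if (any(e$a == e$b))
      msgs <- c(msgs, "self-edges are not allowed")
    if (any(!is.finite(e$sim)) || any(e$sim <= 0))
      msgs <- c(msgs, "all similarities must be finite and > 0")
    if (any(e$a > e$b))
      msgs <- c(msgs, "edges must be stored canonically with a < b")
    if (anyDuplicated(paste0(e$a, "\r", e$b)))
      msgs <- c(msgs, "duplicate edges are not allowed")
    if (!all(c(e$a, e$b) %in% object@entities))
      msgs <- c(msgs, "every edge endpoint must be a known entity")
  }
  if (length(msgs)) msgs else TRUE
})

#' LabelMap: per-entity context association scores
#'
#' Holds the "labels" input: a map from entity identifier to a non-negative
#' context score \eqn{s_i} (disease z-score, percent kinase inhibition, or
#' binary membership). Entities absent from the map implicitly have
#' \eqn{s_i = 0}. The map may contain entities that are not in the graph;
#' they are ignored with a warning when the algorithm runs.
#'
#' @slot scores named non-negative numeric vector.
#'
#' @seealso [LabelMap()], [readLabelsTsv()]
#' @exportClass LabelMap
setClass("LabelMap", representation(scores = "numeric"),
         prototype(scores = setNames(numeric(0), character(0))))

setValidity("LabelMap", function(object) {
  s <- object@scores
  msgs <- character(0)
  if (length(s) && (is.null(names(s)) || any(!nzchar(names(s)))))
    msgs <- c(msgs, "all scores must be named by entity id")
  if (anyDuplicated(names(s)))
    msgs <- c(msgs, "entity ids must be unique")
  if (any(!is.finite(s)) || any(s < 0))
    msgs <- c(msgs, "all label scores must be finite and >= 0")
  if (length(msgs)) msgs else TRUE
})

#' NeighborhoodSet: candidate or ranked context-specific neighborhoods
#'
#' A collection of candidate neighborhoods, each a seed entity plus a prefix
#' of its similarity-sorted neighbors, scored by
#' \eqn{S_j = (\sum_{i=1}^j s_i) / j^\alpha}. An unranked set
#' (\code{ranked = FALSE}) is the raw output of candidate enumeration; a
#' ranked set (\code{ranked = TRUE}, from [rankAndFilter()]) is sorted by
#' descending score, redundancy-filtered, and carries per-entry novelty
#' bookkeeping: \code{newLabeled} (labeled members unseen in higher-ranked
#' kept entries), \code{newEntities} (members unseen in higher-ranked kept
#' entries) and \code{cumulativeEntities} (distinct members used so far).
#'
#' @slot table data.frame with one row per neighborhood; columns \code{seed},
#'   \code{size}, \code{labelSum}, \code{score} plus list-columns
#'   \code{members} (seed first, then neighbors by descending similarity)
#'   and \code{labeledMembers}; ranked sets add \code{rank},
#'   \code{newLabeled}, \code{newEntities}, \code{cumulativeEntities}.
#' @slot alpha the size-penalty exponent the scores were computed with.
#' @slot ranked logical; whether ranking and redundancy filtering have been
#'   applied.
#'
#' @seealso [runHoods()], [rankAndFilter()], [nhoodTable()]
#' @exportClass NeighborhoodSet
setClass("NeighborhoodSet",
  representation(table = "data.frame", alpha = "numeric", ranked = "logical")
)

.emptyNhoodTable <- function(ranked = FALSE) {
  tab <- data.frame(seed = character(0), size = integer(0),
                    labelSum = numeric(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  tab$members <- list()
  tab$labeledMembers <- list()
  if (ranked) {
    tab$rank <- integer(0)
    tab$newLabeled <- integer(0)
    tab$newEntities <- integer(0)
    tab$cumulativeEntities <- integer(0)
  }
  tab
}

setValidity("NeighborhoodSet", function(object) {
  tab <- object@table
  msgs <- character(0)
  need <- c("seed", "size", "labelSum", "score", "members", "labeledMembers")
  if (!all(need %in% colnames(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must be a single number in [0, 1]")
  if (nrow(tab) > 0) {
    sizes <- lengths(tab$members)
    if (!all(tab$size == sizes))
      msgs <- c(msgs, "size must equal the number of members")
    if (any(lengths(tab$labeledMembers) < 2L))
      msgs <- c(msgs, "every neighborhood must contain >= 2 labeled members")
    if (!all(mapply(function(l, m) all(l %in% m),
                    tab$labeledMembers, tab$members)))
      msgs <- c(msgs, "labeled members must be a subset of members")
    if (!all(mapply(function(l, m) m[length(m)] %in% l,
                    tab$labeledMembers, tab$members)))
      msgs <- c(msgs, "the last member must be a labeled entity")
    if (any(tab$labelSum < 0))
      msgs <- c(msgs, "label sums must be >= 0")
    expected <- tab$labelSum / tab$size^object@alpha
    if (any(abs(tab$score - expected) > 1e-9))
      msgs <- c(msgs, "scores must equal labelSum / size^alpha")
  }
  if (isTRUE(object@ranked) && nrow(tab) > 0) {
    extra <- c("rank", "newLabeled", "newEntities", "cumulativeEntities")
    if (!all(extra %in% colnames(tab)))
      return(paste("ranked table must also have columns:",
                   paste(extra, collapse = ", ")))
    if (is.unsorted(-tab$score))
      msgs <- c(msgs, "scores must be non-increasing down a ranked set")
    if (any(tab$newEntities < 1L) || any(tab$newLabeled < 1L))
      msgs <- c(msgs, "every kept entry must add >= 1 new entity and >= 1 new labeled entity")
    cum <- cumsum(vapply(seq_len(nrow(tab)), function(i) {
      length(setdiff(tab$members[[i]],
                     unique(unlist(tab$members[seq_len(i - 1L)]))))
    }, integer(1)))
    if (!all(tab$cumulativeEntities == cum))
      msgs <- c(msgs, "cumulativeEntities must track the running union of members")
  }
  if (length(msgs)) msgs else TRUE
})

#' PlantedTruth: ground truth of a synthetic planted-neighborhood network
#'
#' Records what [generatePlantedNetwork()] planted: the disjoint
#' high-similarity cliques, which entities carry labels, the background
#' entities, and the generator parameters, so recovery can be scored with
#' [recoveryMetric()].
#'
#' @slot cliques list of character vectors, the planted (pairwise disjoint)
#'   cliques.
#' @slot labeled character vector of labeled entities (subset of the clique
#'   union).
#' @slot background character vector of entities outside all cliques.
#' @slot params named list of the generator parameters, including the RNG
#'   seed.
#'
#' @exportClass PlantedTruth
setClass("PlantedTruth",
  representation(cliques = "list", labeled = "character",
                 background = "character", params = "list")
)

setValidity("PlantedTruth", function(object) {
  msgs <- character(0)
  all_members <- unlist(object@cliques)
  if (anyDuplicated(all_members))
    msgs <- c(msgs, "planted cliques must be pairwise disjoint")
  if (!all(object@labeled %in% all_members))
    msgs <- c(msgs, "labeled entities must lie inside the planted cliques")
  if (any(object@background %in% all_members))
    msgs <- c(msgs, "background entities must lie outside the cliques")
  p <- object@params
  if (all(c("simHigh", "simBackground") %in% names(p)) &&
      min(p$simHigh) <= max(p$simBackground))
    msgs <- c(msgs, "simHigh range must lie strictly above simBackground range")
  if (length(msgs)) msgs else TRUE
})

#' LoocvSummary: leave-one-out cross-validation results
#'
#' Per-entity recovery ranks and per-threshold recovery counts from a
#' leave-one-out cross-validation benchmark. The rank of a left-out entity
#' is the number of distinct entities accumulated over the ranked
#' neighborhoods up to and including the first neighborhood that contains
#' it; recovery at threshold t means rank <= t.
#'
#' @slot ranks data.frame with columns \code{entity}, \code{rank} (NA when
#'   not found) and \code{found}.
#' @slot summary data.frame with columns \code{alpha}, \code{threshold},
#'   \code{recovered}, \code{total}, \code{ciLow}, \code{ciHigh}
#'   (Clopper-Pearson 95\% binomial interval on the recovered proportion).
#' @slot alpha the size-penalty exponent used.
#'
#' @seealso [runLoocv()], [randomLabelControl()], [alphaSweep()]
#' @exportClass LoocvSummary
setClass("LoocvSummary",
  representation(ranks = "data.frame", summary = "data.frame",
                 alpha = "numeric")
)

setValidity("LoocvSummary", function(object) {
  s <- object@summary
  msgs <- character(0)
  if (!all(c("alpha", "threshold", "recovered", "total",
             "ciLow", "ciHigh") %in% colnames(s)))
    return("summary is missing required columns")
  if (nrow(s) > 1) {
    o <- order(s$threshold)
    if (is.unsorted(s$recovered[o]))
      msgs <- c(msgs, "recovered counts must be non-decreasing in threshold")
  }
  if (any(s$recovered > s$total))
    msgs <- c(msgs, "recovered counts cannot exceed the benchmark size")
  if (length(msgs)) msgs else TRUE
})
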