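#' Neighborhood score
#'
#' Scores a neighborhood of \code{size} members with total label score
#' \code{labelSum} as
#' \deqn{S_j = \left(\sum_{i=1}^j s_i / j\right)^\alpha \times
#'       \left(\sum_{i=1}^j s_i\right)^{1-\alpha}
#'     = \left(\sum_{i=1}^j s_i\right) / j^\alpha,}
#' a weighted geometric mean of the label density and the total label score.
#' \code{alpha = 1} gives pure density, \code{alpha = 0} the pure total;
#' intermediate values penalize large neighborhoods progressively less.
#'
#' @param labelSum total label score over the members (\eqn{\sum s_i}),
#'   non-negative; vectorized.
#' @param size number of members \eqn{j}, a positive integer; vectorized.
#' @param alpha size-penalty exponent in [0, 1]; default 0.8.
#'
#' @return numeric vector of scores.
#' @examples
#' neighborhoodScore(3, 4, alpha = 0.8)   # 3 / 4^0.8
#' neighborhoodScore(4, 4, alpha = 1)     # pure density: 1
#' @export
neighborhoodScore <- function(labelSum, size, alpha = 0.8) {
  alpha <- .checkAlpha(alpha)
  if (!is.numeric(labelSum) || any(!is.finite(labelSum)) || any(labelSum < 0))
    hoodsArgumentError("'labelSum' must be finite and >= 0")
  if (!is.numeric(size) || any(!is.finite(size)) || any(size < 1) ||
      any(size != floor(size)))
    hoodsArgumentError("'size' must be a positive integer")
  labelSum / size^alpha
}

# enumerate candidates for one seed given its sorted neighbor vector
.enumerateSeed <- function(seed, neighbors, labels, alpha, maxSize) {
  members <- c(seed, neighbors)
  if (length(members) > maxSize)
    members <- members[seq_len(maxSize)]
  s <- .scoreOf(labels, members)
  lab <- s > 0
  cumLab <- cumsum(lab)
  cumSum <- cumsum(s)
  # a candidate is emitted at every prefix that ends at a labeled entity and
  # already contains at least two labeled entities
  emit <- which(lab & cumLab >= 2L)
  if (length(emit) == 0L)
    return(.emptyNhoodTable())
  tab <- data.frame(seed = rep(seed, length(emit)),
                    size = emit,
                    labelSum = cumSum[emit],
                    score = cumSum[emit] / emit^alpha,
                    stringsAsFactors = FALSE)
  tab$members <- lapply(emit, function(j) members[seq_len(j)])
  tab$labeledMembers <- lapply(emit, function(j) members[seq_len(j)][lab[seq_len(j)]])
  tab
}

#' Enumerate candidate neighborhoods for one seed
#'
#' Grows a neighborhood from \code{seed} by walking its direct neighbors in
#' order of descending similarity (ties broken lexicographically by entity
#' id). A candidate is emitted at every prefix whose final member is a
#' labeled entity (\eqn{s_i > 0}), provided the prefix contains at least two
#' labeled entities. The seed itself is member 1 and its own label score
#' contributes to the label sum. Expansion stops when neighbors are
#' exhausted or \code{maxSize} members are reached.
#'
#' @param graph a [SimilarityGraph-class].
#' @param labels a [LabelMap-class].
#' @param seed entity id; must be in the graph.
#' @param alpha size-penalty exponent in [0, 1]; default 0.8.
#' @param maxSize maximum number of members per neighborhood (default
#'   unlimited).
#'
#' @return An unranked [NeighborhoodSet-class] (possibly empty: a seed that
#'   cannot reach two labeled entities yields no candidates).
#' @seealso [buildAllCandidates()], [runHoods()]
#' @export
enumerateCandidates <- function(graph, labels, seed, alpha = 0.8,
                                maxSize = Inf) {
  alpha <- .checkAlpha(alpha)
  maxSize <- .checkMaxSize(maxSize)
  if (!is(graph, "SimilarityGraph") || !is(labels, "LabelMap"))
    hoodsArgumentError("'graph' must be a SimilarityGraph and 'labels' a LabelMap")
  if (length(seed) != 1L || !seed %in% graph@entities)
    hoodsArgumentError(paste0("seed '", seed, "' is not in the graph"))
  adj <- .adjacencyList(graph)
  tab <- .enumerateSeed(seed, adj[[seed]]$neighbor, labels, alpha, maxSize)
  new("NeighborhoodSet", table = tab, alpha = alpha, ranked = FALSE)
}

#' Enumerate candidate neighborhoods from every seed
#'
#' Runs the per-seed enumeration of [enumerateCandidates()] with every graph
#' entity as the seed, in lexicographic seed order, and concatenates the
#' results. Labeled entities that do not occur in the graph are ignored with
#' a warning.
#'
#' @inheritParams enumerateCandidates
#' @return An unranked [NeighborhoodSet-class].
#' @export
buildAllCandidates <- function(graph, labels, alpha = 0.8, maxSize = Inf) {
  alpha <- .checkAlpha(alpha)
  maxSize <- .checkMaxSize(maxSize)
  if (!is(graph, "SimilarityGraph") || !is(labels, "LabelMap"))
    hoodsArgumentError("'graph' must be a SimilarityGraph and 'labels' a LabelMap")
  if (length(graph@entities) == 0L)
    hoodsArgumentError("the graph has no entities")
  missing <- setdiff(labeledEntities(labels), graph@entities)
  if (length(missing))
    warning(length(missing), " labeled entit(y/ies) absent from the graph ",
            "are ignored: ", paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
  adj <- .adjacencyList(graph)
  tabs <- lapply(graph@entities, function(seed)
    .enumerateSeed(seed, adj[[seed]]$neighbor, labels, alpha, maxSize))
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0L) tab <- .emptyNhoodTable()
  rownames(tab) <- NULL
  new("NeighborhoodSet", table = tab, alpha = alpha, ranked = FALSE)
}

#' Rank candidates and filter out redundant neighborhoods
#'
#' Sorts candidate neighborhoods by descending score (ties broken by larger
#' label sum, then smaller size, then lexicographic seed id, then member
#' list) and walks down the ranking keeping an entry only if it contributes
#' at least one labeled member not seen in any higher-ranked kept entry
#' (which also guarantees its labeled-member set differs from every kept
#' entry's) and at least one member, labeled or not, not seen in any
#' higher-ranked kept entry. Each kept entry records how many new labeled
#' members and new members it contributed and the running count of distinct
#' entities used.
#'
#' @param candidates an unranked [NeighborhoodSet-class], e.g. from
#'   [buildAllCandidates()].
#' @return A ranked [NeighborhoodSet-class].
#' @export
rankAndFilter <- function(candidates) {
  if (!is(candidates, "NeighborhoodSet"))
    hoodsArgumentError("'candidates' must be a NeighborhoodSet")
  tab <- candidates@table
  if (nrow(tab) == 0L)
    return(new("NeighborhoodSet", table = .emptyNhoodTable(ranked = TRUE),
               alpha = candidates@alpha, ranked = TRUE))
  memberKey <- vapply(tab$members, paste, character(1), collapse = ",")
  o <- order(-tab$score, -tab$labelSum, tab$size, tab$seed, memberKey,
             method = "radix")
  tab <- tab[o, , drop = FALSE]

  n <- nrow(tab)
  keep <- logical(n)
  newLabeled <- integer(n)
  newEntities <- integer(n)
  cumulative <- integer(n)
  seenAll <- character(0)
  seenLabeled <- character(0)
  for (i in seq_len(n)) {
    nl <- setdiff(tab$labeledMembers[[i]], seenLabeled)
    ne <- setdiff(tab$members[[i]], seenAll)
    if (length(nl) >= 1L && length(ne) >= 1L) {
      keep[i] <- TRUE
      newLabeled[i] <- length(nl)
      newEntities[i] <- length(ne)
      seenLabeled <- c(seenLabeled, nl)
      seenAll <- c(seenAll, ne)
      cumulative[i] <- length(seenAll)
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$newLabeled <- newLabeled[keep]
  tab$newEntities <- newEntities[keep]
  tab$cumulativeEntities <- cumulative[keep]
  rownames(tab) <- NULL
  new("NeighborhoodSet", table = tab, alpha = candidates@alpha, ranked = TRUE)
}

#' Find ranked, non-redundant, context-specific neighborhoods
#'
#' The full pipeline: every graph entity is tried as a seed
#' ([buildAllCandidates()]), candidates are scored by
#' \eqn{S_j = (\sum s_i)/j^\alpha}, and the ranked list is redundancy-
#' filtered ([rankAndFilter()]). Deterministic for fixed inputs.
#'
#' @inheritParams enumerateCandidates
#' @param normalizeLabels if TRUE, min-max rescale the stored label scores
#'   to [0, 1] before running (off by default; raw scores such as percent
#'   inhibition, z-scores or binary indicators are used as-is).
#'
#' @return A ranked [NeighborhoodSet-class].
#' @examples
#' g <- SimilarityGraph(data.frame(a = c("A", "A", "A"),
#'                                 b = c("B", "C", "D"),
#'                                 sim = c(0.9, 0.8, 0.7)))
#' l <- LabelMap(c(B = 1, D = 1))
#' runHoods(g, l, alpha = 0.8)
#' @export
runHoods <- function(graph, labels, alpha = 0.8, maxSize = Inf,
                     normalizeLabels = FALSE) {
  if (isTRUE(normalizeLabels))
    labels <- .normalizeLabels(labels)
  rankAndFilter(buildAllCandidates(graph, labels, alpha, maxSize))
}
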