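# Leave-one-out cross-validation benchmark: hold out one labeled entity,
# rebuild the neighborhoods without its label, and count how many distinct
# entities must be consumed, walking the ranked neighborhoods from the top,
# before the held-out entity appears (including the whole neighborhood that
# contains it).

# rank of `entity` in a ranked set: distinct entities accumulated up to and
# including the first kept neighborhood containing it
.rankInSet <- function(ranked, entity) {
  tab <- ranked@table
  seen <- character(0)
  for (i in seq_len(nrow(tab))) {
    seen <- union(seen, tab$members[[i]])
    if (entity %in% tab$members[[i]])
      return(list(rank = length(seen), found = TRUE))
  }
  list(rank = NA_integer_, found = FALSE)
}

# core LOOCV step without the labeled-entity precondition (the random-label
# control holds out entities that are unlabeled under the substituted map)
.loocvRankRaw <- function(graph, labels, leftOut, alpha, maxSize) {
  s <- labels@scores
  s[leftOut] <- 0
  held <- new("LabelMap", scores = s[order(names(s), method = "radix")])
  ranked <- suppressWarnings(runHoods(graph, held, alpha, maxSize))
  r <- .rankInSet(ranked, leftOut)
  list(entity = leftOut, rank = r$rank, found = r$found)
}

#' LOOCV recovery rank of one held-out entity
#'
#' Sets the label score of \code{leftOut} to zero, reruns the full
#' neighborhood pipeline, and walks the kept neighborhoods in rank order
#' accumulating the union of their members; the rank is the size of that
#' union at the first neighborhood containing \code{leftOut} (i.e., the
#' total number of unique entities encountered before finding it, including
#' all members of the neighborhood that contains it).
#'
#' @inheritParams enumerateCandidates
#' @param leftOut a labeled entity id to hold out.
#' @return list with \code{entity}, \code{rank} (positive integer, NA if not
#'   found) and \code{found} (logical).
#' @seealso [runLoocv()]
#' @export
loocvRank <- function(graph, labels, leftOut, alpha = 0.8, maxSize = Inf) {
  if (length(leftOut) != 1L || .scoreOf(labels, leftOut) <= 0)
    hoodsArgumentError(paste0("left-out entity '", leftOut,
                              "' has no positive label score"))
  .loocvRankRaw(graph, labels, leftOut, alpha, maxSize)
}

.summarizeRanks <- function(ranks, alpha, thresholds) {
  thresholds <- sort(as.integer(thresholds))
  total <- nrow(ranks)
  rows <- lapply(thresholds, function(t) {
    rec <- sum(ranks$found & ranks$rank <= t)
    ci <- stats::binom.test(rec, total)$conf.int
    data.frame(alpha = alpha, threshold = t, recovered = rec, total = total,
               ciLow = ci[1L], ciHigh = ci[2L])
  })
  new("LoocvSummary", ranks = ranks, summary = do.call(rbind, rows),
      alpha = alpha)
}

#' Run the leave-one-out cross-validation benchmark
#'
#' Applies [loocvRank()] to every benchmark entity and reports, for each
#' threshold t, how many entities were recovered among the first t entities
#' used (rank <= t, inclusive), with an exact (Clopper-Pearson) 95\%
#' binomial confidence interval on the recovered proportion. Entities whose
#' neighborhood vanishes when their label is removed are counted as not
#' recovered at every threshold.
#'
#' @inheritParams enumerateCandidates
#' @param benchmark character vector of labeled entities to hold out, one at
#'   a time.
#' @param thresholds integer thresholds for "recovered among the first t
#'   entities"; default \code{c(25, 50, 100)}.
#' @return A [LoocvSummary-class].
#' @export
runLoocv <- function(graph, labels, benchmark, alpha = 0.8,
                     thresholds = c(25, 50, 100), maxSize = Inf) {
  alpha <- .checkAlpha(alpha)
  if (length(benchmark) == 0L)
    hoodsArgumentError("the benchmark set is empty")
  unlabeled <- benchmark[.scoreOf(labels, benchmark) <= 0]
  if (length(unlabeled))
    hoodsArgumentError(paste0("benchmark entit(y/ies) without a positive label: ",
                              paste(utils::head(unlabeled, 5), collapse = ", ")))
  res <- lapply(benchmark, function(e)
    .loocvRankRaw(graph, labels, e, alpha, maxSize))
  ranks <- data.frame(entity = vapply(res, `[[`, character(1), "entity"),
                      rank = vapply(res, `[[`, integer(1), "rank"),
                      found = vapply(res, `[[`, logical(1), "found"),
                      stringsAsFactors = FALSE)
  .summarizeRanks(ranks, alpha, thresholds)
}

#' Random-label control for the LOOCV benchmark
#'
#' Repeats the leave-one-out benchmark with deliberately wrong context: for
#' each benchmark entity, a uniformly random admissible alternative label
#' set is substituted for the informative one before measuring recovery.
#' This controls for recovery driven by network topology (e.g., well-studied
#' hub entities) rather than by the context labels. Admissibility: an
#' alternative must not be the entity's own label set (when
#' \code{benchmarkSets} is given) and, when \code{categories} is given, must
#' not share a category with it (e.g., two diseases affecting the same
#' physiological system). Absent both mappings, all alternatives are
#' admissible.
#'
#' @inheritParams runLoocv
#' @param labelSets named list of at least two [LabelMap-class] objects.
#' @param benchmarkSets optional named character vector mapping each
#'   benchmark entity to the name of its own label set.
#' @param categories optional named character vector mapping label-set names
#'   to a category used by the exclusion rule.
#' @param rngSeed integer seed governing all random label assignment
#'   (default 42; logged).
#' @return A [LoocvSummary-class].
#' @export
randomLabelControl <- function(graph, labelSets, benchmark, alpha = 0.8,
                               thresholds = c(25, 50, 100), rngSeed = 42,
                               benchmarkSets = NULL, categories = NULL,
                               maxSize = Inf) {
  alpha <- .checkAlpha(alpha)
  if (!is.list(labelSets) || length(labelSets) < 2L)
    hoodsArgumentError("'labelSets' must be a list of >= 2 LabelMap objects")
  if (is.null(names(labelSets)) || any(!nzchar(names(labelSets))))
    hoodsArgumentError("'labelSets' must be named")
  if (length(benchmark) == 0L)
    hoodsArgumentError("the benchmark set is empty")
  setNames_ <- names(labelSets)
  message("random-label control with RNG seed ", rngSeed)
  benchmark <- sort(benchmark)   # deterministic draw order
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rngSeed)
  res <- lapply(benchmark, function(e) {
    admissible <- setNames_
    if (!is.null(benchmarkSets) && !is.na(benchmarkSets[e])) {
      own <- benchmarkSets[[e]]
      admissible <- setdiff(admissible, own)
      if (!is.null(categories) && !is.na(categories[own]))
        admissible <- admissible[is.na(categories[admissible]) |
                                 categories[admissible] != categories[[own]]]
    }
    if (length(admissible) == 0L)
      hoodsArgumentError(paste0("no admissible alternative label set for '",
                                e, "'"))
    pick <- if (length(admissible) == 1L) admissible else
      admissible[sample.int(length(admissible), 1L)]
    .loocvRankRaw(graph, labelSets[[pick]], e, alpha, maxSize)
  })
  ranks <- data.frame(entity = vapply(res, `[[`, character(1), "entity"),
                      rank = vapply(res, `[[`, integer(1), "rank"),
                      found = vapply(res, `[[`, logical(1), "found"),
                      stringsAsFactors = FALSE)
  .summarizeRanks(ranks, alpha, thresholds)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Sweep the size-penalty exponent over the LOOCV benchmark
#'
#' Runs [runLoocv()] once per alpha value; used to assess how sensitive
#' recovery is to the size penalty (performance is typically flat for alpha
#' between 0.6 and 1).
#'
#' @inheritParams runLoocv
#' @param alphas numeric vector of exponents, each in [0, 1].
#' @return named list of [LoocvSummary-class], one per alpha.
#' @export
alphaSweep <- function(graph, labels, benchmark, alphas,
                       thresholds = c(25, 50, 100), maxSize = Inf) {
  if (length(alphas) == 0L)
    hoodsArgumentError("'alphas' is empty")
  lapply(alphas, .checkAlpha)
  out <- lapply(alphas, function(a)
    runLoocv(graph, labels, benchmark, a, thresholds, maxSize))
  names(out) <- as.character(alphas)
  out
}

#' @rdname alphaUsed
#' @export
setMethod("alphaUsed", "LoocvSummary", function(x) x@alpha)

#' Per-entity ranks / per-threshold summary of a LOOCV run
#'
#' @param x a [LoocvSummary-class].
#' @return data.frame (see the class slots).
#' @export
setGeneric("loocvRanks", function(x) standardGeneric("loocvRanks"))

#' @rdname loocvRanks
#' @export
setMethod("loocvRanks", "LoocvSummary", function(x) x@ranks)

#' @rdname loocvRanks
#' @export
setGeneric("loocvSummaryTable", function(x) standardGeneric("loocvSummaryTable"))

#' @rdname loocvRanks
#' @export
setMethod("loocvSummaryTable", "LoocvSummary", function(x) x@summary)

setMethod("show", "LoocvSummary", function(object) {
  cat("LoocvSummary over", nrow(object@ranks), "held-out entities",
      paste0("(alpha = ", object@alpha, ")\n"))
  print(object@summary, row.names = FALSE)
})
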