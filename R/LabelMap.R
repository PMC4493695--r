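#' Construct a LabelMap
#'
#' Builds the per-entity context score map \eqn{s_i}. Scores must be finite;
#' negative scores (e.g., text-mining z-scores below zero) are clamped to 0
#' with a warning, since the neighborhood score assumes \eqn{s_i \ge 0}.
#' Duplicate entities keep the maximum score (logged).
#'
#' @param scores named numeric vector (entity id -> score), or a character
#'   vector of entity ids, which are all given score 1 (binary labels).
#'
#' @return A [LabelMap-class] object.
#' @examples
#' LabelMap(c(TP53 = 3.5, BRCA1 = 2.1))
#' LabelMap(c("P1", "P2"))   # binary labels
#' @export
LabelMap <- function(scores = numeric(0)) {
  if (is.character(scores))
    scores <- setNames(rep(1, length(scores)), scores)
  scores <- unlist(scores)
  if (length(scores) == 0L)
    return(new("LabelMap", scores = setNames(numeric(0), character(0))))
  if (is.null(names(scores)))
    hoodsArgumentError("'scores' must be named by entity id")
  scores <- setNames(as.numeric(scores), names(scores))
  if (any(!is.finite(scores)))
    hoodsArgumentError("all label scores must be finite")
  if (anyDuplicated(names(scores))) {
    message("merged ", length(scores) - length(unique(names(scores))),
            " duplicate label(s) by maximum score")
    scores <- vapply(split(scores, names(scores)), max, numeric(1))
  }
  neg <- scores < 0
  if (any(neg)) {
    warning(sum(neg), " negative label score(s) clamped to 0", call. = FALSE)
    scores[neg] <- 0
  }
  scores <- scores[order(names(scores), method = "radix")]
  new("LabelMap", scores = scores)
}

#' Label scores stored in a map
#'
#' @param x a [LabelMap-class].
#' @return named numeric vector of stored scores.
#' @export
setGeneric("labelScores", function(x) standardGeneric("labelScores"))

#' @rdname labelScores
#' @export
setMethod("labelScores", "LabelMap", function(x) x@scores)

#' Entities with a strictly positive label score
#'
#' @param x a [LabelMap-class].
#' @return character vector of labeled entity ids.
#' @export
setGeneric("labeledEntities", function(x) standardGeneric("labeledEntities"))

#' @rdname labeledEntities
#' @export
setMethod("labeledEntities", "LabelMap",
          function(x) names(x@scores)[x@scores > 0])

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap with", length(object@scores), "entries (",
      sum(object@scores > 0), "labeled )\n")
})

# score lookup with implicit 0 for absent entities
.scoreOf <- function(labels, ids) {
  s <- labels@scores[ids]
  s[is.na(s)] <- 0
  unname(s)
}

# optional min-max rescaling of the stored scores to [0, 1]; can unlabel the
# minimum-scoring entity, hence the warning
.normalizeLabels <- function(labels) {
  s <- labels@scores
  if (length(s) == 0L) return(labels)
  rng <- range(s)
  if (rng[1] == rng[2]) {
    s[] <- 1
  } else {
    s <- (s - rng[1]) / (rng[2] - rng[1])
    if (any(s == 0 & labels@scores > 0))
      warning("min-max normalization set the minimum positive label score to 0",
              call. = FALSE)
  }
  new("LabelMap", scores = s)
}
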