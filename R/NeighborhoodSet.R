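#' Neighborhood table
#'
#' @param x a [NeighborhoodSet-class].
#' @return the underlying data.frame, one row per neighborhood, with
#'   list-columns \code{members} and \code{labeledMembers}.
#' @export
setGeneric("nhoodTable", function(x) standardGeneric("nhoodTable"))

#' @rdname nhoodTable
#' @export
setMethod("nhoodTable", "NeighborhoodSet", function(x) x@table)

#' Member lists of the neighborhoods
#'
#' @param x a [NeighborhoodSet-class].
#' @return list of character vectors, each with the seed first and the
#'   remaining members in descending similarity to the seed.
#' @export
setGeneric("nhoodMembers", function(x) standardGeneric("nhoodMembers"))

#' @rdname nhoodMembers
#' @export
setMethod("nhoodMembers", "NeighborhoodSet", function(x) x@table$members)

#' Seeds / scores of the neighborhoods
#'
#' @param x a [NeighborhoodSet-class].
#' @return character vector of seeds, or numeric vector of scores.
#' @export
setGeneric("nhoodSeeds", function(x) standardGeneric("nhoodSeeds"))

#' @rdname nhoodSeeds
#' @export
setMethod("nhoodSeeds", "NeighborhoodSet", function(x) x@table$seed)

#' @rdname nhoodSeeds
#' @export
setGeneric("nhoodScores", function(x) standardGeneric("nhoodScores"))

#' @rdname nhoodSeeds
#' @export
setMethod("nhoodScores", "NeighborhoodSet", function(x) x@table$score)

#' Whether a neighborhood set has been ranked and filtered
#'
#' @param x a [NeighborhoodSet-class].
#' @return logical.
#' @export
setGeneric("isRanked", function(x) standardGeneric("isRanked"))

#' @rdname isRanked
#' @export
setMethod("isRanked", "NeighborhoodSet", function(x) x@ranked)

#' Size-penalty exponent a result was computed with
#'
#' @param x a [NeighborhoodSet-class] or [LoocvSummary-class].
#' @return numeric alpha in [0, 1].
#' @export
setGeneric("alphaUsed", function(x) standardGeneric("alphaUsed"))

#' @rdname alphaUsed
#' @export
setMethod("alphaUsed", "NeighborhoodSet", function(x) x@alpha)

#' @describeIn nhoodTable number of neighborhoods in the set.
#' @export
setMethod("length", "NeighborhoodSet", function(x) nrow(x@table))

#' Flatten a NeighborhoodSet to a plain data.frame
#'
#' Members are comma-joined in order, with labeled members flagged by a
#' trailing \code{*} (the same encoding [writeNeighborhoodsTsv()] uses).
#'
#' @param x a [NeighborhoodSet-class].
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data.frame without list-columns.
#' @export
as.data.frame.NeighborhoodSet <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  tab <- x@table
  out <- tab[, setdiff(colnames(tab), c("members", "labeledMembers")),
             drop = FALSE]
  out$members <- mapply(function(m, l)
    paste0(m, ifelse(m %in% l, "*", ""), collapse = ","),
    tab$members, tab$labeledMembers)
  if (nrow(out) == 0L) out$members <- character(0)
  out
}

setMethod("show", "NeighborhoodSet", function(object) {
  cat(if (object@ranked) "Ranked" else "Candidate",
      "NeighborhoodSet with", nrow(object@table),
      paste0("neighborhoods (alpha = ", object@alpha, ")\n"))
  if (nrow(object@table) > 0) {
    df <- as.data.frame(object)
    df$members <- ifelse(nchar(df$members) > 48,
                         paste0(substr(df$members, 1, 45), "..."),
                         df$members)
    print(utils::head(df, 8), row.names = FALSE)
    if (nrow(df) > 8) cat("  ...", nrow(df) - 8, "more\n")
  }
})
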