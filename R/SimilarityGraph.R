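#' Construct a SimilarityGraph
#'
#' Builds a symmetric weighted entity graph from an edge table. Edges are
#' canonicalized to unordered pairs; reciprocal or duplicate rows are merged
#' by keeping the maximum similarity (logged via [message()]), and
#' self-edges are dropped with a warning. Non-finite or non-positive
#' similarities are rejected.
#'
#' @param edges data.frame whose first three columns are entity A, entity B
#'   and a positive similarity, or NULL for an edgeless graph.
#' @param entities optional character vector of additional (possibly
#'   isolated) entity identifiers; the entity set is the union of these and
#'   all edge endpoints.
#'
#' @return A [SimilarityGraph-class] object.
#' @examples
#' g <- SimilarityGraph(data.frame(a = c("P1", "P2"), b = c("P2", "P3"),
#'                                 sim = c(0.9, 0.4)))
#' numEntities(g)
#' @export
SimilarityGraph <- function(edges = NULL, entities = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- new("SimilarityGraph",
             entities = sort(unique(as.character(entities))),
             edges = data.frame(a = character(0), b = character(0),
                                sim = numeric(0), stringsAsFactors = FALSE))
    return(g)
  }
  if (ncol(edges) < 3L)
    hoodsArgumentError("'edges' must have at least three columns: entityA, entityB, similarity")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  sim <- as.numeric(edges[[3L]])
  if (any(!is.finite(sim)) || any(sim <= 0))
    hoodsArgumentError("all similarities must be finite and > 0")

  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped", call. = FALSE)
    a <- a[!self]; b <- b[!self]; sim <- sim[!self]
  }
  # canonical unordered pairs: a < b lexicographically (C collation)
  swap <- .cmpGt(a, b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  key <- paste0(a, "\r", b)
  if (anyDuplicated(key)) {
    message("merged ", length(key) - length(unique(key)),
            " duplicate/reciprocal edge(s) by maximum similarity")
    sim <- vapply(split(sim, key), max, numeric(1))
    ab <- strsplit(names(sim), "\r", fixed = TRUE)
    a <- vapply(ab, `[`, character(1), 1L)
    b <- vapply(ab, `[`, character(1), 2L)
    sim <- unname(sim)
  }
  ents <- sort(unique(c(a, b, as.character(entities))))
  o <- order(a, b, method = "radix")
  new("SimilarityGraph", entities = ents,
      edges = data.frame(a = unname(a[o]), b = unname(b[o]),
                         sim = unname(sim[o]), row.names = NULL,
                         stringsAsFactors = FALSE))
}

# locale-independent string comparison (C collation, like sort method="radix");
# x[i] == y[i] gives an arbitrary answer, which is harmless for swapping
.cmpGt <- function(x, y) {
  n <- length(x)
  o <- order(c(x, y), method = "radix")
  pos <- integer(2L * n)
  pos[o] <- seq_along(o)
  pos[seq_len(n)] > pos[n + seq_len(n)]
}

#' Entity identifiers of a graph
#'
#' @param x a [SimilarityGraph-class].
#' @return character vector of entity ids (sorted).
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname entityIds
#' @export
setMethod("entityIds", "SimilarityGraph", function(x) x@entities)

#' Edge table of a graph
#'
#' @param x a [SimilarityGraph-class].
#' @return data.frame with columns \code{a}, \code{b}, \code{sim}; one row
#'   per unordered entity pair, \code{a < b}.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "SimilarityGraph", function(x) x@edges)

#' Number of entities / edges
#'
#' @param x a [SimilarityGraph-class].
#' @return integer count.
#' @export
setGeneric("numEntities", function(x) standardGeneric("numEntities"))

#' @rdname numEntities
#' @export
setMethod("numEntities", "SimilarityGraph", function(x) length(x@entities))

#' @rdname numEntities
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname numEntities
#' @export
setMethod("numEdges", "SimilarityGraph", function(x) nrow(x@edges))

#' Sparse symmetric similarity matrix
#'
#' @param x a [SimilarityGraph-class].
#' @return a symmetric sparse \linkS4class{Matrix} with entity ids as
#'   dimnames and zeros for absent pairs.
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "SimilarityGraph", function(x) {
  ents <- x@entities
  e <- x@edges
  i <- match(e$a, ents)
  j <- match(e$b, ents)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(e$sim, e$sim),
                       dims = c(length(ents), length(ents)),
                       dimnames = list(ents, ents))
})

setMethod("show", "SimilarityGraph", function(object) {
  cat("SimilarityGraph with", length(object@entities), "entities and",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges) > 0)
    cat("  similarity range: [",
        format(min(object@edges$sim), digits = 4), ", ",
        format(max(object@edges$sim), digits = 4), "]\n", sep = "")
})

# adjacency list: for each entity, a list(neighbor=, sim=) with neighbors
# sorted by descending similarity, ties broken lexicographically
.adjacencyList <- function(graph) {
  ents <- graph@entities
  e <- graph@edges
  from <- c(e$a, e$b)
  to <- c(e$b, e$a)
  sim <- c(e$sim, e$sim)
  adj <- vector("list", length(ents))
  names(adj) <- ents
  idx <- split(seq_along(from), factor(from, levels = ents))
  for (k in seq_along(ents)) {
    ii <- idx[[k]]
    nb <- to[ii]
    ss <- sim[ii]
    o <- order(-ss, nb, method = "radix")
    adj[[k]] <- list(neighbor = nb[o], sim = ss[o])
  }
  adj
}
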