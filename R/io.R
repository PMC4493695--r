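#' Read a similarity matrix from a TSV edge list
#'
#' Expects at least three columns per data row: entity A, entity B,
#' similarity. A header row is auto-detected: if the third field of the
#' first row does not parse as a number, that row is skipped. Duplicate and
#' reciprocal edges are merged by maximum similarity, self-edges are dropped
#' with a warning, and blank lines are ignored.
#'
#' @param path path to the file.
#' @param delimiter field delimiter; tab by default.
#' @return A [SimilarityGraph-class].
#' @seealso [writeNeighborhoodsTsv()], [readLabelsTsv()]
#' @export
readSimilarityTsv <- function(path, delimiter = "\t") {
  rows <- .readDelimRows(path, delimiter)
  if (length(rows$fields) == 0L)
    hoodsFormatError(paste0(path, ": no data rows"))
  first <- rows$fields[[1L]]
  start <- 1L
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L]))))
    start <- 2L   # header
  if (start > length(rows$fields))
    hoodsFormatError(paste0(path, ": no data rows"))
  idx <- start:length(rows$fields)
  nf <- lengths(rows$fields[idx])
  if (any(nf < 3L))
    hoodsFormatError(paste0(path, ": line ", rows$lines[idx][which(nf < 3L)[1L]],
                            ": expected at least 3 fields"))
  a <- vapply(rows$fields[idx], `[`, character(1), 1L)
  b <- vapply(rows$fields[idx], `[`, character(1), 2L)
  sim <- suppressWarnings(as.numeric(vapply(rows$fields[idx], `[`,
                                            character(1), 3L)))
  bad <- !is.finite(sim) | sim <= 0
  if (any(bad))
    hoodsFormatError(paste0(path, ": line ", rows$lines[idx][which(bad)[1L]],
                            ": similarity must be a finite positive number"))
  SimilarityGraph(data.frame(a = a, b = b, sim = sim,
                             stringsAsFactors = FALSE))
}

#' Read context label scores from a TSV file
#'
#' One or two columns: entity id and an optional score. One-column rows get
#' score 1 (binary labels). A header row is auto-detected on the first row
#' when its second field does not parse as a number. Duplicate entities keep
#' the maximum score; negative scores are clamped to 0 with a warning.
#'
#' @inheritParams readSimilarityTsv
#' @return A [LabelMap-class].
#' @export
readLabelsTsv <- function(path, delimiter = "\t") {
  rows <- .readDelimRows(path, delimiter)
  if (length(rows$fields) == 0L)
    hoodsFormatError(paste0(path, ": no data rows"))
  first <- rows$fields[[1L]]
  start <- 1L
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L]))))
    start <- 2L
  if (start > length(rows$fields))
    hoodsFormatError(paste0(path, ": no data rows"))
  idx <- start:length(rows$fields)
  ent <- vapply(rows$fields[idx], `[`, character(1), 1L)
  rawScore <- vapply(rows$fields[idx], function(f)
    if (length(f) >= 2L) f[2L] else NA_character_, character(1))
  score <- suppressWarnings(as.numeric(rawScore))
  score[is.na(rawScore)] <- 1
  bad <- !is.finite(score)
  if (any(bad))
    hoodsFormatError(paste0(path, ": line ", rows$lines[idx][which(bad)[1L]],
                            ": score must be a finite number"))
  LabelMap(setNames(score, ent))
}

# split a delimited file into fields, skipping blank lines but remembering
# original line numbers for error messages
.readDelimRows <- function(path, delimiter) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    hoodsFormatError(paste0("cannot read file: ", path))
  txt <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(txt))
  list(fields = strsplit(txt[keep], delimiter, fixed = TRUE),
       lines = which(keep))
}

#' Write ranked neighborhoods to a TSV file
#'
#' One row per kept neighborhood with its rank, seed, score (6 significant
#' digits), size, label sum, novelty bookkeeping, and the comma-joined
#' member list in similarity order, labeled members flagged with a trailing
#' \code{*}. Output is byte-deterministic for a given input.
#'
#' @param ranked a ranked [NeighborhoodSet-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeNeighborhoodsTsv <- function(ranked, path) {
  if (!is(ranked, "NeighborhoodSet") || !isTRUE(ranked@ranked))
    hoodsArgumentError("'ranked' must be a ranked NeighborhoodSet")
  tab <- ranked@table
  header <- paste("rank", "seed", "score", "size", "label_sum",
                  "new_labeled", "new_entities", "total_entities_used",
                  "members", sep = "\t")
  rows <- character(0)
  if (nrow(tab) > 0) {
    members <- mapply(function(m, l)
      paste0(m, ifelse(m %in% l, "*", ""), collapse = ","),
      tab$members, tab$labeledMembers)
    rows <- paste(tab$rank, tab$seed,
                  formatC(tab$score, digits = 6, format = "g"),
                  tab$size,
                  formatC(tab$labelSum, digits = 10, format = "g"),
                  tab$newLabeled, tab$newEntities, tab$cumulativeEntities,
                  members, sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a neighborhoods TSV written by [writeNeighborhoodsTsv()]
#'
#' @param path path to the file.
#' @param delimiter field delimiter; tab by default.
#' @return data.frame with the tabular columns plus list-columns
#'   \code{members} and \code{labeledMembers} decoded from the \code{*}
#'   flags.
#' @export
readNeighborhoodsTsv <- function(path, delimiter = "\t") {
  rows <- .readDelimRows(path, delimiter)
  if (length(rows$fields) == 0L)
    hoodsFormatError(paste0(path, ": no header row"))
  dat <- rows$fields[-1L]
  grab <- function(k) vapply(dat, `[`, character(1), k)
  if (length(dat) == 0L) {
    out <- data.frame(rank = integer(0), seed = character(0),
                      score = numeric(0), size = integer(0),
                      labelSum = numeric(0), newLabeled = integer(0),
                      newEntities = integer(0),
                      cumulativeEntities = integer(0),
                      stringsAsFactors = FALSE)
    out$members <- list()
    out$labeledMembers <- list()
    return(out)
  }
  memb <- strsplit(grab(9L), ",", fixed = TRUE)
  starred <- lapply(memb, function(m) endsWith(m, "*"))
  clean <- mapply(function(m, st) sub("\\*$", "", m), memb, starred,
                  SIMPLIFY = FALSE)
  out <- data.frame(rank = as.integer(grab(1L)), seed = grab(2L),
                    score = as.numeric(grab(3L)),
                    size = as.integer(grab(4L)),
                    labelSum = as.numeric(grab(5L)),
                    newLabeled = as.integer(grab(6L)),
                    newEntities = as.integer(grab(7L)),
                    cumulativeEntities = as.integer(grab(8L)),
                    stringsAsFactors = FALSE)
  out$members <- clean
  out$labeledMembers <- mapply(function(m, st) m[st], clean, starred,
                               SIMPLIFY = FALSE)
  out
}

#' Write a LOOCV summary to TSV
#'
#' @param x a [LoocvSummary-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeLoocvTsv <- function(x, path) {
  if (!is(x, "LoocvSummary"))
    hoodsArgumentError("'x' must be a LoocvSummary")
  s <- x@summary
  header <- paste("alpha", "threshold", "recovered", "total",
                  "ci_low", "ci_high", sep = "\t")
  rows <- paste(s$alpha, s$threshold, s$recovered, s$total,
                formatC(s$ciLow, digits = 6, format = "g"),
                formatC(s$ciHigh, digits = 6, format = "g"), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a similarity graph / label map in the package's TSV dialects
#'
#' @param graph a [SimilarityGraph-class].
#' @param labels a [LabelMap-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSimilarityTsv <- function(graph, path) {
  if (!is(graph, "SimilarityGraph"))
    hoodsArgumentError("'graph' must be a SimilarityGraph")
  e <- graph@edges
  # 17 significant digits: doubles survive a write/read round trip exactly
  rows <- paste(e$a, e$b, formatC(e$sim, digits = 17, format = "g"),
                sep = "\t")
  writeLines(c("entityA\tentityB\tsimilarity", rows), path)
  invisible(path)
}

#' @rdname writeSimilarityTsv
#' @export
writeLabelsTsv <- function(labels, path) {
  if (!is(labels, "LabelMap"))
    hoodsArgumentError("'labels' must be a LabelMap")
  s <- labels@scores
  rows <- paste(names(s), formatC(s, digits = 17, format = "g"), sep = "\t")
  writeLines(c("entity\tscore", rows), path)
  invisible(path)
}
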