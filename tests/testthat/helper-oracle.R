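# Independent brute-force reference implementation, written against the
# algorithm description only: enumerate every (seed, prefix) pair from a raw
# edge list, score each prefix, and apply the ranking and redundancy filters
# literally with plain loops. Shares no code with the package internals.
#
# edges: data.frame(a, b, sim) - undirected, one row per pair
# scores: named numeric vector; absent entities score 0
# returns a list of kept neighborhoods in rank order

oracle_hoods <- function(entities, edges, scores, alpha, maxSize = Inf) {
  s_of <- function(e) {
    v <- scores[e]
    v[is.na(v)] <- 0
    unname(v)
  }
  candidates <- list()
  for (seed in sort(entities, method = "radix")) {
    hit_a <- edges$a == seed
    hit_b <- edges$b == seed
    nb <- c(edges$b[hit_a], edges$a[hit_b])
    sim <- c(edges$sim[hit_a], edges$sim[hit_b])
    if (length(nb) > 0) {
      o <- order(-sim, nb, method = "radix")
      nb <- nb[o]
    }
    members_full <- c(seed, nb)
    if (length(members_full) > maxSize)
      members_full <- members_full[seq_len(maxSize)]
    for (j in seq_along(members_full)) {
      prefix <- members_full[seq_len(j)]
      labeled <- prefix[s_of(prefix) > 0]
      ends_labeled <- s_of(members_full[j]) > 0
      if (ends_labeled && length(labeled) >= 2) {
        labelSum <- sum(s_of(prefix))
        candidates[[length(candidates) + 1L]] <- list(
          seed = seed, members = prefix, labeled = labeled,
          size = j, labelSum = labelSum, score = labelSum / j^alpha)
      }
    }
  }
  if (length(candidates) == 0L) return(list())
  score <- vapply(candidates, `[[`, numeric(1), "score")
  labelSum <- vapply(candidates, `[[`, numeric(1), "labelSum")
  size <- vapply(candidates, `[[`, numeric(1), "size")
  seed <- vapply(candidates, `[[`, character(1), "seed")
  mkey <- vapply(candidates, function(c) paste(c$members, collapse = ","),
                 character(1))
  candidates <- candidates[order(-score, -labelSum, size, seed, mkey,
                                 method = "radix")]
  kept <- list()
  seenLabeled <- character(0)
  seenAll <- character(0)
  for (cand in candidates) {
    newLab <- cand$labeled[!(cand$labeled %in% seenLabeled)]
    newEnt <- cand$members[!(cand$members %in% seenAll)]
    if (length(newLab) >= 1 && length(newEnt) >= 1) {
      cand$newLabeled <- length(newLab)
      cand$newEntities <- length(newEnt)
      seenLabeled <- c(seenLabeled, newLab)
      seenAll <- c(seenAll, newEnt)
      cand$cumulativeEntities <- length(seenAll)
      kept[[length(kept) + 1L]] <- cand
    }
  }
  kept
}

# compare a package result against the oracle's kept list
expect_matches_oracle <- function(ranked, kept) {
  tab <- nhoodTable(ranked)
  expect_equal(nrow(tab), length(kept))
  for (i in seq_along(kept)) {
    expect_identical(tab$seed[i], kept[[i]]$seed)
    expect_identical(tab$members[[i]], kept[[i]]$members)
    expect_identical(sort(tab$labeledMembers[[i]]), sort(kept[[i]]$labeled))
    expect_equal(tab$score[i], kept[[i]]$score, tolerance = 1e-12)
    expect_equal(tab$labelSum[i], kept[[i]]$labelSum, tolerance = 1e-12)
    expect_equal(tab$newLabeled[i], kept[[i]]$newLabeled)
    expect_equal(tab$newEntities[i], kept[[i]]$newEntities)
    expect_equal(tab$cumulativeEntities[i], kept[[i]]$cumulativeEntities)
  }
  invisible(TRUE)
}
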