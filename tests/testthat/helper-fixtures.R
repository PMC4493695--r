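# Programmatic fixtures shared across test files.

# a star graph: unlabeled-or-labeled center with named spokes
star_graph <- function(center, spokes, sims) {
  SimilarityGraph(data.frame(a = rep(center, length(spokes)), b = spokes,
                             sim = sims, stringsAsFactors = FALSE))
}

# random small instance for property tests: n entities, Erdos-Renyi edges
# with uniform similarities, a random subset labeled (binary or weighted)
random_instance <- function(n = sample(4:12, 1), p = runif(1, 0.25, 0.7),
                            labeledFrac = runif(1, 0.2, 0.9),
                            weighted = sample(c(TRUE, FALSE), 1)) {
  ents <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  edges <- data.frame(a = ents[pairs[1, keep]], b = ents[pairs[2, keep]],
                      sim = runif(sum(keep), 0.05, 1),
                      stringsAsFactors = FALSE)
  nLab <- max(0L, round(labeledFrac * n))
  lab <- sample(ents, nLab)
  scores <- setNames(if (weighted) runif(nLab, 0.2, 3) else rep(1, nLab), lab)
  list(entities = ents, edges = edges, scores = scores,
       graph = SimilarityGraph(edges, entities = ents),
       labels = LabelMap(scores))
}

# the frozen planted-neighborhood fixture used throughout the evaluation
frozen_fixture <- function(rngSeed = 42) {
  generatePlantedNetwork(n = 60, kCliques = 3, cliqueSize = 8,
                         labelFraction = 0.75, backgroundDensity = 0.05,
                         rngSeed = rngSeed)
}

# per-clique label sets and ownership map for the random-label control
clique_label_sets <- function(truth) {
  cl <- plantedCliques(truth)
  lab <- plantedLabeled(truth)
  sets <- lapply(cl, function(x) LabelMap(intersect(lab, x)))
  names(sets) <- paste0("clique", seq_along(cl))
  own <- setNames(rep(names(sets), vapply(cl, function(x)
    length(intersect(lab, x)), integer(1))),
    unlist(lapply(cl, function(x) intersect(lab, x))))
  list(sets = sets, own = own)
}
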