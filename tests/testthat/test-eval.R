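# Leave-one-out cross-validation, random-label control, alpha sweep.

test_that("a left-out entity found in the top neighborhood gets its size as rank", {
  # center X unlabeled; spokes A, L, B, C labeled in descending similarity.
  # Holding out L leaves the single kept neighborhood [X, A, L, B, C]
  # (label sum 3, size 5 outscores the size-4 prefix), so rank = 5.
  g <- star_graph("X", c("A", "L", "B", "C"), c(0.9, 0.8, 0.7, 0.6))
  l <- LabelMap(c(A = 1, L = 1, B = 1, C = 1))
  r <- loocvRank(g, l, "L")
  expect_true(r$found)
  expect_identical(r$rank, 5L)
})

test_that("rank accumulates the union over earlier kept neighborhoods", {
  # with similarities .9 .8 .7 .6 for A, B, L, C the compact prefix
  # [X, A, B] outscores [X, A, B, L, C]; the latter is kept second (new
  # labeled C), so L's rank is the union size 5 with 3 shared members
  g <- star_graph("X", c("A", "B", "L", "C"), c(0.9, 0.8, 0.7, 0.6))
  l <- LabelMap(c(A = 1, B = 1, L = 1, C = 1))
  r <- loocvRank(g, l, "L")
  expect_true(r$found)
  expect_identical(r$rank, 5L)
  held <- runHoods(g, LabelMap(c(A = 1, B = 1, C = 1)))
  expect_identical(length(held), 2L)
  expect_identical(nhoodTable(held)$members[[1]], c("X", "A", "B"))
})

test_that("entities absent from the graph or unlabeled are handled", {
  g <- star_graph("X", c("A", "B"), c(0.9, 0.8))
  l <- LabelMap(c(A = 1, B = 1, Z = 1))
  r <- suppressWarnings(loocvRank(g, l, "Z"))
  expect_false(r$found)
  expect_true(is.na(r$rank))
  expect_error(loocvRank(g, l, "X"), class = "hoods_argument_error")
})

test_that("holding out a label equals running with that label omitted", {
  set.seed(51)
  for (i in 1:10) {
    inst <- random_instance(n = 10)
    lab <- names(inst$scores)[inst$scores > 0]
    lab <- intersect(lab, inst$entities)
    if (length(lab) == 0) next
    e <- sample(lab, 1)
    r <- suppressWarnings(loocvRank(inst$graph, inst$labels, e))
    omitted <- LabelMap(inst$scores[setdiff(names(inst$scores), e)])
    ranked <- suppressWarnings(runHoods(inst$graph, omitted))
    # recompute the rank by hand on the from-scratch run
    seen <- character(0); expected <- list(rank = NA_integer_, found = FALSE)
    for (m in nhoodMembers(ranked)) {
      seen <- union(seen, m)
      if (e %in% m) { expected <- list(rank = length(seen), found = TRUE); break }
    }
    expect_identical(r$rank, expected$rank)
    expect_identical(r$found, expected$found)
  }
})

test_that("summary counts are monotone in threshold and bounded by the total", {
  fx <- frozen_fixture()
  bench <- plantedLabeled(fx$truth)
  s <- runLoocv(fx$graph, fx$labels, bench, thresholds = c(5, 10, 25, 60))
  st <- loocvSummaryTable(s)
  expect_true(!is.unsorted(st$recovered[order(st$threshold)]))
  expect_true(all(st$recovered <= st$total))
  expect_true(all(st$ciLow <= st$recovered / st$total &
                  st$recovered / st$total <= st$ciHigh))
  expect_error(runLoocv(fx$graph, fx$labels, character(0)),
               class = "hoods_argument_error")
  expect_error(runLoocv(fx$graph, fx$labels, "E999"),
               class = "hoods_argument_error")
})

test_that("single-entity benchmarks count once at every threshold they clear", {
  g <- star_graph("X", c("A", "L", "B", "C"), c(0.9, 0.8, 0.7, 0.6))
  l <- LabelMap(c(A = 1, L = 1, B = 1, C = 1))
  s <- runLoocv(g, l, "L", thresholds = c(3, 25, 50, 100))
  st <- loocvSummaryTable(s)
  expect_identical(st$recovered, c(0L, 1L, 1L, 1L))   # rank 5 misses t = 3
})

test_that("the random-label control recovers nothing when labels are off-target", {
  fx <- frozen_fixture()
  cls <- clique_label_sets(fx$truth)
  bench <- plantedLabeled(fx$truth)
  ctrl <- suppressMessages(randomLabelControl(
    fx$graph, cls$sets, bench, rngSeed = 7, benchmarkSets = cls$own))
  st <- loocvSummaryTable(ctrl)
  inf <- loocvSummaryTable(runLoocv(fx$graph, fx$labels, bench))
  expect_lte(max(st$recovered), min(inf$recovered))
})

test_that("a single admissible alternative makes the control deterministic", {
  fx <- generatePlantedNetwork(n = 30, kCliques = 2, cliqueSize = 6,
                               labelFraction = 1, backgroundDensity = 0.05,
                               rngSeed = 9)
  cls <- clique_label_sets(fx$truth)
  bench <- plantedLabeled(fx$truth)
  r1 <- suppressMessages(randomLabelControl(fx$graph, cls$sets, bench,
                                            rngSeed = 1,
                                            benchmarkSets = cls$own))
  r2 <- suppressMessages(randomLabelControl(fx$graph, cls$sets, bench,
                                            rngSeed = 999,
                                            benchmarkSets = cls$own))
  expect_identical(loocvRanks(r1), loocvRanks(r2))
})

test_that("the exclusion rule can make a control infeasible", {
  fx <- generatePlantedNetwork(n = 30, kCliques = 2, cliqueSize = 6,
                               labelFraction = 1, backgroundDensity = 0,
                               rngSeed = 9)
  cls <- clique_label_sets(fx$truth)
  cats <- setNames(rep("sameSystem", length(cls$sets)), names(cls$sets))
  err <- tryCatch(
    suppressMessages(randomLabelControl(
      fx$graph, cls$sets, plantedLabeled(fx$truth), rngSeed = 1,
      benchmarkSets = cls$own, categories = cats)),
    hoods_argument_error = identity)
  expect_s3_class(err, "hoods_argument_error")
  expect_match(conditionMessage(err), "E0")
})

test_that("alpha sweep matches individual runs and spans the alpha range", {
  fx <- generatePlantedNetwork(n = 30, kCliques = 2, cliqueSize = 6,
                               labelFraction = 0.8, backgroundDensity = 0.05,
                               rngSeed = 13)
  bench <- plantedLabeled(fx$truth)
  sw <- alphaSweep(fx$graph, fx$labels, bench, alphas = c(0, 0.8, 1),
                   thresholds = c(25, 100))
  expect_identical(names(sw), c("0", "0.8", "1"))
  solo <- runLoocv(fx$graph, fx$labels, bench, alpha = 0.8,
                   thresholds = c(25, 100))
  expect_identical(loocvSummaryTable(sw[["0.8"]]), loocvSummaryTable(solo))
  expect_error(alphaSweep(fx$graph, fx$labels, bench, alphas = numeric(0)),
               class = "hoods_argument_error")
  expect_error(alphaSweep(fx$graph, fx$labels, bench, alphas = c(0.5, 2)),
               class = "hoods_argument_error")
})

test_that("size penalty protects small-threshold recovery from diffuse hub neighborhoods", {
  # a 60-spoke hub with 12 scattered labeled spokes forms a big diffuse
  # neighborhood with the highest total label score; without a size penalty
  # (alpha = 0) it tops the ranking and its 61 members are consumed before
  # the compact labeled star, pushing every rank past 25
  nF <- 60
  spokes <- sprintf("F%02d", seq_len(nF))
  hub <- data.frame(a = "H", b = spokes,
                    sim = 0.88 - 0.006 * (seq_len(nF) - 1))
  starY <- data.frame(a = "Y", b = c("P1", "P2", "P3"),
                      sim = c(0.9, 0.8, 0.7))
  g <- SimilarityGraph(rbind(hub, starY))
  l <- LabelMap(c(setNames(rep(1, 12), spokes[seq(5, nF, by = 5)]),
                  P1 = 1, P2 = 1, P3 = 1))
  sw <- alphaSweep(g, l, c("P1", "P2"), alphas = c(0, 0.8), thresholds = 25)
  rec <- vapply(sw, function(s) loocvSummaryTable(s)$recovered[1], integer(1))
  expect_gte(rec[["0.8"]], rec[["0"]])
  expect_identical(rec[["0.8"]], 2L)
  expect_identical(rec[["0"]], 0L)
})
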