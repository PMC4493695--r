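# Planted-neighborhood generator and recovery metric.

test_that("the generator is reproducible from its seed", {
  f1 <- generatePlantedNetwork(rngSeed = 17)
  f2 <- generatePlantedNetwork(rngSeed = 17)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  f3 <- generatePlantedNetwork(rngSeed = 18)
  expect_false(identical(edgeTable(f1$graph), edgeTable(f3$graph)))
})

test_that("infeasible parameters are rejected", {
  expect_error(generatePlantedNetwork(n = 10, kCliques = 3, cliqueSize = 4),
               class = "hoods_argument_error")
  expect_error(generatePlantedNetwork(labelFraction = 0),
               class = "hoods_argument_error")
  expect_error(generatePlantedNetwork(backgroundDensity = 1.2),
               class = "hoods_argument_error")
  expect_error(generatePlantedNetwork(simHigh = c(0.2, 0.5),
                                      simBackground = c(0.4, 0.6)),
               class = "hoods_argument_error")
})

test_that("a noiseless fully-labeled clique is recovered exactly", {
  fx <- generatePlantedNetwork(n = 20, kCliques = 1, cliqueSize = 6,
                               labelFraction = 1, backgroundDensity = 0,
                               rngSeed = 23)
  ranked <- runHoods(fx$graph, fx$labels)
  expect_identical(length(ranked), 1L)
  expect_setequal(nhoodMembers(ranked)[[1]], plantedCliques(fx$truth)[[1]])
  expect_identical(recoveryMetric(ranked, fx$truth), 1)
})

test_that("cliques with fewer than two labeled members produce no neighborhoods", {
  fx <- generatePlantedNetwork(n = 30, kCliques = 3, cliqueSize = 8,
                               labelFraction = 0.1, backgroundDensity = 0,
                               rngSeed = 23)   # ceil(0.1 * 8) = 1 label each
  expect_identical(length(runHoods(fx$graph, fx$labels)), 0L)
})

test_that("three noiseless cliques surface as the top three neighborhoods", {
  fx <- generatePlantedNetwork(n = 40, kCliques = 3, cliqueSize = 6,
                               labelFraction = 1, backgroundDensity = 0,
                               rngSeed = 29)
  ranked <- runHoods(fx$graph, fx$labels)
  top3 <- nhoodMembers(ranked)[1:3]
  cliques <- plantedCliques(fx$truth)
  for (cl in cliques)
    expect_true(any(vapply(top3, setequal, logical(1), y = cl)))
  expect_identical(recoveryMetric(ranked, fx$truth), 1)
})

test_that("weighted label mode draws scores in [0.5, 1.5]", {
  fx <- generatePlantedNetwork(weightedLabels = TRUE, rngSeed = 31)
  s <- labelScores(fx$labels)
  expect_true(all(s >= 0.5 & s <= 1.5))
  expect_gt(stats::sd(s), 0)
})

test_that("recovery metric averages the best Jaccard per clique", {
  # a graph holding only the first of two planted cliques: the first is
  # recovered exactly, the second not at all -> mean (1 + 0) / 2
  c1 <- sprintf("A%02d", 1:4); c2 <- sprintf("B%02d", 1:4)
  pairs <- utils::combn(c1, 2)
  g <- SimilarityGraph(data.frame(a = pairs[1, ], b = pairs[2, ], sim = 0.9))
  ranked <- runHoods(g, LabelMap(c1))
  truth <- new("PlantedTruth", cliques = list(c1, c2), labeled = c(c1, c2),
               background = character(0),
               params = list(simHigh = c(0.7, 0.95),
                             simBackground = c(0.05, 0.4)))
  expect_identical(recoveryMetric(ranked, truth), 0.5)
  # empty ranked set scores 0; a truth without cliques is an error
  empty <- rankAndFilter(buildAllCandidates(g, LabelMap()))
  expect_identical(recoveryMetric(empty, truth), 0)
  expect_error(recoveryMetric(ranked,
                              new("PlantedTruth", cliques = list(),
                                  labeled = character(0),
                                  background = character(0), params = list())),
               class = "hoods_argument_error")
})

test_that("recovery metric is invariant under consistent relabeling", {
  fx <- generatePlantedNetwork(n = 30, kCliques = 2, cliqueSize = 6,
                               labelFraction = 0.8, backgroundDensity = 0.05,
                               rngSeed = 37)
  ranked <- runHoods(fx$graph, fx$labels)
  m0 <- recoveryMetric(ranked, fx$truth)
  rename <- function(x) paste0("Z_", rev(x))  # injective id mapping
  renameVec <- function(v) unname(setNames(rename(entityIds(fx$graph)),
                                           entityIds(fx$graph))[v])
  tab <- nhoodTable(ranked)
  tab$seed <- renameVec(tab$seed)
  tab$members <- lapply(tab$members, renameVec)
  tab$labeledMembers <- lapply(tab$labeledMembers, renameVec)
  ranked2 <- new("NeighborhoodSet", table = tab, alpha = alphaUsed(ranked),
                 ranked = TRUE)
  truth2 <- new("PlantedTruth",
                cliques = lapply(plantedCliques(fx$truth), renameVec),
                labeled = renameVec(plantedLabeled(fx$truth)),
                background = renameVec(fx$truth@background),
                params = truthParams(fx$truth))
  expect_identical(recoveryMetric(ranked2, truth2), m0)
})

test_that("fixtures round-trip through the TSV dialects", {
  fx <- generatePlantedNetwork(n = 30, kCliques = 2, cliqueSize = 6,
                               labelFraction = 0.8, backgroundDensity = 0.1,
                               rngSeed = 41)
  prefix <- file.path(withr::local_tempdir(), "fix_")
  paths <- writePlantedFixture(fx, prefix)
  expect_true(all(file.exists(paths)))
  g <- readSimilarityTsv(paths[1])
  l <- readLabelsTsv(paths[2])
  expect_identical(edgeTable(g), edgeTable(fx$graph))
  expect_equal(labelScores(l), labelScores(fx$labels))
  truth <- read.delim(paths[3])
  expect_identical(sort(truth$entity[truth$clique == 1]),
                   plantedCliques(fx$truth)[[1]])
})
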