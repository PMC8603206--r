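# Network reconstruction, node metrics and drug prioritization.

mkRecords <- function(a, b, ev, orgB = NULL) {
  data.frame(a = a, b = b, organism_a = "9606",
             organism_b = if (is.null(orgB)) "9606" else orgB,
             evidence_count = ev, stringsAsFactors = FALSE)
}

test_that("buildNetwork applies the full filter cascade", {
  rec <- rbind(
    mkRecords("A", "B", 2),             # kept
    mkRecords("A", "C", 1),             # evidence < 2
    mkRecords("A", "A", 3),             # self loop
    mkRecords("A", "D", 2, orgB = "10090"))  # non-human
  net <- buildNetwork(rec, seeds = c("A", "B", "C", "D"))
  expect_identical(sort(nodeTable(net)$node), c("A", "B"))
  expect_identical(igraph::ecount(networkGraph(net)), 1)
  # duplicate A-B / B-A collapses to one edge
  rec2 <- rbind(mkRecords("A", "B", 2), mkRecords("B", "A", 3))
  net2 <- buildNetwork(rec2, seeds = c("A", "B"))
  expect_identical(igraph::ecount(networkGraph(net2)), 1)
  # records between non-seeds are excluded in seeded mode
  rec3 <- rbind(mkRecords("A", "B", 2), mkRecords("X", "Y", 5))
  net3 <- buildNetwork(rec3, seeds = c("A", "B"))
  expect_false("X" %in% nodeTable(net3)$node)
  # empty post-filter graph is an explicit empty result
  net4 <- buildNetwork(mkRecords("A", "B", 1), seeds = c("A", "B"))
  expect_identical(igraph::vcount(networkGraph(net4)), 0)
})

test_that("focus mode keeps the focus protein and its direct interactors", {
  rec <- rbind(mkRecords("F", "A", 2), mkRecords("F", "B", 2),
               mkRecords("A", "B", 2), mkRecords("B", "C", 2))
  net <- buildNetwork(rec, mode = "focus", focus = "F")
  expect_setequal(nodeTable(net)$node, c("F", "A", "B"))
  expect_identical(igraph::ecount(networkGraph(net)), 3)  # F-A, F-B, A-B
})

test_that("betweenness and degree match hand enumeration on canonical graphs", {
  # path A-B-C: B sits on the single shortest A..C path
  path <- buildNetwork(rbind(mkRecords("A", "B", 2), mkRecords("B", "C", 2)),
                       seeds = c("A", "B", "C"))
  nt <- nodeTable(path)
  expect_equal(nt$betweenness[nt$node == "B"], 1)
  expect_equal(nt$betweenness[nt$node != "B"], c(0, 0))
  # triangle: no intermediate vertices anywhere
  tri <- buildNetwork(rbind(mkRecords("A", "B", 2), mkRecords("B", "C", 2),
                            mkRecords("A", "C", 2)),
                      seeds = c("A", "B", "C"))
  expect_equal(nodeTable(tri)$betweenness, c(0, 0, 0))
  # star: center is the top-1 node by degree
  star <- buildNetwork(rbind(mkRecords("X", "L1", 2), mkRecords("X", "L2", 2),
                             mkRecords("X", "L3", 2)),
                       seeds = c("X", "L1", "L2", "L3"))
  top <- rankNodes(star, 1)
  expect_identical(top$node, "X")
  expect_equal(top$degree, 3)
  expect_error(rankNodes(star, 0), "positive")
})

test_that("betweenness agrees with brute-force path enumeration on random graphs", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    nodes <- LETTERS[1:n]
    pairs <- t(combn(nodes, 2))
    pick <- runif(nrow(pairs)) < 0.5
    if (sum(pick) < n - 1) next
    rec <- mkRecords(pairs[pick, 1], pairs[pick, 2], 2)
    net <- buildNetwork(rec, seeds = nodes)
    nt <- nodeTable(net)
    if (!nrow(nt)) next
    edges <- igraph::as_data_frame(networkGraph(net), what = "edges")
    oracle <- betweennessOracle(as.matrix(edges[, 1:2]), nt$node)
    expect_equal(setNames(nt$betweenness, nt$node), oracle[nt$node],
                 tolerance = 1e-9)
  }
})

test_that("filter cascade is order independent and degree sum is twice edges", {
  spec <- fixtureSpec(nNodes = 20L, edgeProb = 0.3)
  qn <- makeQuantNetwork(spec, seed = 17)
  net <- buildNetwork(qn$interactions, seeds = qn$seeds)
  # independent expectation computed by the generator with table arithmetic
  expect_equal(igraph::ecount(networkGraph(net)), nrow(qn$expectedEdges))
  deg <- setNames(nodeTable(net)$degree, nodeTable(net)$node)
  expect_equal(deg[names(qn$expectedDegrees)], qn$expectedDegrees,
               ignore_attr = FALSE, tolerance = 0)
  expect_equal(sum(deg), 2 * igraph::ecount(networkGraph(net)))
  # shuffling the record order changes nothing (betweenness up to float
  # summation order)
  shuffled <- qn$interactions[sample(nrow(qn$interactions)), ]
  net2 <- buildNetwork(shuffled, seeds = qn$seeds)
  r1 <- rankNodes(net, 100)
  r2 <- rankNodes(net2, 100)
  expect_identical(r1$node, r2$node)
  expect_identical(r1$degree, r2$degree)
  expect_equal(r1$betweenness, r2$betweenness, tolerance = 1e-10)
})

test_that("drug specificity and priority follow their definitions", {
  rec <- rbind(mkRecords("A", "B", 2), mkRecords("A", "C", 2),
               mkRecords("A", "D", 2), mkRecords("B", "C", 2))
  net <- buildNetwork(rec, seeds = c("A", "B", "C", "D"))
  # drug with 4 reported targets, 2 in the network
  r <- computeDrugSpecificity("d1", c("A", "B", "Z1", "Z2"), net)
  expect_equal(r$specificity, 0.5)
  # priority = sum of in-network target degrees (A:3 + B:2)
  expect_equal(r$priorityScore, 5)
  # all targets in network
  expect_equal(computeDrugSpecificity("d2", c("C", "D"), net)$specificity, 1.0)
  # no in-network target, or non-human: excluded
  expect_null(computeDrugSpecificity("d3", "Z9", net))
  expect_null(computeDrugSpecificity("d4", "A", net, human = FALSE))

  drugs <- data.frame(
    drug = c("x", "x", "y", "n"),
    target = c("A", "B", "D", "A"),
    organism = c("9606", "9606", "9606", "10090"))
  rank <- prioritizeDrugs(drugs, net)
  expect_identical(rank$drug, c("x", "y"))   # scores 5 then 1; n is non-human
  expect_equal(rank$priority_score, c(5, 1))
})

test_that("annotateNodes joins effects, quant directions and impact sizes", {
  rec <- rbind(mkRecords("A", "B", 2), mkRecords("B", "C", 2))
  net <- buildNetwork(rec, seeds = c("A", "B", "C"))
  net <- annotateNodes(
    net,
    impact = data.frame(gene_id = "B", scaled_score = 0.5),
    quant = data.frame(gene = "A", direction = "up_in_R", layer = "proteome"),
    variantEffects = data.frame(gene = "B", effect = "gain_of_function"),
    drugs = data.frame(drug = "d", target = "C", organism = "9606"))
  nt <- nodeTable(net)
  row <- function(n) nt[nt$node == n, ]
  expect_identical(row("B")$variant_effect, "gain_of_function")
  expect_equal(row("B")$impact_size, 0.5)
  expect_identical(row("A")$significance_direction, "up_in_R")
  expect_identical(row("C")$variant_effect, "not_mutated")
  expect_identical(row("C")$significance_direction, "not_found")
  expect_true(row("C")$druggable)
  expect_false(row("A")$druggable)
})

test_that("network export writes node, edge and GraphML files", {
  rec <- rbind(mkRecords("A", "B", 2), mkRecords("B", "C", 2))
  net <- buildNetwork(rec, seeds = c("A", "B", "C"))
  out <- tempfile()
  paths <- writeNetwork(net, out)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[["edges"]])
  expect_identical(nrow(edges), 2L)
  expect_match(readLines(paths[["graphml"]], n = 2)[2], "graphml",
               ignore.case = TRUE)
})

test_that("readInteractions aggregates raw BioGRID-style rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Official Symbol Interactor A", "Official Symbol Interactor B",
          "Organism Interactor A", "Organism Interactor B",
          "Pubmed ID", "Experimental System", sep = "\t"),
    "A\tB\t9606\t9606\t111\tTwo-hybrid",
    "B\tA\t9606\t9606\t222\tAP-MS",        # same pair, second evidence
    "A\tB\t9606\t9606\t111\tTwo-hybrid",   # exact duplicate, not new evidence
    "A\tC\t9606\t9606\t333\tTwo-hybrid"), f)
  rec <- readInteractions(f)
  ab <- rec[rec$a == "A" & rec$b == "B", ]
  expect_identical(ab$evidence_count, 2L)
  ac <- rec[rec$a == "A" & rec$b == "C", ]
  expect_identical(ac$evidence_count, 1L)
})
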