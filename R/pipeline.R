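# End-to-end driver over the synthetic fixtures: genome -> variant databases
# -> impact annotation -> peptide classification -> quantitative statistics
# -> network reconstruction -> drug prioritization.

# resources derived from the variant truth table, so impact annotation has
# guaranteed positive and negative cases
truthResources <- function(truth, models) {
  geneOf <- function(tid) vapply(tid, function(t)
    as.character(mcols(models[[t]])$gene_id[1]), character(1))
  subs <- truth[truth$type == "substitution", , drop = FALSE]
  loss <- subs[subs$sty_change %in% c("loss", "loss_and_gain"), , drop = FALSE]
  mel <- subs[seq_len(nrow(subs)) %% 3L == 0L, , drop = FALSE]
  annotationResources(
    knownPhosphosites = data.frame(protein = geneOf(loss$transcript_id),
                                   position = loss$aa_pos),
    kinaseMotifs = data.frame(
      kinase = c("basophilic", "proline_directed", "acidophilic"),
      motif = c("RxxS", "SP", "SxxE")),
    melanomaVariants = data.frame(gene = geneOf(mel$transcript_id),
                                  position = mel$aa_pos),
    cancerVariants = data.frame(gene = geneOf(mel$transcript_id),
                                position = mel$aa_pos),
    cancerGenes = unique(geneOf(subs$transcript_id))[c(TRUE, FALSE)],
    resistanceGenes = unique(geneOf(subs$transcript_id))[c(FALSE, TRUE)]
  )
}

#' Run the full synthetic pipeline
#'
#' Generates seeded fixtures and pushes them through every stage: database
#' construction, impact annotation (phospho strategy), peptide
#' classification and coverage, phosphosite normalization and the moderated
#' permutation test (proteome FDR 0.05, phosphoproteome FDR 0.10),
#' overrepresentation, network reconstruction, node ranking and drug
#' prioritization. With a fixed seed the result is fully deterministic.
#'
#' @param seed integer seed driving every random component.
#' @param spec a \code{\link{fixtureSpec}}.
#' @param outDir optional directory; when given, all tables are written as
#'   tab-separated files plus FASTA/VCF/GraphML.
#' @param topN node cutoff for the ranked network view (default 200).
#' @return named list with every intermediate and final result.
#' @export
runPipeline <- function(seed = 1L, spec = fixtureSpec(), outDir = NULL,
                        topN = 200L) {
  ga <- makeGenomeAnnotation(spec, seed, outDir = outDir)
  mv <- makeVariants(spec, ga$genome, ga$models, seed = seed + 1L,
                     outDir = outDir)
  db <- buildDatabases(ga$genome, ga$models, list(S1 = mv$variants))
  resources <- truthResources(mv$truth, ga$models)
  impact <- annotateImpact(db, resources, strategy = "phospho")

  ev <- makeEvidence(spec, db, seed = seed + 2L, outDir = outDir)
  cls <- classifyEvidence(ev$evidence, db)
  coverage <- summarizeCoverage(cls$classified)

  qn <- makeQuantNetwork(spec, seed = seed + 3L, outDir = outDir)
  norm <- normalizePhospho(qn$sites, qn$proteins, qn$parent)
  protTest <- moderatedTTest(filterComplete(qn$proteins), qn$groups,
                             testParams(s0 = 0.1, fdrThreshold = 0.05,
                                        seed = seed + 4L))
  siteTest <- moderatedTTest(filterComplete(norm$matrix), qn$groups,
                             testParams(s0 = 0.1, fdrThreshold = 0.10,
                                        seed = seed + 5L))
  categories <- list(
    spiked_set = qn$spiked,
    background_set = setdiff(rownames(qn$proteins), qn$spiked)[1:200])
  enrich <- fisherEnrichment(protTest$feature[protTest$significant],
                             protTest$feature, categories,
                             fdrThreshold = 0.2)

  net <- buildNetwork(qn$interactions, seeds = qn$seeds, mode = "seeded")
  quantDir <- data.frame(
    gene = protTest$feature[protTest$significant],
    direction = ifelse(protTest$difference[protTest$significant] > 0,
                       "up_in_R", "up_in_S"),
    layer = "proteome", stringsAsFactors = FALSE)
  net <- annotateNodes(net, impact = impact, quant = quantDir,
                       drugs = qn$drugs)
  topNodes <- if (nrow(nodeTable(net))) rankNodes(net, topN) else nodeTable(net)
  drugRank <- prioritizeDrugs(qn$drugs, net)

  out <- list(genome = ga, variants = mv, db = db, resources = resources,
              impact = impact, evidence = ev, classified = cls$classified,
              unassigned = cls$unassigned, coverage = coverage,
              normalized = norm, proteinTest = protTest, siteTest = siteTest,
              enrichment = enrich, network = net, topNodes = topNodes,
              drugRanking = drugRank)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeDatabases(db, outDir)
    wt <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(impact, "impact_annotation.tsv")
    wt(cls$classified, "classified_peptides.tsv")
    wt(coverage, "isoform_coverage.tsv")
    wt(protTest, "protein_test.tsv")
    wt(siteTest, "phosphosite_test.tsv")
    wt(enrich, "enrichment.tsv")
    wt(topNodes, "top_nodes.tsv")
    wt(drugRank, "drug_ranking.tsv")
    writeNetwork(net, file.path(outDir, "network"))
  }
  out
}
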