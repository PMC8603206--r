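# Reconstruction of the filtered undirected PPI network, node metrics and
# drug prioritization.

#' Read an interaction table
#'
#' Accepts the BioGRID TAB 2.0/3.0 column layout (official symbols, organism
#' columns, publication and experimental system) or a minimal table with
#' columns \code{a}, \code{b}, \code{evidence_count} and optionally
#' \code{organism_a}, \code{organism_b}. Raw BioGRID rows are aggregated per
#' undirected pair, counting distinct (publication, method) combinations as
#' the evidence count.
#'
#' @param path tab-separated interaction file.
#' @return data.frame(a, b, organism_a, organism_b, evidence_count).
#' @export
readInteractions <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
  nm <- names(tab)
  symA <- grep("Official Symbol Interactor A", nm, value = TRUE)
  if (length(symA)) {
    a <- tab[["Official Symbol Interactor A"]]
    b <- tab[["Official Symbol Interactor B"]]
    orgA <- as.character(tab[[grep("Organism.*A", nm, value = TRUE)[1]]])
    orgB <- as.character(tab[[grep("Organism.*B", nm, value = TRUE)[1]]])
    pub <- if ("Pubmed ID" %in% nm) tab[["Pubmed ID"]] else
      if ("Publication Source" %in% nm) tab[["Publication Source"]] else seq_len(nrow(tab))
    met <- if ("Experimental System" %in% nm) tab[["Experimental System"]] else ""
    key <- ifelse(a < b, paste(a, b, orgA, orgB, sep = "\r"),
                  paste(b, a, orgB, orgA, sep = "\r"))
    ev <- tapply(paste(pub, met), key, function(x) length(unique(x)))
    parts <- strsplit(names(ev), "\r", fixed = TRUE)
    data.frame(
      a = vapply(parts, `[`, character(1), 1),
      b = vapply(parts, `[`, character(1), 2),
      organism_a = vapply(parts, `[`, character(1), 3),
      organism_b = vapply(parts, `[`, character(1), 4),
      evidence_count = as.integer(ev),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    assertThat(all(c("a", "b", "evidence_count") %in% nm),
               "interaction table needs columns a, b, evidence_count")
    if (!"organism_a" %in% nm) tab$organism_a <- "9606"
    if (!"organism_b" %in% nm) tab$organism_b <- "9606"
    tab[, c("a", "b", "organism_a", "organism_b", "evidence_count")]
  }
}

isHuman <- function(x) {
  tolower(as.character(x)) %in% c("9606", "homo sapiens", "human", "h. sapiens")
}

#' Build the filtered undirected signaling network
#'
#' Applies the filter cascade to interaction records — both interactors
#' human, at least two experimental evidences, self loops removed, parallel
#' edges deduplicated, orphan (degree-0) nodes dropped — and restricts the
#' graph either to edges strictly between seed entries (\code{mode =
#' "seeded"}; seeds = significantly changing (phospho)proteins plus
#' potential driver-mutation genes) or to the subnetwork induced on a focus
#' protein and its direct interactors (\code{mode = "focus"}, used for
#' single-protein interactome views).
#'
#' @param records interaction data.frame (see \code{\link{readInteractions}}).
#' @param seeds character vector of seed gene symbols (\code{mode="seeded"}).
#' @param mode \code{"seeded"} or \code{"focus"}.
#' @param focus focus gene symbol (\code{mode="focus"}).
#' @param minEvidence minimum evidence count (default 2).
#' @return a \code{\link{SignalingNetwork-class}}; empty graph allowed.
#' @export
buildNetwork <- function(records, seeds = NULL,
                         mode = c("seeded", "focus"), focus = NULL,
                         minEvidence = 2L) {
  mode <- match.arg(mode)
  keep <- isHuman(records$organism_a) & isHuman(records$organism_b) &
    records$evidence_count >= minEvidence & records$a != records$b
  rec <- records[keep, , drop = FALSE]
  if (mode == "seeded") {
    assertThat(length(seeds) > 0L, "seeded mode requires seed entries")
    rec <- rec[rec$a %in% seeds & rec$b %in% seeds, , drop = FALSE]
  } else {
    assertThat(!is.null(focus), "focus mode requires a focus gene")
    inter <- unique(c(rec$b[rec$a == focus], rec$a[rec$b == focus]))
    keepN <- c(focus, inter)
    rec <- rec[rec$a %in% keepN & rec$b %in% keepN, , drop = FALSE]
  }
  if (!nrow(rec)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(new("SignalingNetwork", graph = g,
               nodes = data.frame(node = character(0), degree = numeric(0),
                                  betweenness = numeric(0)),
               mode = mode))
  }
  g <- graph_from_data_frame(rec[, c("a", "b")], directed = FALSE)
  g <- simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- delete_vertices(g, which(degree(g) == 0))
  nodes <- data.frame(
    node = V(g)$name,
    degree = as.numeric(degree(g)),
    betweenness = as.numeric(betweenness(g, directed = FALSE,
                                         normalized = FALSE)),
    stringsAsFactors = FALSE)
  new("SignalingNetwork", graph = g, nodes = nodes, mode = mode)
}

#' Rank network nodes and keep the top N
#'
#' Nodes are ranked by degree descending (ties by betweenness descending,
#' then by name) and the first \code{topN} retained; metrics are those of the
#' full filtered graph, computed before truncation.
#'
#' @param net a \code{\link{SignalingNetwork-class}}.
#' @param topN how many nodes to keep (e.g. 200 for a resistance network, 50
#'   for a single-kinase interactome).
#' @return data.frame of the top nodes with their metrics.
#' @export
rankNodes <- function(net, topN) {
  assertThat(topN > 0L, "topN must be positive")
  nodes <- nodeTable(net)
  assertThat(nrow(nodes) > 0L, "network is empty")
  o <- order(-nodes$degree, -nodes$betweenness, nodes$node)
  out <- nodes[o, , drop = FALSE][seq_len(min(topN, nrow(nodes))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate network nodes with variant, omics and impact information
#'
#' Joins (by gene symbol) the impact annotation table, the quantitative test
#' results and a variant-effect table onto the node table. Unmatched nodes
#' default to \code{not_mutated} / \code{not_found} / impact 0.
#'
#' @param net a \code{\link{SignalingNetwork-class}}.
#' @param impact optional data.frame(gene_id, scaled_score) (e.g. from
#'   \code{\link{annotateImpact}}).
#' @param quant optional data.frame(gene, direction) with direction in
#'   \code{up_in_R}/\code{up_in_S}/\code{not_changing}, plus optional
#'   \code{layer} (\code{proteome}/\code{phosphoproteome}).
#' @param variantEffects optional data.frame(gene, effect) with effect in
#'   \code{unknown_effect}/\code{resistant_unique}/\code{loss_of_function}/
#'   \code{gain_of_function}.
#' @param drugs optional drug table (see \code{\link{readDrugs}}) used to set
#'   the \code{druggable} flag.
#' @return the network with its node table extended.
#' @export
annotateNodes <- function(net, impact = NULL, quant = NULL,
                          variantEffects = NULL, drugs = NULL) {
  nodes <- nodeTable(net)
  nodes$variant_effect <- "not_mutated"
  nodes$significance_direction <- "not_found"
  nodes$omic_layers <- ""
  nodes$impact_size <- 0
  nodes$druggable <- FALSE
  if (!is.null(variantEffects) && nrow(variantEffects)) {
    m <- match(nodes$node, variantEffects$gene)
    hit <- !is.na(m)
    nodes$variant_effect[hit] <- variantEffects$effect[m[hit]]
    nodes$omic_layers[hit] <- "variant"
  }
  if (!is.null(quant) && nrow(quant)) {
    m <- match(nodes$node, quant$gene)
    hit <- !is.na(m)
    nodes$significance_direction[hit] <- quant$direction[m[hit]]
    if ("layer" %in% names(quant)) {
      lay <- quant$layer[m[hit]]
      nodes$omic_layers[hit] <- trimws(paste(nodes$omic_layers[hit], lay), whitespace = "[ ]")
    }
  }
  if (!is.null(impact) && nrow(impact)) {
    agg <- tapply(impact$scaled_score, impact$gene_id, max)
    m <- match(nodes$node, names(agg))
    hit <- !is.na(m)
    nodes$impact_size[hit] <- as.numeric(agg[m[hit]])
  }
  if (!is.null(drugs) && nrow(drugs))
    nodes$druggable <- nodes$node %in% drugs$target
  new("SignalingNetwork", graph = networkGraph(net), nodes = nodes,
      mode = net@mode)
}

#' Read a drug-target table
#'
#' One row per (drug, target) pair: columns \code{drug}, \code{target},
#' \code{organism}; extra columns (category, approval status) are retained
#' but never filtered on.
#'
#' @param path tab-separated file.
#' @return data.frame.
#' @export
readDrugs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assertThat(all(c("drug", "target") %in% names(tab)),
             "drug table needs columns drug, target")
  if (!"organism" %in% names(tab)) tab$organism <- "9606"
  tab
}

#' Specificity of one drug against a network
#'
#' Specificity = number of the drug's targets present in the network divided
#' by all of its reported targets. Drugs without any in-network target (or
#' not acting in human) are excluded (\code{NULL}).
#'
#' @param drug drug name.
#' @param targets character vector of all reported targets of the drug.
#' @param net a \code{\link{SignalingNetwork-class}}.
#' @param human logical; whether the drug acts in human.
#' @return list(drug, inNetworkTargets, specificity, priorityScore) or NULL.
#' @export
computeDrugSpecificity <- function(drug, targets, net, human = TRUE) {
  if (!human) return(NULL)
  targets <- unique(targets)
  assertThat(length(targets) > 0L, "drug must have at least one target")
  nodes <- nodeTable(net)
  inNet <- intersect(targets, nodes$node)
  if (!length(inNet)) return(NULL)
  list(drug = drug, inNetworkTargets = inNet,
       specificity = length(inNet) / length(targets),
       priorityScore = sum(nodes$degree[match(inNet, nodes$node)]))
}

#' Prioritize drugs against a signaling network
#'
#' Keeps human-acting drugs with at least one in-network target; specificity
#' is the in-network fraction of all reported targets and the priority score
#' sums the network degree of the in-network targets. Sorted by priority
#' score descending, ties by specificity descending then drug name.
#'
#' @param drugs data.frame(drug, target, organism) — one row per pair.
#' @param net a \code{\link{SignalingNetwork-class}}.
#' @return data.frame(drug, n_targets, in_network_targets, specificity,
#'   priority_score), ranked.
#' @export
prioritizeDrugs <- function(drugs, net) {
  rows <- list()
  for (d in unique(drugs$drug)) {
    sub <- drugs[drugs$drug == d, , drop = FALSE]
    human <- all(isHuman(sub$organism))
    res <- computeDrugSpecificity(d, sub$target, net, human = human)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, n_targets = length(unique(sub$target)),
      in_network_targets = paste(sort(res$inNetworkTargets), collapse = ";"),
      specificity = res$specificity, priority_score = res$priorityScore,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(drug = character(0), n_targets = integer(0),
                      in_network_targets = character(0),
                      specificity = numeric(0), priority_score = numeric(0)))
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$priority_score, -tab$specificity, tab$drug), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Export a network for external visualization
#'
#' Writes the node table, edge table (tab-separated) and a GraphML file
#' importable into Cytoscape.
#'
#' @param net a \code{\link{SignalingNetwork-class}}.
#' @param outDir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
writeNetwork <- function(net, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nodesPath <- file.path(outDir, "nodes.tsv")
  edgesPath <- file.path(outDir, "edges.tsv")
  gmlPath <- file.path(outDir, "network.graphml")
  write.table(nodeTable(net), nodesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  edges <- as_data_frame(networkGraph(net), what = "edges")
  names(edges)[1:2] <- c("a", "b")
  write.table(edges, edgesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- networkGraph(net)
  nodes <- nodeTable(net)
  for (cn in setdiff(names(nodes), "node"))
    vertex_attr(g, cn) <- nodes[[cn]][match(V(g)$name, nodes$node)]
  write_graph(g, gmlPath, format = "graphml")
  invisible(c(nodes = nodesPath, edges = edgesPath, graphml = gmlPath))
}
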