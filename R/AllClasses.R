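#' Reference/alternate protein isoform pair
#'
#' Holds the translated reference protein of one transcript together with the
#' alternate protein obtained by injecting all sample variants that fall in
#' its CDS, plus the amino acid level mapping of every injected variant.
#'
#' @slot transcriptId,geneId,sample identifiers.
#' @slot referenceProtein,alternateProtein amino acid strings (no internal
#'   stop character; translation stops at the first stop codon).
#' @slot variants data.frame with one row per injected variant: genomic
#'   coordinates (`chrom`, `pos`, `ref`, `alt`, `zygosity`), the 1-based
#'   transcript nucleotide span (`txStart`, `txEnd`), the 1-based amino acid
#'   spans on each protein (`refAaStart`, `refAaEnd`, `altAaStart`,
#'   `altAaEnd`), the protein-level `name` (e.g. "F31I", "E61X",
#'   "V110RfsX24"; empty when synonymous) and a `synonymous` flag.
#'
#' @exportClass ProteinIsoformPair
setClass("ProteinIsoformPair",
  representation(
    transcriptId = "character",
    geneId = "character",
    sample = "character",
    referenceProtein = "character",
    alternateProtein = "character",
    variants = "data.frame"
  )
)

setValidity("ProteinIsoformPair", function(object) {
  msg <- character()
  for (s in c(object@referenceProtein, object@alternateProtein)) {
    if (!nzchar(s)) msg <- c(msg, "protein sequences must be nonempty")
    if (grepl("\\*", s)) msg <- c(msg, "protein sequences must not contain internal stops")
  }
  v <- object@variants
  if (nrow(v)) {
    if (any(v$refAaStart < 1 | v$refAaEnd > nchar(object@referenceProtein), na.rm = TRUE))
      msg <- c(msg, "reference amino acid span out of bounds")
    if (any(v$altAaStart < 1 | v$altAaEnd > nchar(object@alternateProtein), na.rm = TRUE))
      msg <- c(msg, "alternate amino acid span out of bounds")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProteinIsoformPair-class compact display
#' @param object a \code{ProteinIsoformPair}
#' @export
setMethod("show", "ProteinIsoformPair", function(object) {
  nm <- variantNames(object)
  cat("ProteinIsoformPair", object@transcriptId,
      sprintf("(%s, sample %s)\n", object@geneId, object@sample))
  cat(sprintf("  reference: %d aa; alternate: %d aa\n",
              nchar(object@referenceProtein), nchar(object@alternateProtein)))
  cat("  variants:", if (length(nm)) paste(nm, collapse = "; ") else "none", "\n")
})

#' Variant protein database
#'
#' Container for the reference protein database and the per-sample alternate
#' databases produced by \code{\link{buildDatabases}}.
#'
#' @slot reference \code{AAStringSet} of reference proteins (one per
#'   translatable transcript).
#' @slot alternate named list (by sample) of \code{AAStringSet}s of alternate
#'   proteins, one per transcript carrying at least one protein-changing
#'   variant.
#' @slot pairs named list (by sample) of lists of
#'   \code{\link{ProteinIsoformPair}} objects.
#' @slot skipped data.frame log of variants that could not be injected
#'   (splice-junction overlap, outside CDS, reference mismatch, start-codon
#'   disruption) with a reason per row.
#'
#' @exportClass VariantDB
setClass("VariantDB",
  representation(
    reference = "AAStringSet",
    alternate = "list",
    pairs = "list",
    skipped = "data.frame"
  )
)

#' @describeIn VariantDB-class compact display
#' @param object a \code{VariantDB}
#' @export
setMethod("show", "VariantDB", function(object) {
  cat("VariantDB\n")
  cat(sprintf("  reference proteins : %d\n", length(object@reference)))
  for (s in names(object@alternate))
    cat(sprintf("  alternate [%s]     : %d\n", s, length(object@alternate[[s]])))
  cat(sprintf("  skipped variants   : %d\n", nrow(object@skipped)))
})

#' Filtered undirected signaling network
#'
#' Wraps the igraph object produced by \code{\link{buildNetwork}} together
#' with its node metric/annotation table.
#'
#' @slot graph undirected simple \code{igraph} (no self loops, no orphan
#'   nodes, deduplicated edges).
#' @slot nodes data.frame with one row per node: `node`, `degree`,
#'   `betweenness` and, after \code{\link{annotateNodes}}, `variant_effect`,
#'   `omic_layers`, `significance_direction`, `impact_size`, `druggable`.
#' @slot mode "seeded" (edges strictly between seed entries) or "focus"
#'   (subnetwork induced on a focus protein and its direct interactors).
#'
#' @exportClass SignalingNetwork
setClass("SignalingNetwork",
  representation(graph = "ANY", nodes = "data.frame", mode = "character")
)

setValidity("SignalingNetwork", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (igraph::any_loop(g)) return("self loops must be removed")
  if (vcount(g) > 0 && any(degree(g) == 0)) return("orphan nodes must be removed")
  TRUE
})

#' @describeIn SignalingNetwork-class compact display
#' @param object a \code{SignalingNetwork}
#' @export
setMethod("show", "SignalingNetwork", function(object) {
  cat(sprintf("SignalingNetwork (%s): %d nodes, %d edges\n",
              object@mode, vcount(object@graph), ecount(object@graph)))
  if (nrow(object@nodes)) {
    top <- object@nodes[order(-object@nodes$degree), , drop = FALSE]
    cat("  top degree:", paste(head(top$node, 5), collapse = ", "), "\n")
  }
})

#' Accessors
#'
#' @param x a \code{ProteinIsoformPair}, \code{VariantDB} or
#'   \code{SignalingNetwork}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("referenceProtein", function(x) standardGeneric("referenceProtein"))
#' @rdname accessors
#' @export
setMethod("referenceProtein", "ProteinIsoformPair", function(x) x@referenceProtein)

#' @rdname accessors
#' @export
setGeneric("alternateProtein", function(x) standardGeneric("alternateProtein"))
#' @rdname accessors
#' @export
setMethod("alternateProtein", "ProteinIsoformPair", function(x) x@alternateProtein)

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setMethod("variantTable", "ProteinIsoformPair", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("variantNames", function(x) standardGeneric("variantNames"))
#' @rdname accessors
#' @export
setMethod("variantNames", "ProteinIsoformPair", function(x) {
  nm <- x@variants$name
  nm[nzchar(nm)]
})

#' @rdname accessors
#' @export
setGeneric("referenceDB", function(x) standardGeneric("referenceDB"))
#' @rdname accessors
#' @export
setMethod("referenceDB", "VariantDB", function(x) x@reference)

#' @rdname accessors
#' @export
setGeneric("alternateDB", function(x) standardGeneric("alternateDB"))
#' @rdname accessors
#' @export
setMethod("alternateDB", "VariantDB", function(x) x@alternate)

#' @rdname accessors
#' @export
setGeneric("isoformPairs", function(x) standardGeneric("isoformPairs"))
#' @rdname accessors
#' @export
setMethod("isoformPairs", "VariantDB", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("skippedVariants", function(x) standardGeneric("skippedVariants"))
#' @rdname accessors
#' @export
setMethod("skippedVariants", "VariantDB", function(x) x@skipped)

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @rdname accessors
#' @export
setMethod("networkGraph", "SignalingNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setMethod("nodeTable", "SignalingNetwork", function(x) x@nodes)
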