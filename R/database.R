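# Construction of the reference and per-sample alternate protein databases.

#' Build reference and alternate variant protein databases
#'
#' Translates every transcript model into the reference database and, per
#' sample, injects all of the sample's variants overlapping each transcript
#' CDS into a single alternate isoform. Alternate isoforms whose protein
#' equals the reference (all changes synonymous) are omitted, as are isoforms
#' whose start codon is disrupted; the reasons are logged in the skip table.
#'
#' @param genome named \code{DNAStringSet} or named character vector.
#' @param models list of transcript model \code{GRanges} (see
#'   \code{\link{readTranscriptModels}}).
#' @param variantSets named list (sample -> variant data.frame as returned by
#'   \code{\link{readVariants}}); a single data.frame is treated as one
#'   sample named after its \code{sample} column (or \code{"sample"}).
#'
#' @return a \code{\link{VariantDB-class}} object.
#' @export
buildDatabases <- function(genome, models, variantSets) {
  genome <- asGenome(genome)
  if (is.data.frame(variantSets)) {
    nm <- if ("sample" %in% names(variantSets) && nrow(variantSets))
      as.character(variantSets$sample[1]) else "sample"
    variantSets <- setNames(list(variantSets), nm)
  }

  refSeqs <- character(0)
  refNames <- character(0)
  for (model in models) {
    prot <- tryCatch(translateCds(extractCdsSequence(genome, model)),
                     error = function(e) "")
    if (!nzchar(prot)) next
    tid <- as.character(mcols(model)$transcript_id[1])
    gid <- as.character(mcols(model)$gene_id[1])
    refSeqs <- c(refSeqs, prot)
    refNames <- c(refNames, sprintf("%s|%s|reference|", tid, gid))
  }
  if (!length(refSeqs))
    warning("no translatable transcripts: databases are empty")
  reference <- AAStringSet(refSeqs)
  names(reference) <- refNames

  alternate <- list()
  pairs <- list()
  skipCols <- c("chrom", "pos", "ref", "alt", "zygosity", "sample", "reason")
  skipped <- data.frame(matrix(nrow = 0, ncol = length(skipCols),
                               dimnames = list(NULL, skipCols)),
                        stringsAsFactors = FALSE)
  addSkips <- function(sk, sample) {
    if (is.null(sk) || !nrow(sk)) return(invisible())
    sk$sample <- sample
    for (cn in setdiff(skipCols, names(sk))) sk[[cn]] <- NA
    skipped <<- rbind(skipped, sk[, skipCols, drop = FALSE])
  }

  for (sampleName in names(variantSets)) {
    vars <- variantSets[[sampleName]]
    altSeqs <- character(0); altNames <- character(0)
    samplePairs <- list()
    for (model in models) {
      chrom <- as.character(seqnames(model))[1]
      onChrom <- vars[vars$chrom == chrom, , drop = FALSE]
      if (!nrow(onChrom)) next
      hits <- onChrom[overlapsCds(model, onChrom), , drop = FALSE]
      if (!nrow(hits)) next
      built <- buildIsoformPair(genome, model, hits, sample = sampleName)
      addSkips(built$skipped, sampleName)
      pair <- built$pair
      if (is.null(pair)) next
      nm <- variantNames(pair)
      altSeqs <- c(altSeqs, alternateProtein(pair))
      altNames <- c(altNames, sprintf("%s|%s|%s|%s", pair@transcriptId,
                                      pair@geneId, sampleName,
                                      paste(nm, collapse = ";")))
      samplePairs[[pair@transcriptId]] <- pair
    }
    aas <- AAStringSet(altSeqs)
    names(aas) <- altNames
    alternate[[sampleName]] <- aas
    pairs[[sampleName]] <- samplePairs
  }

  new("VariantDB", reference = reference, alternate = alternate,
      pairs = pairs, skipped = skipped)
}

# logical index of variants whose genomic span touches the transcript CDS
overlapsCds <- function(model, vars) {
  if (!nrow(vars)) return(logical(0))
  ir <- IRanges(vars$pos, vars$pos + nchar(vars$ref) - 1L)
  IRanges::overlapsAny(ir, IRanges::ranges(model))
}

#' Write a variant protein database to FASTA
#'
#' Writes the reference database and one alternate FASTA per sample, with
#' 60-column wrapping and headers
#' \code{>transcript_id|gene_id|sample|variant1;variant2}.
#'
#' @param db a \code{\link{VariantDB-class}} object.
#' @param outDir output directory (created if missing).
#' @return invisibly, the paths written (named character vector).
#' @export
writeDatabases <- function(db, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(outDir, "reference.fasta"))
  writeXStringSet(referenceDB(db), paths[["reference"]], width = 60L)
  for (s in names(alternateDB(db))) {
    p <- file.path(outDir, sprintf("alternate_%s.fasta", s))
    writeXStringSet(alternateDB(db)[[s]], p, width = 60L)
    paths[[paste0("alternate_", s)]] <- p
  }
  invisible(paths)
}
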