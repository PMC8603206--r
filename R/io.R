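# Readers for the standard input formats: genome FASTA, GFF3/GTF transcript
# models, VCF variant calls and the tab-separated annotation resources.

#' Read a genome FASTA
#'
#' @param path multi-record FASTA, wrapped or unwrapped.
#' @return named \code{DNAStringSet}; names are truncated at the first
#'   whitespace of the FASTA header.
#' @export
readGenome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read transcript models from GFF3/GTF
#'
#' Imports CDS features and groups them per transcript. Each returned element
#' is a \code{GRanges} of the (sorted, non-overlapping) CDS segments of one
#' transcript with metadata columns \code{transcript_id}, \code{gene_id} and
#' \code{phase} (phase of the first codon in transcription order, replicated
#' on every row).
#'
#' @param path GFF3 or GTF file with CDS features.
#' @param transcriptKey,geneKey attribute names holding the transcript and
#'   gene identifiers. For GFF3 the default falls back to \code{Parent} when
#'   \code{transcript_id} is absent.
#' @return named list of \code{GRanges}, one per transcript.
#' @export
readTranscriptModels <- function(path, transcriptKey = "transcript_id",
                                 geneKey = "gene_id") {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  assertThat(length(gr) > 0L, "no CDS features found in %s", path)
  mc <- mcols(gr)
  tid <- if (transcriptKey %in% names(mc)) as.character(mc[[transcriptKey]])
         else NULL
  if (is.null(tid) || all(is.na(tid))) {
    assertThat("Parent" %in% names(mc), "no transcript identifier attribute found")
    tid <- vapply(mc$Parent, function(p) sub("^transcript:", "", as.character(p)[1]),
                  character(1))
  }
  gid <- if (geneKey %in% names(mc)) as.character(mc[[geneKey]]) else tid
  gid[is.na(gid)] <- tid[is.na(gid)]
  phase <- if ("phase" %in% names(mc)) suppressWarnings(as.integer(mc$phase))
           else rep(0L, length(gr))
  phase[is.na(phase)] <- 0L

  out <- lapply(split(seq_along(gr), tid), function(idx) {
    m <- gr[idx]
    o <- order(start(m))
    m <- m[o]
    ph <- phase[idx][o]
    # phase of the first codon in transcription order
    first <- if (as.character(strand(m))[1] == "-") length(m) else 1L
    g <- GRanges(seqnames(m), IRanges(start(m), end(m)), strand = strand(m))
    mcols(g)$transcript_id <- tid[idx][o]
    mcols(g)$gene_id <- gid[idx][o]
    mcols(g)$phase <- ph[first]
    validateModel(g)
    g
  })
  out
}

validateModel <- function(model) {
  assertThat(sum(width(model)) >= 3L, "total CDS length of %s below one codon",
             mcols(model)$transcript_id[1])
  if (length(model) > 1L) {
    s <- start(model); e <- end(model)
    assertThat(all(s[-1] > e[-length(e)]),
               "CDS segments of %s overlap", mcols(model)$transcript_id[1])
  }
  assertThat(modelPhase(model) %in% 0:2, "phase must be 0, 1 or 2")
  invisible(model)
}

#' Read variant calls from VCF
#'
#' Consumes CHROM/POS/REF/ALT and the GT genotype field of a VCF v4.x file;
#' multi-allelic records are split into one row per alternate allele.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample sample label to attach; defaults to the first VCF sample
#'   column name (or \code{"sample"} when none).
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{zygosity} (\code{homozygous}/\code{heterozygous}/
#'   \code{unknown}) and \code{sample}.
#' @export
readVariants <- function(path, sample = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (is.null(sample)) {
    sn <- colnames(vcf)
    sample <- if (length(sn)) sn[1] else "sample"
  }
  zyg <- rep("unknown", length(rr))
  if (!is.null(gt) && ncol(gt) >= 1L) {
    g <- gsub("\\|", "/", gt[, 1])
    zyg[g %in% c("1/1")] <- "homozygous"
    zyg[g %in% c("0/1", "1/0")] <- "heterozygous"
  }
  out <- data.frame(
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    zygosity = zyg,
    sample = sample,
    stringsAsFactors = FALSE
  )
  keep <- grepl("^[ACGT]+$", out$ref) & grepl("^[ACGT]+$", out$alt)
  out[keep, , drop = FALSE]
}

#' Read annotation resources from a directory of tab-separated tables
#'
#' Expected files (all optional; missing ones give empty resources):
#' \itemize{
#'   \item \code{known_phosphosites.tsv}: columns \code{protein},
#'     \code{position}
#'   \item \code{kinase_motifs.tsv}: columns \code{kinase}, \code{motif}
#'     (pattern over the 20 amino acids with \code{x} as wildcard)
#'   \item \code{melanoma_variants.tsv} / \code{cancer_variants.tsv}:
#'     columns \code{gene}, \code{position}
#'   \item \code{cancer_genes.tsv} / \code{resistance_genes.tsv}: column
#'     \code{gene}
#' }
#'
#' @param dir directory path.
#' @return list of resource tables/vectors as used by
#'   \code{\link{annotateImpact}}.
#' @export
readResources <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  emptyPos <- data.frame(gene = character(0), position = integer(0))
  ph <- rd("known_phosphosites.tsv")
  km <- rd("kinase_motifs.tsv")
  mv <- rd("melanoma_variants.tsv")
  cv <- rd("cancer_variants.tsv")
  cg <- rd("cancer_genes.tsv")
  rg <- rd("resistance_genes.tsv")
  annotationResources(
    knownPhosphosites = if (is.null(ph))
      data.frame(protein = character(0), position = integer(0)) else ph,
    kinaseMotifs = if (is.null(km))
      data.frame(kinase = character(0), motif = character(0)) else km,
    melanomaVariants = if (is.null(mv)) emptyPos else mv,
    cancerVariants = if (is.null(cv)) emptyPos else cv,
    cancerGenes = if (is.null(cg)) character(0) else cg$gene,
    resistanceGenes = if (is.null(rg)) character(0) else rg$gene
  )
}

#' Assemble annotation resources
#'
#' Validates and bundles the lookup tables used by the impact annotation:
#' known phosphosites, kinase motifs, known melanoma/cancer variant sites and
#' cancer/resistance gene lists.
#'
#' @param knownPhosphosites data.frame(protein, position), 1-based protein
#'   coordinates.
#' @param kinaseMotifs data.frame(kinase, motif); motifs over the 20 amino
#'   acids with \code{x} matching any residue.
#' @param melanomaVariants,cancerVariants data.frame(gene, position).
#' @param cancerGenes,resistanceGenes character vectors of gene identifiers.
#' @return list with class \code{"AnnotationResources"}.
#' @export
annotationResources <- function(knownPhosphosites = data.frame(protein = character(0), position = integer(0)),
                                kinaseMotifs = data.frame(kinase = character(0), motif = character(0)),
                                melanomaVariants = data.frame(gene = character(0), position = integer(0)),
                                cancerVariants = data.frame(gene = character(0), position = integer(0)),
                                cancerGenes = character(0),
                                resistanceGenes = character(0)) {
  if (nrow(kinaseMotifs)) {
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYx]+$", kinaseMotifs$motif)
    assertThat(all(ok), "malformed kinase motif(s): %s",
               paste(kinaseMotifs$motif[!ok], collapse = ", "))
  }
  structure(list(
    knownPhosphosites = knownPhosphosites,
    kinaseMotifs = kinaseMotifs,
    melanomaVariants = melanomaVariants,
    cancerVariants = cancerVariants,
    cancerGenes = as.character(cancerGenes),
    resistanceGenes = as.character(resistanceGenes)
  ), class = "AnnotationResources")
}
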