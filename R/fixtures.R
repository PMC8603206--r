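# Seeded synthetic-data generators. They produce toy genomes, transcript
# models, variant calls, MS peptide evidence, quantitative matrices,
# interaction tables and drug tables with the exact structure the other
# modules consume, each alongside a machine-readable truth table for oracle
# comparisons. Identical spec + seed gives byte-identical outputs.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Fixture specification
#'
#' Bundles the knobs of all synthetic generators with their defaults: a toy
#' multi-transcript genome (including multi-exon and minus-strand models),
#' a variant set dominated by substitutions with a controllable fraction
#' hitting S/T/Y codons, peptide evidence sampled from the true digests, a
#' 3-vs-3 quantitative design with a 5% spike-in at four noise SDs, and an
#' interaction/drug layer with known filter outcomes.
#'
#' @param nTranscripts number of transcript models.
#' @param fractionMinus fraction of minus-strand transcripts.
#' @param nSubstitutions,nInsertions,nDeletions variant counts per class.
#' @param styFraction fraction of substitutions forced to gain/lose S/T/Y.
#' @param nObservedPeptides rows of the synthetic evidence table.
#' @param nFeatures,nPerGroup,effectSD,noiseSD,spikeFraction quantitative
#'   design: features, samples per group, spike effect in noise-SD units,
#'   noise SD of log2 intensities, fraction of spiked features.
#' @param nNodes,edgeProb,nonHumanFraction interaction layer: node count,
#'   edge probability, fraction of non-human rows.
#' @param nDrugs,maxTargets drug layer size.
#' @return list with class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(nTranscripts = 12L, fractionMinus = 1 / 3,
                        nSubstitutions = 30L, nInsertions = 3L,
                        nDeletions = 3L, styFraction = 0.5,
                        nObservedPeptides = 60L,
                        nFeatures = 1000L, nPerGroup = 3L, effectSD = 4,
                        noiseSD = 0.3, spikeFraction = 0.05,
                        nNodes = 30L, edgeProb = 0.15,
                        nonHumanFraction = 0.1,
                        nDrugs = 10L, maxTargets = 4L) {
  spec <- as.list(environment())
  assertThat(all(vapply(spec, function(x) is.numeric(x) && x >= 0, logical(1))),
             "all fixture spec values must be nonnegative numbers")
  assertThat(fractionMinus <= 1 && styFraction <= 1 && spikeFraction <= 1 &&
               edgeProb <= 1 && nonHumanFraction <= 1,
             "fractions must lie in [0, 1]")
  structure(spec, class = "FixtureSpec")
}

randomCodons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)
randomBases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

#' Generate a toy genome and transcript annotation
#'
#' Builds small chromosomes carrying \code{nTranscripts} CDS models — every
#' CDS starts with ATG and ends with a stop codon, at least one model is
#' multi-exon and (when \code{fractionMinus > 0}) at least one is on the
#' minus strand. Optionally writes genome FASTA and GFF3.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param seed RNG seed.
#' @param outDir optional directory for \code{genome.fasta} / \code{models.gff3}.
#' @return list(genome = DNAStringSet, models = named list of GRanges,
#'   paths = written files or NULL).
#' @export
makeGenomeAnnotation <- function(spec = fixtureSpec(), seed = 1L,
                                 outDir = NULL) {
  nT <- as.integer(spec$nTranscripts)
  assertThat(nT >= 1L, "at least one transcript required")
  res <- withSeed(seed, {
    chromOf <- rep(c("chr1", "chr2"), length.out = nT)
    minus <- rep(FALSE, nT)
    if (spec$fractionMinus > 0) {
      k <- max(1L, round(spec$fractionMinus * nT))
      minus[sample(nT, k)] <- TRUE
    }
    nExons <- sample(1:3, nT, replace = TRUE)
    if (all(nExons == 1L)) nExons[sample(nT, 1)] <- 2L

    chromSeq <- list(chr1 = "", chr2 = "")
    models <- list()
    for (i in seq_len(nT)) {
      nCodon <- sample(40:120, 1)
      cds <- paste0("ATG", paste(randomCodons(nCodon - 2L), collapse = ""),
                    sample(STOP_CODONS, 1))
      L <- nchar(cds)
      k <- min(nExons[i], L %/% 6L)
      bnd <- if (k > 1) sort(sample(seq(3L, L - 3L, by = 3L), k - 1L)) else integer(0)
      exStart <- c(1L, bnd + 1L)
      exEnd <- c(bnd, L)
      exons <- substring(cds, exStart, exEnd)
      if (minus[i]) exons <- rev(vapply(exons, revComp, character(1)))
      introns <- if (k > 1) vapply(seq_len(k - 1L), function(j)
        randomBases(sample(20:50, 1)), character(1)) else character(0)
      block <- exons[1]
      segLen <- nchar(exons[1])
      segOff <- 0L
      for (j in seq_len(k - 1L)) {
        block <- paste0(block, introns[j], exons[j + 1L])
        segOff <- c(segOff, nchar(block) - nchar(exons[j + 1L]))
        segLen <- c(segLen, nchar(exons[j + 1L]))
      }
      chrom <- chromOf[i]
      pad <- randomBases(sample(50:150, 1))
      base <- nchar(chromSeq[[chrom]]) + nchar(pad)
      chromSeq[[chrom]] <- paste0(chromSeq[[chrom]], pad, block)
      gStart <- base + segOff + 1L
      gEnd <- gStart + segLen - 1L
      tid <- sprintf("t%02d", i)
      g <- GRanges(chrom, IRanges(gStart, gEnd),
                   strand = if (minus[i]) "-" else "+")
      mcols(g)$transcript_id <- tid
      mcols(g)$gene_id <- sprintf("g%02d", i)
      mcols(g)$phase <- 0L
      models[[tid]] <- g
    }
    for (cn in names(chromSeq))
      chromSeq[[cn]] <- paste0(chromSeq[[cn]], randomBases(60))
    genome <- DNAStringSet(unlist(chromSeq))
    list(genome = genome, models = models)
  })
  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(outDir, "genome.fasta")
    gff <- file.path(outDir, "models.gff3")
    writeXStringSet(res$genome, fa, width = 60L)
    writeGff3(res$models, gff)
    paths <- c(genome = fa, annotation = gff)
  }
  c(res, list(paths = paths))
}

# minimal deterministic GFF3 writer for the fixture models
writeGff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    tid <- mcols(m)$transcript_id[1]
    gid <- mcols(m)$gene_id[1]
    for (i in seq_along(m)) {
      attrs <- sprintf("ID=cds_%s_%d;Parent=transcript:%s;transcript_id=%s;gene_id=%s",
                       tid, i, tid, tid, gid)
      lines <- c(lines, paste(
        as.character(seqnames(m))[i], "fixture", "CDS",
        start(m)[i], end(m)[i], ".",
        as.character(strand(m))[i], mcols(m)$phase[i], attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
}

# transcript coordinate (phase-trimmed) -> genomic coordinate
mapTranscriptToGenomic <- function(model, tpos) {
  model <- sortModel(model)
  w <- width(model)
  L <- sum(w)
  phase <- modelPhase(model)
  o <- if (as.character(strand(model))[1] == "-") L - (tpos + phase) + 1L
       else tpos + phase
  cb <- cumsum(w) - w
  i <- max(which(cb < o))
  start(model)[i] + (o - cb[i] - 1L)
}

complementBase <- function(x) chartr("ACGT", "TGCA", x)

# single-nucleotide codon mutations with the requested S/T/Y behaviour
pickCodonMutation <- function(codon, wantSty) {
  refAa <- GENETIC_CODE_TABLE[[codon]]
  bases <- c("A", "C", "G", "T")
  cand <- list()
  for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
    nc <- codon
    substr(nc, p, p) <- b
    altAa <- GENETIC_CODE_TABLE[[nc]]
    if (altAa == refAa) next
    styInvolved <- xor(refAa %in% STY, altAa %in% STY) ||
      (refAa %in% STY && altAa %in% STY && refAa != altAa)
    if (wantSty != styInvolved) next
    cand[[length(cand) + 1L]] <- list(pos = p, base = b, refAa = refAa,
                                      altAa = altAa)
  }
  if (!length(cand)) return(NULL)
  cand[[sample(length(cand), 1)]]
}

#' Generate variant calls over a toy genome
#'
#' Places nonsynonymous single-nucleotide substitutions (the requested
#' fraction constructively gaining or losing an S/T/Y residue) plus
#' frameshift insertions and deletions into the CDS of the fixture
#' transcripts, never overlapping each other. REF alleles are taken from the
#' genome, so they match by construction. Indels are placed on dedicated
#' plus-strand transcripts that carry no other variant, keeping every
#' variant's protein-level consequence independently predictable. A truth
#' table records the expected protein-level outcome of each variant.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param genome,models output of \code{\link{makeGenomeAnnotation}}.
#' @param seed RNG seed.
#' @param sample sample label for the VCF column.
#' @param outDir optional directory for \code{variants.vcf} and
#'   \code{variant_truth.tsv}.
#' @return list(variants = data.frame, truth = data.frame, paths).
#' @export
makeVariants <- function(spec = fixtureSpec(), genome, models, seed = 1L,
                         sample = "S1", outDir = NULL) {
  res <- withSeed(seed, {
    tids <- names(models)
    nIndel <- as.integer(spec$nInsertions + spec$nDeletions)
    plusTids <- tids[vapply(models, function(m)
      as.character(strand(m))[1] == "+", logical(1))]
    indelTids <- if (nIndel > 0) {
      assertThat(length(plusTids) >= nIndel,
                 "not enough plus-strand transcripts for the requested indels")
      sample(plusTids, nIndel)
    } else character(0)
    subTids <- setdiff(tids, indelTids)

    usedCodons <- lapply(models, function(m) integer(0))
    cdsCache <- lapply(models, function(m) extractCdsSequence(genome, m))

    vrows <- list(); trows <- list()
    nSty <- round(spec$styFraction * spec$nSubstitutions)
    wantSty <- c(rep(TRUE, nSty), rep(FALSE, spec$nSubstitutions - nSty))

    for (v in seq_len(spec$nSubstitutions)) {
      placed <- FALSE
      for (try in 1:2000) {
        tid <- if (length(subTids) == 1) subTids else sample(subTids, 1)
        model <- models[[tid]]
        cds <- cdsCache[[tid]]
        nCodon <- nchar(cds) %/% 3L
        ci <- sample(2:(nCodon - 1L), 1)   # spare start and stop codons
        if (ci %in% usedCodons[[tid]]) next
        codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
        mut <- pickCodonMutation(codon, wantSty[v])
        if (is.null(mut)) next
        tpos <- (ci - 1L) * 3L + mut$pos
        gpos <- mapTranscriptToGenomic(model, tpos)
        # one genomic base per transcript base only when within one exon
        minusStrand <- as.character(strand(model))[1] == "-"
        txRef <- substr(cds, tpos, tpos)
        txAlt <- mut$base
        gRef <- if (minusStrand) complementBase(txRef) else txRef
        gAlt <- if (minusStrand) complementBase(txAlt) else txAlt
        usedCodons[[tid]] <- c(usedCodons[[tid]], ci)
        chrom <- as.character(seqnames(model))[1]
        vrows[[length(vrows) + 1L]] <- data.frame(
          chrom = chrom, pos = gpos, ref = gRef, alt = gAlt,
          zygosity = sample(c("homozygous", "heterozygous"), 1),
          sample = sample, stringsAsFactors = FALSE)
        sty <- if (!wantSty[v]) "none"
          else if (mut$refAa %in% STY && !(mut$altAa %in% STY)) "loss"
          else if (!(mut$refAa %in% STY) && mut$altAa %in% STY) "gain"
          else "loss_and_gain"
        trows[[length(trows) + 1L]] <- data.frame(
          chrom = chrom, pos = gpos, ref = gRef, alt = gAlt,
          transcript_id = tid, type = "substitution",
          expected_name = if (mut$altAa == "*")
            sprintf("%s%dX", mut$refAa, ci) else
            sprintf("%s%d%s", mut$refAa, ci, mut$altAa),
          aa_pos = ci, ref_aa = mut$refAa, alt_aa = mut$altAa,
          sty_change = sty, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      assertThat(placed, "could not place substitution %d; enlarge the genome spec", v)
    }

    indelKind <- c(rep("insertion", spec$nInsertions),
                   rep("deletion", spec$nDeletions))
    for (j in seq_along(indelKind)) {
      tid <- indelTids[j]
      model <- models[[tid]]
      cds <- cdsCache[[tid]]
      nCodon <- nchar(cds) %/% 3L
      placed <- FALSE
      for (try in 1:200) {
        ci <- sample(3:(nCodon - 6L), 1)
        tpos <- (ci - 1L) * 3L + sample(1:3, 1)
        len <- sample(1:2, 1)              # not divisible by 3: frameshift
        gpos <- mapTranscriptToGenomic(model, tpos)
        gEndNeeded <- if (indelKind[j] == "deletion") tpos + len else tpos
        # keep the whole REF span within one exon
        if (is.null(mapToTranscript(model, gpos,
                                    gEndNeeded - tpos + 1L))) next
        chrom <- as.character(seqnames(model))[1]
        anchor <- substr(cds, tpos, tpos)
        if (indelKind[j] == "insertion") {
          ins <- randomBases(len)
          gRef <- anchor
          gAlt <- paste0(anchor, ins)
        } else {
          gRef <- substr(cds, tpos, tpos + len)
          gAlt <- anchor
        }
        vrows[[length(vrows) + 1L]] <- data.frame(
          chrom = chrom, pos = gpos, ref = gRef, alt = gAlt,
          zygosity = sample(c("homozygous", "heterozygous"), 1),
          sample = sample, stringsAsFactors = FALSE)
        trows[[length(trows) + 1L]] <- data.frame(
          chrom = chrom, pos = gpos, ref = gRef, alt = gAlt,
          transcript_id = tid,
          type = paste0("frameshift_", indelKind[j]),
          expected_name = NA_character_,
          aa_pos = ci, ref_aa = NA_character_, alt_aa = NA_character_,
          sty_change = NA_character_, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      assertThat(placed, "could not place %s on %s", indelKind[j], tid)
    }
    emptyV <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         zygosity = character(0), sample = character(0))
    emptyT <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         transcript_id = character(0), type = character(0),
                         expected_name = character(0), aa_pos = integer(0),
                         ref_aa = character(0), alt_aa = character(0),
                         sty_change = character(0))
    list(variants = if (length(vrows)) do.call(rbind, vrows) else emptyV,
         truth = if (length(trows)) do.call(rbind, trows) else emptyT)
  })
  res$variants <- res$variants[order(res$variants$chrom, res$variants$pos), ]
  res$truth <- res$truth[order(res$truth$chrom, res$truth$pos), ]
  rownames(res$variants) <- rownames(res$truth) <- NULL
  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(outDir, "variants.vcf")
    tru <- file.path(outDir, "variant_truth.tsv")
    writeVcfTable(res$variants, vcf, sample)
    write.table(res$truth, tru, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(vcf = vcf, truth = tru)
  }
  c(res, list(paths = paths))
}

# minimal VCF v4.2 writer for fixture variant tables
writeVcfTable <- function(variants, path, sample = "S1") {
  gtOf <- c(homozygous = "1/1", heterozygous = "0/1", unknown = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(variants$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  gtOf[variants$zygosity])
  writeLines(c(header, body), path)
}

#' Generate MS peptide evidence from true digests
#'
#' Samples peptides directly from the in-silico digests of the reference and
#' alternate isoforms of a \code{\link{VariantDB-class}} so the expected
#' classification label of every row is known at construction time:
#' variant-spanning peptides unique to one digest are labeled reference or
#' alternate, peptides common to both digests without variant overlap are
#' unspecific. Phosphosites (with localization probabilities straddling the
#' 0.99 cutoff) are attached to S/T/Y residues, preferentially on variant
#' positions where possible.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param db a \code{\link{VariantDB-class}}.
#' @param seed RNG seed.
#' @param params \code{\link{digestParams}}.
#' @param outDir optional directory for \code{evidence.tsv} /
#'   \code{evidence_truth.tsv}.
#' @return list(evidence = data.frame, truth = data.frame, paths).
#' @export
makeEvidence <- function(spec = fixtureSpec(), db, seed = 1L,
                         params = digestParams(), outDir = NULL) {
  res <- withSeed(seed, {
    pool <- list()
    for (s in names(isoformPairs(db))) {
      for (pair in isoformPairs(db)[[s]]) {
        iso <- sprintf("%s|%s", pair@transcriptId, s)
        dg <- pairDigests(pair, params)
        refVar <- variantPositions(pair, "ref")
        altVar <- variantPositions(pair, "alt")
        spans <- function(tab, vp) vapply(seq_len(nrow(tab)), function(i)
          any(vp >= tab$start[i] & vp <= tab$end[i]), logical(1))
        refCov <- if (nrow(dg$ref)) spans(dg$ref, refVar) else logical(0)
        altCov <- if (nrow(dg$alt)) spans(dg$alt, altVar) else logical(0)
        refOnly <- dg$ref[refCov & !(dg$ref$peptide %in% dg$alt$peptide), , drop = FALSE]
        altOnly <- dg$alt[altCov & !(dg$alt$peptide %in% dg$ref$peptide), , drop = FALSE]
        common <- dg$ref[!refCov &
                           dg$ref$peptide %in% dg$alt$peptide &
                           !(dg$ref$peptide %in% dg$alt$peptide[altCov]) &
                           !(dg$ref$peptide %in% dg$ref$peptide[refCov]), , drop = FALSE]
        addRows <- function(tab, label, side) {
          for (i in seq_len(nrow(tab)))
            pool[[length(pool) + 1L]] <<- list(
              sequence = tab$peptide[i], isoform = iso, pair = pair,
              start = tab$start[i], end = tab$end[i],
              label = label, side = side, sample = s)
        }
        addRows(refOnly, "reference", "ref")
        addRows(altOnly, "alternate", "alt")
        addRows(common, "unspecific", "ref")
      }
    }
    assertThat(length(pool) > 0L, "no digestible peptides in the database")
    take <- sample(length(pool), min(spec$nObservedPeptides, length(pool)),
                   replace = FALSE)
    evRows <- list(); trRows <- list()
    for (idx in take) {
      p <- pool[[idx]]
      aa <- strsplit(p$sequence, "")[[1]]
      styOff <- which(aa %in% STY)
      varPos <- variantPositions(p$pair, p$side)
      varOff <- intersect(styOff, varPos - p$start + 1L)
      offs <- integer(0); probs <- numeric(0)
      if (length(styOff) && runif(1) < 0.7) {
        off <- if (length(varOff)) varOff[1]
               else styOff[sample(length(styOff), 1)]
        offs <- off
        probs <- sample(c(0.999, 0.995, 0.8, 0.5), 1)
      }
      evRows[[length(evRows) + 1L]] <- data.frame(
        sequence = p$sequence, proteins = p$isoform,
        phospho_offsets = paste(offs, collapse = ";"),
        phospho_probs = paste(probs, collapse = ";"),
        intensity = round(2^rnorm(1, 23, 2)), sample = p$sample,
        stringsAsFactors = FALSE)
      onVar <- length(offs) > 0 && (p$start + offs[1] - 1L) %in% varPos
      trRows[[length(trRows) + 1L]] <- data.frame(
        sequence = p$sequence, isoform = p$isoform,
        expected_class = p$label,
        expected_phospho_on_variant = onVar,
        expected_phospho_localized = onVar && length(probs) && probs[1] >= 0.99,
        stringsAsFactors = FALSE)
    }
    list(evidence = do.call(rbind, evRows), truth = do.call(rbind, trRows))
  })
  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ev <- file.path(outDir, "evidence.tsv")
    tru <- file.path(outDir, "evidence_truth.tsv")
    write.table(res$evidence, ev, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$truth, tru, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(evidence = ev, truth = tru)
  }
  c(res, list(paths = paths))
}

#' Generate quantitative matrices, interaction and drug tables
#'
#' Produces (i) a log2 protein matrix and a phosphosite matrix linked to
#' parent proteins, with a recorded fraction of features shifted in group R
#' by \code{effectSD} noise SDs; (ii) an interaction table with evidence
#' counts 1-4, a non-human contaminant fraction, self loops and duplicate
#' rows, plus a truth column marking rows the filter cascade must drop; and
#' (iii) a drug table with known in-network/out-of-network target mixes.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param seed RNG seed.
#' @param outDir optional output directory.
#' @return list(sites, proteins, parent, groups, spiked, interactions,
#'   drugs, seeds, expectedEdges, expectedDegrees, paths).
#' @export
makeQuantNetwork <- function(spec = fixtureSpec(), seed = 1L, outDir = NULL) {
  res <- withSeed(seed, {
    n <- as.integer(spec$nFeatures)
    m <- as.integer(spec$nPerGroup)
    groups <- rep(c("R", "S"), each = m)
    samples <- paste0(groups, rep(seq_len(m), 2))
    prot <- matrix(rnorm(n * 2 * m, mean = 25, sd = spec$noiseSD),
                   nrow = n, dimnames = list(sprintf("P%04d", seq_len(n)), samples))
    nSpike <- ceiling(spec$spikeFraction * n)
    spiked <- sort(sample(n, nSpike))
    prot[spiked, groups == "R"] <- prot[spiked, groups == "R"] +
      spec$effectSD * spec$noiseSD
    # phosphosites: one per a subset of proteins, offset + own noise
    siteIdx <- sort(sample(n, max(10L, n %/% 2L)))
    parent <- rownames(prot)[siteIdx]
    sites <- prot[siteIdx, , drop = FALSE] +
      matrix(rnorm(length(siteIdx) * 2 * m, 2, spec$noiseSD / 2),
             nrow = length(siteIdx))
    rownames(sites) <- sprintf("%s_S%d", parent, seq_along(parent))

    nodes <- sprintf("N%02d", seq_len(spec$nNodes))
    pairs <- t(combn(nodes, 2))
    pick <- runif(nrow(pairs)) < spec$edgeProb
    inter <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                        stringsAsFactors = FALSE)
    inter$organism_a <- "9606"
    inter$organism_b <- ifelse(runif(nrow(inter)) < spec$nonHumanFraction,
                               "10090", "9606")
    inter$evidence_count <- sample(1:4, nrow(inter), replace = TRUE)
    loops <- data.frame(a = sample(nodes, 2), b = NA, organism_a = "9606",
                        organism_b = "9606",
                        evidence_count = sample(2:4, 2, replace = TRUE),
                        stringsAsFactors = FALSE)
    loops$b <- loops$a
    dup <- inter[sample(nrow(inter), min(3L, nrow(inter))), c("b", "a", "organism_b",
                                                              "organism_a", "evidence_count")]
    names(dup) <- c("a", "b", "organism_a", "organism_b", "evidence_count")
    interactions <- rbind(inter, loops, dup)
    interactions$keep <- interactions$organism_a == "9606" &
      interactions$organism_b == "9606" &
      interactions$evidence_count >= 2 & interactions$a != interactions$b

    # expected simple graph, computed with plain table arithmetic
    keptRows <- interactions[interactions$keep, , drop = FALSE]
    key <- ifelse(keptRows$a < keptRows$b, paste(keptRows$a, keptRows$b),
                  paste(keptRows$b, keptRows$a))
    edges <- unique(key)
    expectedEdges <- do.call(rbind, strsplit(edges, " "))
    degTab <- table(c(expectedEdges))
    expectedDegrees <- setNames(as.integer(degTab), names(degTab))

    inNet <- names(expectedDegrees)
    drugs <- list()
    for (d in seq_len(spec$nDrugs)) {
      nt <- sample(seq_len(max(1L, spec$maxTargets)), 1)
      nIn <- sample(0:nt, 1)
      tgt <- c(if (nIn > 0 && length(inNet)) sample(inNet, min(nIn, length(inNet))),
               if (nt - nIn > 0) sprintf("X%02d_%d", d, seq_len(nt - nIn)))
      drugs[[d]] <- data.frame(drug = sprintf("drug%02d", d), target = tgt,
                               organism = if (runif(1) < 0.9) "9606" else "10090",
                               stringsAsFactors = FALSE)
    }
    drugs <- do.call(rbind, drugs)
    list(sites = sites, proteins = prot, parent = parent, groups = groups,
         spiked = rownames(prot)[spiked], interactions = interactions,
         drugs = drugs, seeds = nodes, expectedEdges = expectedEdges,
         expectedDegrees = expectedDegrees)
  })
  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pr <- file.path(outDir, "proteins.tsv")
    write.table(data.frame(feature = rownames(res$proteins), res$proteins,
                           check.names = FALSE),
                pr, sep = "\t", quote = FALSE, row.names = FALSE)
    st <- file.path(outDir, "sites.tsv")
    write.table(data.frame(feature = rownames(res$sites), parent = res$parent,
                           res$sites, check.names = FALSE),
                st, sep = "\t", quote = FALSE, row.names = FALSE)
    it <- file.path(outDir, "interactions.tsv")
    write.table(res$interactions, it, sep = "\t", quote = FALSE, row.names = FALSE)
    dr <- file.path(outDir, "drugs.tsv")
    write.table(res$drugs, dr, sep = "\t", quote = FALSE, row.names = FALSE)
    sd <- file.path(outDir, "seeds.txt")
    writeLines(res$seeds, sd)
    tru <- file.path(outDir, "spiked_truth.txt")
    writeLines(res$spiked, tru)
    paths <- c(proteins = pr, sites = st, interactions = it, drugs = dr,
               seeds = sd, spiked = tru)
  }
  c(res, list(paths = paths))
}
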