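# Variant protein database construction: CDS extraction, injection,
# translation, naming and FASTA assembly.

test_that("extractCdsSequence handles strand, splicing and phase", {
  g <- toyGenome(chr1 = "ATGAAACGTTAG")
  expect_identical(extractCdsSequence(g, toyModel("chr1", 1, 12)),
                   "ATGAAACGTTAG")
  # minus strand: genomic forward CTAACGTTTCAT reverse-complements back
  g2 <- toyGenome(chr1 = "CTAACGTTTCAT")
  expect_identical(extractCdsSequence(g2, toyModel("chr1", 1, 12, strand = "-")),
                   "ATGAAACGTTAG")
  # two plus-strand exons with an intron between them
  g3 <- toyGenome(chr1 = "ATGAAAgggttCGTTAG")
  expect_identical(
    extractCdsSequence(g3, toyModel("chr1", c(1, 12), c(6, 17))),
    "ATGAAACGTTAG")
  # phase trimming drops leading bases
  m <- toyModel("chr1", 1, 12, phase = 2L)
  expect_identical(extractCdsSequence(g, m), "GAAACGTTAG")
  # error surfaces
  expect_error(extractCdsSequence(g, toyModel("chrX", 1, 12)), "chromosome")
  expect_error(extractCdsSequence(g, toyModel("chr1", 1, 40)), "bounds")
})

test_that("injectVariants applies substitutions with strand complementation", {
  m <- toyModel("chr1", 1, 9)
  v <- data.frame(chrom = "chr1", pos = 4, ref = "A", alt = "C",
                  zygosity = "homozygous", sample = "S1")
  expect_identical(injectVariants("ATGAAACGT", m, v)$cds, "ATGCAACGT")
  # empty variant list is the identity
  expect_identical(injectVariants("ATGAAACGT", m, v[0, ])$cds, "ATGAAACGT")
  # minus strand: genomic T>G at position 6 maps to transcript base 4, A>C
  mm <- toyModel("chr1", 1, 9, strand = "-")
  cdsMinus <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGAAACGT")))
  gm <- toyGenome(chr1 = cdsMinus)
  cds <- extractCdsSequence(gm, mm)
  expect_identical(cds, "ATGAAACGT")
  v2 <- data.frame(chrom = "chr1", pos = 6, ref = "T", alt = "G",
                   zygosity = "homozygous", sample = "S1")
  res <- injectVariants(cds, mm, v2)
  expect_identical(res$cds, "ATGCAACGT")
  expect_identical(res$applied$txRef, "A")
  expect_identical(res$applied$txAlt, "C")
  # allele mismatch is logged, not applied
  v3 <- data.frame(chrom = "chr1", pos = 4, ref = "G", alt = "C",
                   zygosity = "homozygous", sample = "S1")
  res3 <- injectVariants("ATGAAACGT", m, v3)
  expect_identical(res3$cds, "ATGAAACGT")
  expect_match(res3$skipped$reason, "mismatch")
  # overlapping variants are rejected outright
  v4 <- data.frame(chrom = "chr1", pos = c(4, 4), ref = c("A", "A"),
                   alt = c("C", "G"), zygosity = "homozygous", sample = "S1")
  expect_error(injectVariants("ATGAAACGT", m, v4), "overlap")
})

test_that("translateCds truncates at the first stop and drops partial codons", {
  expect_identical(translateCds("ATGAAACGTTAG"), "MKR")
  expect_identical(translateCds("ATGTAGAAACCC"), "M")
  expect_identical(translateCds("ATGAAACG"), "MK")
  expect_identical(translateCds("ATGNAAAAA"), "MXK")
  expect_error(translateCds("AT"), "codon")
})

test_that("protein variant naming follows field nomenclature", {
  # substitution
  ref <- paste(rep("A", 40), collapse = "")
  alt <- ref; substr(alt, 31, 31) <- "I"
  ref2 <- ref; substr(ref2, 31, 31) <- "F"
  expect_identical(nameProteinVariant(ref2, alt)$name, "F31I")
  # stop gain truncates the alternate protein at residue 61
  refLong <- paste(rep("E", 80), collapse = "")
  expect_identical(nameProteinVariant(refLong, substr(refLong, 1, 60))$name,
                   "E61X")
  # frameshift: changed residue 110 -> R, new stop 24 residues downstream
  refP <- paste(rep("V", 140), collapse = "")
  altP <- paste0(substr(refP, 1, 109), "R",
                 paste(rep("G", 22), collapse = ""))
  expect_identical(nameProteinVariant(refP, altP, frameshift = TRUE)$name,
                   "V110RfsX24")
  # synonymous at protein level
  nm <- nameProteinVariant("MKR", "MKR")
  expect_identical(nm$name, "")
  expect_true(nm$synonymous)
})

test_that("buildDatabases writes one alternate entry per changed transcript", {
  # three transcripts; one carries a nonsynonymous SNV, one a synonymous SNV
  g <- toyGenome(chr1 = paste0("ATGAAACGTTAG", "ATGTCTCCGTAG", "ATGGGATTTTAG"))
  models <- list(
    t1 = toyModel("chr1", 1, 12, tid = "t1", gid = "g1"),
    t2 = toyModel("chr1", 13, 24, tid = "t2", gid = "g2"),
    t3 = toyModel("chr1", 25, 36, tid = "t3", gid = "g3"))
  vars <- data.frame(
    chrom = "chr1",
    pos = c(5, 24),          # t1 codon2 A(A)A->ACA (K->T); t3... pos 24 = t2 last base
    ref = c("A", "G"), alt = c("C", "A"),
    zygosity = "homozygous", sample = "S1")
  # pos 24 is the third base of t2's stop codon TAG -> TAA (synonymous stop)
  db <- buildDatabases(g, models, list(S1 = vars))
  expect_length(referenceDB(db), 3L)
  expect_length(alternateDB(db)$S1, 1L)
  expect_match(names(alternateDB(db)$S1), "^t1\\|g1\\|S1\\|K2T$")
  # FASTA round trip with 60-column wrapping and header grammar
  out <- tempfile()
  writeDatabases(db, out)
  ref <- Biostrings::readAAStringSet(file.path(out, "reference.fasta"))
  expect_length(ref, 3L)
  expect_true(all(grepl("^t[0-9]+\\|g[0-9]+\\|reference\\|$", names(ref))))
})

test_that("two nonsynonymous SNVs on one transcript give one combined entry", {
  g <- toyGenome(chr1 = "ATGAAACGTACGGCATAG")
  models <- list(t1 = toyModel("chr1", 1, 18))
  vars <- data.frame(chrom = "chr1", pos = c(4, 10), ref = c("A", "A"),
                     alt = c("C", "T"), zygosity = "heterozygous",
                     sample = "S1")
  db <- buildDatabases(g, models, list(S1 = vars))
  expect_length(alternateDB(db)$S1, 1L)
  pair <- isoformPairs(db)$S1$t1
  expect_identical(sort(variantNames(pair)), c("K2Q", "T4S"))
  expect_identical(referenceProtein(pair), "MKRTA")
  expect_identical(alternateProtein(pair), "MQRSA")
})

test_that("start-codon disruption yields no alternate entry, with a log", {
  g <- toyGenome(chr1 = "ATGAAACGTTAG")
  models <- list(t1 = toyModel("chr1", 1, 12))
  vars <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "C",
                     zygosity = "homozygous", sample = "S1")
  db <- buildDatabases(g, models, list(S1 = vars))
  expect_length(alternateDB(db)$S1, 0L)
  expect_match(skippedVariants(db)$reason, "start codon")
})

test_that("minus-strand extraction+translation equals hand reverse complement", {
  spec <- fixtureSpec(nTranscripts = 6L, fractionMinus = 0.5)
  ga <- makeGenomeAnnotation(spec, seed = 11)
  for (m in ga$models) {
    if (as.character(GenomicRanges::strand(m))[1] != "-") next
    cds <- extractCdsSequence(ga$genome, m)
    chrom <- as.character(GenomicRanges::seqnames(m))[1]
    parts <- vapply(seq_along(m), function(i)
      substr(as.character(ga$genome[[chrom]]),
             GenomicRanges::start(m)[i], GenomicRanges::end(m)[i]),
      character(1))
    byHand <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste(parts[order(GenomicRanges::start(m))],
                                  collapse = ""))))
    expect_identical(translateCds(cds), translateCds(byHand))
  }
})

test_that("substitutions never change protein length; frameshifts are named fsX", {
  spec <- fixtureSpec(nTranscripts = 10L, nSubstitutions = 20L,
                      nInsertions = 3L, nDeletions = 3L)
  ga <- makeGenomeAnnotation(spec, seed = 21)
  mv <- makeVariants(spec, ga$genome, ga$models, seed = 22)
  db <- buildDatabases(ga$genome, ga$models, list(S1 = mv$variants))
  for (pair in isoformPairs(db)$S1) {
    vt <- variantTable(pair)
    subs <- vt[nchar(vt$ref) == 1 & nchar(vt$alt) == 1 & !vt$synonymous, ]
    if (nrow(subs) && !any(grepl("X$|fsX", vt$name))) {
      expect_identical(nchar(referenceProtein(pair)),
                       nchar(alternateProtein(pair)))
    }
    fs <- vt[abs(nchar(vt$ref) - nchar(vt$alt)) %% 3 != 0, ]
    for (nm in fs$name[!fs$synonymous])
      expect_match(nm, "fsX[0-9]+$")
  }
})
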