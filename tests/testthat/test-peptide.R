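# In-silico digestion, peptide classification, phospho flagging and
# coverage summaries.

test_that("digestProtein enumerates tryptic peptides with missed cleavages", {
  d0 <- digestProtein("MKRASTK", maxMissedCleavages = 0, minLength = 1,
                      maxLength = 50)
  expect_setequal(d0$peptide, c("MK", "R", "ASTK"))
  d2 <- digestProtein("MKRASTK", maxMissedCleavages = 2, minLength = 1,
                      maxLength = 50)
  expect_setequal(d2$peptide,
                  c("MK", "R", "ASTK", "MKR", "RASTK", "MKRASTK"))
  # trypsin/P: cleavage before proline is NOT suppressed
  dP <- digestProtein("MKPR", maxMissedCleavages = 0, minLength = 1,
                      maxLength = 50)
  expect_setequal(dP$peptide, c("MK", "PR"))
  # coordinates are 1-based inclusive
  expect_identical(d0[d0$peptide == "ASTK", c("start", "end")],
                   data.frame(start = 4L, end = 7L, row.names = 3L))
  # length bounds filter
  d7 <- digestProtein("MKRASTK", maxMissedCleavages = 2)
  expect_setequal(d7$peptide, "MKRASTK")
})

test_that("digestProtein matches brute-force enumeration over cleavage points", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    prot <- paste(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    mc <- sample(0:2, 1)
    got <- digestProtein(prot, mc, minLength = 1, maxLength = 100)
    # brute force: all substrings whose context is tryptic and whose internal
    # missed cleavages are within bounds
    want <- list()
    n <- nchar(prot)
    for (s in 1:n) for (e in s:n) {
      aav <- strsplit(substr(prot, s, e), "")[[1]]
      prevOk <- s == 1 || substr(prot, s - 1, s - 1) %in% c("K", "R")
      endOk <- e == n || aav[length(aav)] %in% c("K", "R")
      internal <- sum(aav[-length(aav)] %in% c("K", "R"))
      if (prevOk && endOk && internal <= mc)
        want[[length(want) + 1L]] <- c(s, e)
    }
    wantKey <- sort(vapply(want, paste, character(1), collapse = "-"))
    gotKey <- sort(paste(got$start, got$end, sep = "-"))
    expect_identical(gotKey, unique(wantKey))
  }
})

test_that("classifyPeptide separates reference, alternate and unspecific", {
  # MKRSSTAAAK with S4L-style change -> MKRSLTAAAK at residue 5
  pair <- toyPair(c("ATG", "AAA", "CGT", "TCT", "TCA", "ACG", "GCA", "GCA",
                    "GCA", "AAA", "TAG"), altCodon = "TTA", codonIndex = 5)
  expect_identical(variantNames(pair), "S5L")
  params <- digestParams(maxMissedCleavages = 2, minLength = 3, maxLength = 50)
  refPep <- "SSTAAAK"   # covers residue 5 with the reference S
  altPep <- "SLTAAAK"   # covers residue 5 with the alternate L
  unspec <- "MKR"       # upstream of the variant, identical in both
  expect_identical(classifyPeptide(refPep, pair, params)$class, "reference")
  expect_identical(classifyPeptide(altPep, pair, params)$class, "alternate")
  expect_identical(classifyPeptide(unspec, pair, params)$class, "unspecific")
  expect_true(is.na(classifyPeptide("WWWWW", pair, params)$class))
})

test_that("flagPhospho maps offsets onto variant positions with localization", {
  pair <- toyPair(c("ATG", "AAA", "CGT", "TCT", "TCA", "ACG", "GCA", "GCA",
                    "GCA", "AAA", "TAG"), altCodon = "TTA", codonIndex = 5)
  params <- digestParams(maxMissedCleavages = 2, minLength = 3, maxLength = 50)
  cl <- classifyPeptide("SSTAAAK", pair, params)  # starts at residue 4
  # offset 2 = protein residue 5 = the variant S, well localized
  fl <- flagPhospho(cl, pair, 2L, 0.995)
  expect_true(fl$phosphoOnVariant)
  expect_true(fl$phosphoLocalized)
  # same site, poorly localized
  fl2 <- flagPhospho(cl, pair, 2L, 0.5)
  expect_true(fl2$phosphoOnVariant)
  expect_false(fl2$phosphoLocalized)
  # phospho elsewhere on the peptide: flagged phosphorylated, not on variant
  fl3 <- flagPhospho(cl, pair, 1L, 0.999)
  expect_false(fl3$phosphoOnVariant)
  expect_true(fl3$phosphorylated)
  # offsets outside the peptide are an input error
  expect_error(flagPhospho(cl, pair, 99L, 1), "outside")
})

test_that("summarizeCoverage collapses classes with variant precedence", {
  cls <- data.frame(
    isoform = c("a", "a", "b", "c", "c", "d"),
    class = c("reference", "alternate", "unspecific", "alternate",
              "unspecific", "reference"))
  cov <- summarizeCoverage(cls, isoforms = c("a", "b", "c", "d", "e"))
  got <- setNames(cov$coverage_class, cov$isoform)
  expect_identical(got[["a"]], "reference_and_alternate")
  expect_identical(got[["b"]], "unspecific")
  expect_identical(got[["c"]], "alternate_only")
  expect_identical(got[["d"]], "reference_only")
  expect_identical(got[["e"]], "none")
  # exactly one class per isoform
  expect_identical(anyDuplicated(cov$isoform), 0L)
})

test_that("classifyPeptide agrees with the substring+overlap oracle", {
  spec <- fixtureSpec(nTranscripts = 12L, nSubstitutions = 18L,
                      nInsertions = 2L, nDeletions = 2L)
  ga <- makeGenomeAnnotation(spec, seed = 41)
  mv <- makeVariants(spec, ga$genome, ga$models, seed = 42)
  db <- buildDatabases(ga$genome, ga$models, list(S1 = mv$variants))
  params <- digestParams()
  for (pair in isoformPairs(db)$S1) {
    dg <- proteovar:::pairDigests(pair, params)
    peps <- unique(c(dg$ref$peptide, dg$alt$peptide))
    refVar <- proteovar:::variantPositions(pair, "ref")
    altVar <- proteovar:::variantPositions(pair, "alt")
    for (pep in peps) {
      got <- classifyPeptide(pep, pair, params, dg)$class
      want <- classifyOracle(pep, referenceProtein(pair),
                             alternateProtein(pair), refVar, altVar)
      expect_identical(got, want)
    }
  }
})

test_that("alternate-classified peptides never occur in the reference digest", {
  spec <- fixtureSpec(nTranscripts = 10L, nSubstitutions = 15L,
                      nInsertions = 1L, nDeletions = 1L)
  ga <- makeGenomeAnnotation(spec, seed = 51)
  mv <- makeVariants(spec, ga$genome, ga$models, seed = 52)
  db <- buildDatabases(ga$genome, ga$models, list(S1 = mv$variants))
  for (pair in isoformPairs(db)$S1) {
    dg <- proteovar:::pairDigests(pair, digestParams())
    for (pep in unique(dg$alt$peptide)) {
      cl <- classifyPeptide(pep, pair, digests = dg)
      if (identical(cl$class, "alternate"))
        expect_false(pep %in% dg$ref$peptide)
    }
  }
})

test_that("generated evidence labels round-trip through classification", {
  spec <- fixtureSpec(nTranscripts = 10L, nObservedPeptides = 40L)
  ga <- makeGenomeAnnotation(spec, seed = 61)
  mv <- makeVariants(spec, ga$genome, ga$models, seed = 62)
  db <- buildDatabases(ga$genome, ga$models, list(S1 = mv$variants))
  ev <- makeEvidence(spec, db, seed = 63)
  out <- classifyEvidence(ev$evidence, db)
  key <- paste(out$classified$sequence, out$classified$isoform)
  tk <- paste(ev$truth$sequence, ev$truth$isoform)
  m <- match(tk, key)
  expect_false(anyNA(m))
  expect_identical(out$classified$class[m], ev$truth$expected_class)
  expect_identical(out$classified$phospho_on_variant[m],
                   ev$truth$expected_phospho_on_variant)
  expect_identical(out$classified$phospho_localized[m],
                   ev$truth$expected_phospho_localized)
})

test_that("readEvidence parses both dialects", {
  # MaxQuant dialect with a probability string
  mq <- tempfile(fileext = ".txt")
  writeLines(c("Sequence\tProteins\tPhospho (STY) Probabilities\tIntensity\tExperiment",
               "AASTK\tt01|S1\tAAS(0.98)T(0.02)K\t1000\tS1"), mq)
  ev <- readEvidence(mq)
  expect_identical(ev$sequence, "AASTK")
  expect_identical(ev$phospho_offsets, "3;4")
  expect_identical(ev$phospho_probs, "0.98;0.02")
  # minimal dialect
  mn <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tproteins\tphospho_offsets\tphospho_probs",
               "AASTK\tt01|S1\t3\t0.99"), mn)
  ev2 <- readEvidence(mn)
  expect_identical(ev2$sequence, "AASTK")
  expect_identical(as.character(ev2$phospho_offsets), "3")
})
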