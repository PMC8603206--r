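# In-silico tryptic digestion and classification of observed MS peptides
# against reference/alternate isoforms.

#' In-silico tryptic digestion (trypsin/P)
#'
#' Cleaves C-terminal to every K or R, including before proline (the
#' trypsin/P convention), and enumerates all peptides with up to
#' \code{maxMissedCleavages} internal uncleaved sites, filtered by length.
#'
#' @param protein amino acid string.
#' @param maxMissedCleavages maximum internal K/R sites per peptide
#'   (default 2, the usual search-engine setting).
#' @param minLength,maxLength peptide length bounds (defaults 7 and 52).
#' @return data.frame(peptide, start, end, missed) with 1-based inclusive
#'   coordinates on the protein.
#' @examples
#' digestProtein("MKRASTK", maxMissedCleavages = 0, minLength = 1)
#' @export
digestProtein <- function(protein, maxMissedCleavages = 2L,
                          minLength = 7L, maxLength = 52L) {
  assertThat(nzchar(protein), "protein must be nonempty")
  assertThat(maxMissedCleavages >= 0L, "maxMissedCleavages must be >= 0")
  assertThat(minLength <= maxLength, "minLength must be <= maxLength")
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cuts <- which(aa %in% c("K", "R"))        # cleave after these positions
  bounds <- unique(c(0L, cuts[cuts < n], n))  # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nf <- length(starts)
  out <- list()
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + maxMissedCleavages)
    for (j in i:jmax) {
      len <- ends[j] - starts[i] + 1L
      if (len < minLength || len > maxLength) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(protein, starts[i], ends[j]),
        start = starts[i], end = ends[j], missed = j - i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  unique(do.call(rbind, out))
}

#' Digestion parameters
#'
#' @param maxMissedCleavages,minLength,maxLength see
#'   \code{\link{digestProtein}}.
#' @return list of parameters.
#' @export
digestParams <- function(maxMissedCleavages = 2L, minLength = 7L,
                         maxLength = 52L) {
  list(maxMissedCleavages = as.integer(maxMissedCleavages),
       minLength = as.integer(minLength), maxLength = as.integer(maxLength))
}

# all variant amino acid positions on the reference / alternate protein
variantPositions <- function(pair, side = c("ref", "alt")) {
  side <- match.arg(side)
  vt <- variantTable(pair)
  vt <- vt[!vt$synonymous, , drop = FALSE]
  if (!nrow(vt)) return(integer(0))
  a <- if (side == "ref") vt$refAaStart else vt$altAaStart
  b <- if (side == "ref") vt$refAaEnd else vt$altAaEnd
  sort(unique(unlist(Map(seq, a, b))))
}

#' Classify an observed peptide against an isoform pair
#'
#' Matches the peptide sequence exactly against the in-silico digests of the
#' reference and alternate proteins and classifies it as
#' \code{"alternate"} (matches an alternate peptide whose span covers a
#' variant position), \code{"reference"} (matches a reference peptide
#' covering a variant position) or \code{"unspecific"} (matches either digest
#' without covering a variant, or covers the variant identically on both
#' sequences). Peptides matching neither digest return class \code{NA} and
#' are excluded from coverage summaries.
#'
#' @param sequence observed peptide sequence.
#' @param pair a \code{\link{ProteinIsoformPair-class}}.
#' @param params \code{\link{digestParams}}.
#' @param digests optional precomputed list(ref =, alt =) of
#'   \code{\link{digestProtein}} tables, to avoid re-digestion in loops.
#' @return list(class, overlappedVariant, refHit, altHit) where the hits are
#'   single-row digest tables (or NULL).
#' @export
classifyPeptide <- function(sequence, pair, params = digestParams(),
                            digests = NULL) {
  if (is.null(digests)) digests <- pairDigests(pair, params)
  refHit <- digests$ref[digests$ref$peptide == sequence, , drop = FALSE]
  altHit <- digests$alt[digests$alt$peptide == sequence, , drop = FALSE]
  refVar <- variantPositions(pair, "ref")
  altVar <- variantPositions(pair, "alt")
  coversRef <- nrow(refHit) > 0 &&
    any(vapply(seq_len(nrow(refHit)), function(i)
      any(refVar >= refHit$start[i] & refVar <= refHit$end[i]), logical(1)))
  coversAlt <- nrow(altHit) > 0 &&
    any(vapply(seq_len(nrow(altHit)), function(i)
      any(altVar >= altHit$start[i] & altVar <= altHit$end[i]), logical(1)))

  overlapped <- NA_character_
  if (coversAlt && coversRef) {
    cls <- "unspecific"           # variant invisible at the peptide level
  } else if (coversAlt) {
    cls <- "alternate"
    overlapped <- whichVariant(pair, altHit, "alt")
  } else if (coversRef) {
    cls <- "reference"
    overlapped <- whichVariant(pair, refHit, "ref")
  } else if (nrow(refHit) || nrow(altHit)) {
    cls <- "unspecific"
  } else {
    cls <- NA_character_
  }
  list(class = cls, overlappedVariant = overlapped,
       refHit = if (nrow(refHit)) refHit[1, , drop = FALSE] else NULL,
       altHit = if (nrow(altHit)) altHit[1, , drop = FALSE] else NULL)
}

pairDigests <- function(pair, params = digestParams()) {
  list(
    ref = digestProtein(referenceProtein(pair), params$maxMissedCleavages,
                        params$minLength, params$maxLength),
    alt = digestProtein(alternateProtein(pair), params$maxMissedCleavages,
                        params$minLength, params$maxLength)
  )
}

whichVariant <- function(pair, hit, side) {
  vt <- variantTable(pair)
  vt <- vt[!vt$synonymous, , drop = FALSE]
  if (!nrow(vt)) return(NA_character_)
  a <- if (side == "ref") vt$refAaStart else vt$altAaStart
  b <- if (side == "ref") vt$refAaEnd else vt$altAaEnd
  ov <- which(a <= hit$end[1] & b >= hit$start[1])
  if (!length(ov)) return(NA_character_)
  paste(vt$name[ov], collapse = ";")
}

#' Flag phosphorylation on a classified peptide
#'
#' Maps each phospho offset (within the peptide) onto the matched isoform
#' coordinates and flags whether any phosphorylation sits exactly on a
#' variant amino acid position, and whether that site is localized
#' (localization probability >= 0.99).
#'
#' @param classified result of \code{\link{classifyPeptide}}.
#' @param pair the \code{\link{ProteinIsoformPair-class}} used.
#' @param phosphoOffsets integer offsets of phosphosites within the peptide
#'   (1-based).
#' @param localizationProbs matching localization probabilities in [0, 1].
#' @param localizationThreshold probability above which a site counts as
#'   localized (default 0.99).
#' @return list(phosphoOnVariant, phosphoLocalized, phosphorylated).
#' @export
flagPhospho <- function(classified, pair, phosphoOffsets,
                        localizationProbs = rep(1, length(phosphoOffsets)),
                        localizationThreshold = 0.99) {
  if (!length(phosphoOffsets))
    return(list(phosphoOnVariant = FALSE, phosphoLocalized = FALSE,
                phosphorylated = FALSE))
  assertThat(all(localizationProbs >= 0 & localizationProbs <= 1),
             "localization probabilities must lie in [0, 1]")
  hit <- switch(classified$class,
                alternate = classified$altHit,
                reference = classified$refHit,
                if (!is.null(classified$refHit)) classified$refHit
                else classified$altHit)
  if (is.null(hit))
    return(list(phosphoOnVariant = FALSE, phosphoLocalized = FALSE,
                phosphorylated = TRUE))
  pepLen <- hit$end[1] - hit$start[1] + 1L
  assertThat(all(phosphoOffsets >= 1L & phosphoOffsets <= pepLen),
             "phospho offset outside peptide bounds")
  side <- if (identical(classified$class, "alternate")) "alt" else "ref"
  varPos <- variantPositions(pair, side)
  absPos <- hit$start[1] + phosphoOffsets - 1L
  onVar <- absPos %in% varPos
  list(
    phosphoOnVariant = any(onVar),
    phosphoLocalized = any(onVar & localizationProbs >= localizationThreshold),
    phosphorylated = TRUE
  )
}

#' Classify a table of observed peptides against a variant database
#'
#' Driver over \code{\link{classifyPeptide}}/\code{\link{flagPhospho}}: each
#' evidence row is classified against every isoform pair it can match
#' (one output row per peptide-isoform combination).
#'
#' @param evidence data.frame as returned by \code{\link{readEvidence}}:
#'   columns \code{sequence}, optional \code{proteins} (semicolon-joined
#'   isoform restriction), \code{phospho_offsets} / \code{phospho_probs}
#'   (semicolon-joined numbers), \code{intensity}, \code{sample}.
#' @param db a \code{\link{VariantDB-class}}.
#' @param params \code{\link{digestParams}}.
#' @return list(classified = data.frame, unassigned = data.frame).
#' @export
classifyEvidence <- function(evidence, db, params = digestParams()) {
  allPairs <- list()
  for (s in names(isoformPairs(db)))
    for (pair in isoformPairs(db)[[s]])
      allPairs[[sprintf("%s|%s", pair@transcriptId, s)]] <- pair
  digests <- lapply(allPairs, pairDigests, params = params)

  rows <- list(); un <- list()
  for (i in seq_len(nrow(evidence))) {
    ev <- evidence[i, , drop = FALSE]
    restrict <- if (!is.null(ev$proteins) && nzchar(ev$proteins) && !is.na(ev$proteins))
      strsplit(ev$proteins, ";")[[1]] else names(allPairs)
    offs <- parseNums(ev$phospho_offsets)
    probs <- parseNums(ev$phospho_probs)
    if (length(probs) < length(offs))
      probs <- c(probs, rep(1, length(offs) - length(probs)))
    matched <- FALSE
    for (iso in intersect(restrict, names(allPairs))) {
      pair <- allPairs[[iso]]
      cl <- classifyPeptide(ev$sequence, pair, params, digests[[iso]])
      if (is.na(cl$class)) next
      matched <- TRUE
      fl <- flagPhospho(cl, pair, as.integer(offs), probs)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = ev$sequence, isoform = iso,
        transcript_id = pair@transcriptId, gene_id = pair@geneId,
        sample = if (!is.null(ev$sample)) ev$sample else pair@sample,
        class = cl$class, overlapped_variant = cl$overlappedVariant,
        phosphorylated = fl$phosphorylated,
        phospho_on_variant = fl$phosphoOnVariant,
        phospho_localized = fl$phosphoLocalized,
        intensity = if (!is.null(ev$intensity)) ev$intensity else NA_real_,
        stringsAsFactors = FALSE)
    }
    if (!matched) un[[length(un) + 1L]] <- ev
  }
  classified <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), isoform = character(0),
               class = character(0))
  unassigned <- if (length(un)) do.call(rbind, un) else evidence[0, , drop = FALSE]
  list(classified = classified, unassigned = unassigned)
}

parseNums <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(as.character(x))) return(numeric(0))
  as.numeric(strsplit(as.character(x), ";")[[1]])
}

#' Summarize peptide coverage per isoform
#'
#' Collapses the classified peptides of each isoform into a single coverage
#' class: \code{reference_and_alternate}, \code{reference_only},
#' \code{alternate_only}, \code{unspecific} (only unspecific peptides) or
#' \code{none}.
#'
#' @param classified the classification table from
#'   \code{\link{classifyEvidence}} (columns \code{isoform}, \code{class}).
#' @param isoforms optional character vector of all isoform ids, so isoforms
#'   without any peptide are reported as \code{"none"}.
#' @return data.frame(isoform, coverage_class).
#' @export
summarizeCoverage <- function(classified, isoforms = NULL) {
  ids <- unique(c(classified$isoform, isoforms))
  cov <- vapply(ids, function(id) {
    cls <- classified$class[classified$isoform == id]
    hasRef <- "reference" %in% cls
    hasAlt <- "alternate" %in% cls
    if (hasRef && hasAlt) "reference_and_alternate"
    else if (hasRef) "reference_only"
    else if (hasAlt) "alternate_only"
    else if (length(cls)) "unspecific"
    else "none"
  }, character(1))
  data.frame(isoform = ids, coverage_class = unname(cov),
             stringsAsFactors = FALSE)
}

#' Read MS peptide evidence
#'
#' Accepts either a MaxQuant-dialect tab-separated table (columns
#' \code{Sequence}, \code{Proteins}, \code{Phospho (STY) Probabilities},
#' \code{Intensity}, \code{Experiment}) or a minimal table with columns
#' \code{sequence}, \code{proteins}, \code{phospho_offsets},
#' \code{phospho_probs}, \code{intensity}, \code{sample}. The MaxQuant
#' probability string notation \code{"AAS(0.98)TK"} is parsed into offsets
#' and probabilities.
#'
#' @param path tab-separated file.
#' @return normalized data.frame for \code{\link{classifyEvidence}}.
#' @export
readEvidence <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("Sequence" %in% names(tab)) {
    probCol <- grep("Probabilities$", names(tab), value = TRUE)
    parsed <- lapply(seq_len(nrow(tab)), function(i) {
      if (length(probCol) && nzchar(tab[[probCol[1]]][i]))
        parseProbString(tab[[probCol[1]]][i])
      else list(offsets = integer(0), probs = numeric(0))
    })
    data.frame(
      sequence = tab$Sequence,
      proteins = if ("Proteins" %in% names(tab)) tab$Proteins else "",
      phospho_offsets = vapply(parsed, function(p)
        paste(p$offsets, collapse = ";"), character(1)),
      phospho_probs = vapply(parsed, function(p)
        paste(p$probs, collapse = ";"), character(1)),
      intensity = if ("Intensity" %in% names(tab)) tab$Intensity else NA_real_,
      sample = if ("Experiment" %in% names(tab)) tab$Experiment else "sample",
      stringsAsFactors = FALSE)
  } else {
    need <- c("sequence")
    assertThat(all(need %in% names(tab)), "evidence table needs a 'sequence' column")
    for (cn in c("proteins", "phospho_offsets", "phospho_probs"))
      if (!cn %in% names(tab)) tab[[cn]] <- ""
    if (!"intensity" %in% names(tab)) tab$intensity <- NA_real_
    if (!"sample" %in% names(tab)) tab$sample <- "sample"
    tab
  }
}

# "AAS(0.98)T(0.02)K" -> offsets on the bare sequence + probabilities
parseProbString <- function(x) {
  offsets <- integer(0); probs <- numeric(0)
  pos <- 0L; i <- 1L; n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "(") {
      j <- regexpr(")", substr(x, i, n), fixed = TRUE)
      p <- as.numeric(substr(x, i + 1L, i + j - 2L))
      offsets <- c(offsets, pos)
      probs <- c(probs, p)
      i <- i + j
    } else {
      pos <- pos + 1L
      i <- i + 1L
    }
  }
  list(offsets = offsets, probs = probs)
}
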