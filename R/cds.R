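# Coding-sequence extraction, variant injection, translation and
# protein-level variant naming.

#' Extract the spliced coding sequence of a transcript model
#'
#' Concatenates the CDS segments of one transcript in transcription order,
#' reverse-complementing minus-strand models, and trims the coding phase
#' offset from the 5' end.
#'
#' @param genome named \code{DNAStringSet} (one entry per chromosome) or a
#'   named character vector of chromosome sequences.
#' @param model \code{GRanges} of the CDS segments of a single transcript.
#'   All segments must share one chromosome and strand; metadata columns
#'   \code{transcript_id}, \code{gene_id} and \code{phase} (phase of the
#'   first codon, 0/1/2, stored on every row) are expected as produced by
#'   \code{\link{readTranscriptModels}}.
#'
#' @return the coding nucleotide sequence as a character string.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ATGAAACGTTAG"))
#' m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12), strand = "+",
#'                             transcript_id = "t1", gene_id = "g1", phase = 0L)
#' extractCdsSequence(g, m)
#' @export
extractCdsSequence <- function(genome, model) {
  genome <- asGenome(genome)
  chrom <- as.character(seqnames(model))[1]
  assertThat(length(unique(as.character(seqnames(model)))) == 1L,
             "CDS segments of one transcript must share a chromosome")
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  chromSeq <- genome[[chrom]]
  if (max(end(model)) > length(chromSeq) || min(start(model)) < 1L)
    stop("CDS segment beyond chromosome bounds on ", chrom, call. = FALSE)
  model <- sortModel(model)
  parts <- vapply(seq_along(model), function(i) {
    as.character(subseq(chromSeq, start(model)[i], end(model)[i]))
  }, character(1))
  spliced <- paste(parts, collapse = "")
  minus <- as.character(strand(model))[1] == "-"
  if (minus) spliced <- revComp(spliced)
  phase <- modelPhase(model)
  if (phase > 0L) spliced <- substr(spliced, phase + 1L, nchar(spliced))
  spliced
}

asGenome <- function(genome) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  assertThat(!is.null(names(genome)), "genome must be named by chromosome")
  genome
}

sortModel <- function(model) {
  model[order(start(model))]
}

modelPhase <- function(model) {
  ph <- mcols(model)$phase
  if (is.null(ph)) 0L else as.integer(ph[1])
}

# Map a genomic span [pos, pos + refLen - 1] to 1-based coordinates on the
# phase-trimmed spliced transcript. Returns NULL when the span is not fully
# inside a single CDS segment (splice junction or outside the CDS) or falls
# in the phase-trimmed region.
mapToTranscript <- function(model, pos, refLen = 1L) {
  model <- sortModel(model)
  gEnd <- pos + refLen - 1L
  hit <- which(start(model) <= pos & end(model) >= gEnd)
  if (length(hit) != 1L) return(NULL)
  w <- width(model)
  before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
  o1 <- before + (pos - start(model)[hit]) + 1L
  o2 <- o1 + refLen - 1L
  L <- sum(w)
  if (as.character(strand(model))[1] == "-") {
    t1 <- L - o2 + 1L
    t2 <- L - o1 + 1L
  } else {
    t1 <- o1
    t2 <- o2
  }
  phase <- modelPhase(model)
  t1 <- t1 - phase
  t2 <- t2 - phase
  if (t1 < 1L) return(NULL)
  c(t1, t2)
}

#' Inject variants into a coding sequence
#'
#' Applies genomic variants to the spliced, phase-trimmed coding sequence of
#' a transcript. Alleles of minus-strand models are reverse-complemented
#' before injection, and variants are applied in descending transcript
#' coordinate so that insertions and deletions cannot shift the mapped
#' positions of variants applied after them.
#'
#' @param cds coding nucleotide string as returned by
#'   \code{\link{extractCdsSequence}}.
#' @param model the transcript's CDS \code{GRanges} (see
#'   \code{\link{extractCdsSequence}}).
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (VCF conventions, 1-based) and optionally
#'   \code{zygosity} and \code{sample}.
#'
#' @return list with elements \code{cds} (the alternate coding sequence),
#'   \code{applied} (data.frame of applied variants with transcript
#'   coordinates \code{txStart}, \code{txEnd} and transcript-strand alleles
#'   \code{txRef}, \code{txAlt}) and \code{skipped} (data.frame of variants
#'   not applied, with a \code{reason}).
#' @export
injectVariants <- function(cds, model, variants) {
  skipped <- cbind(variants[0, , drop = FALSE], reason = character(0))
  if (is.null(variants) || nrow(variants) == 0L)
    return(list(cds = cds, applied = data.frame(), skipped = skipped))
  chrom <- as.character(seqnames(model))[1]
  minus <- as.character(strand(model))[1] == "-"

  rows <- list(); skip <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    if (v$chrom != chrom) { skip[[length(skip) + 1L]] <- cbind(v, reason = "other chromosome"); next }
    tc <- mapToTranscript(model, v$pos, nchar(v$ref))
    if (is.null(tc)) { skip[[length(skip) + 1L]] <- cbind(v, reason = "outside CDS or splice junction"); next }
    txRef <- if (minus) revComp(v$ref) else v$ref
    txAlt <- if (minus) revComp(v$alt) else v$alt
    if (substr(cds, tc[1], tc[2]) != txRef) {
      skip[[length(skip) + 1L]] <- cbind(v, reason = "reference allele mismatch")
      next
    }
    rows[[length(rows) + 1L]] <- cbind(v, txStart = tc[1], txEnd = tc[2],
                                       txRef = txRef, txAlt = txAlt)
  }
  applied <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (length(skip)) skipped <- do.call(rbind, skip)

  if (nrow(applied)) {
    ir <- IRanges(applied$txStart, applied$txEnd)
    if (any(IRanges::countOverlaps(ir, ir) > 1L))
      stop("overlapping variants on one transcript are not supported", call. = FALSE)
    applied <- applied[order(-applied$txStart), , drop = FALSE]
    for (i in seq_len(nrow(applied))) {
      cds <- paste0(substr(cds, 1L, applied$txStart[i] - 1L),
                    applied$txAlt[i],
                    substr(cds, applied$txEnd[i] + 1L, nchar(cds)))
    }
    applied <- applied[order(applied$txStart), , drop = FALSE]
    rownames(applied) <- NULL
  }
  list(cds = cds, applied = applied, skipped = skipped)
}

#' Translate a coding sequence
#'
#' Standard-code translation starting at the first base and stopping at
#' (excluding) the first stop codon; a trailing incomplete codon is dropped
#' and codons containing ambiguous bases translate to \code{"X"}.
#'
#' @param cds coding nucleotide string, length >= 3.
#' @return amino acid string (possibly empty when the first codon is a stop).
#' @examples
#' translateCds("ATGAAACGTTAG")  # "MKR"
#' @export
translateCds <- function(cds) {
  assertThat(nchar(cds) >= 3L, "coding sequence must be at least one codon long")
  n <- nchar(cds) - nchar(cds) %% 3L
  aa <- as.character(translate(DNAString(substr(cds, 1L, n)),
                               if.fuzzy.codon = "X", no.init.codon = TRUE))
  stop1 <- regexpr("*", aa, fixed = TRUE)
  if (stop1 > 0L) aa <- substr(aa, 1L, stop1 - 1L)
  aa
}

# First index at which two strings differ; NA when one is a prefix of the
# other (or they are identical).
firstDiff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    av <- strsplit(substr(a, 1, n), "")[[1]]
    bv <- strsplit(substr(b, 1, n), "")[[1]]
    d <- which(av != bv)
    if (length(d)) return(d[1])
  }
  NA_integer_
}

#' Name a protein-level variant
#'
#' Produces the field's protein change nomenclature by diffing the reference
#' protein against the protein obtained by injecting a single variant:
#' substitutions give \code{"F31I"}-style names, stop gains \code{"E61X"},
#' and frameshifts \code{"V110RfsX24"} where the trailing count is the number
#' of residues from the changed position to the new stop codon inclusive.
#' In-frame indels are named \code{"<ref><pos>del"} / \code{"<ref><pos>ins<seq>"}.
#'
#' @param refProtein,altProtein full protein strings (single-variant
#'   injection for \code{altProtein}).
#' @param frameshift logical; whether the underlying nucleotide change has
#'   length difference not divisible by 3.
#' @return list with \code{name} (empty string when synonymous) and
#'   \code{synonymous} flag.
#' @export
nameProteinVariant <- function(refProtein, altProtein, frameshift = FALSE) {
  if (identical(refProtein, altProtein))
    return(list(name = "", synonymous = TRUE))
  i <- firstDiff(refProtein, altProtein)
  if (is.na(i)) {
    # one protein is a strict prefix of the other
    if (nchar(altProtein) < nchar(refProtein)) {
      # stop gained at the first changed position (also covers frameshifts
      # whose first shifted codon is already a stop)
      pos <- nchar(altProtein) + 1L
      return(list(name = sprintf("%s%dX", substr(refProtein, pos, pos), pos),
                  synonymous = FALSE))
    }
    # alternate is longer: stop-loss / extension
    pos <- nchar(refProtein) + 1L
    return(list(name = sprintf("X%d%sext", pos, substr(altProtein, pos, pos)),
                synonymous = FALSE))
  }
  refAa <- substr(refProtein, i, i)
  altAa <- substr(altProtein, i, i)
  if (frameshift) {
    k <- nchar(altProtein) - i + 2L  # residues from change to new stop, inclusive
    return(list(name = sprintf("%s%d%sfsX%d", refAa, i, altAa, k),
                synonymous = FALSE))
  }
  if (nchar(refProtein) == nchar(altProtein) &&
      substr(refProtein, i + 1L, nchar(refProtein)) ==
      substr(altProtein, i + 1L, nchar(altProtein)))
    return(list(name = sprintf("%s%d%s", refAa, i, altAa), synonymous = FALSE))
  if (nchar(altProtein) < nchar(refProtein) &&
      substr(altProtein, i, nchar(altProtein)) ==
      substr(refProtein, i + (nchar(refProtein) - nchar(altProtein)),
             nchar(refProtein)) &&
      !frameshift)
    return(list(name = sprintf("%s%ddel", refAa, i), synonymous = FALSE))
  if (nchar(altProtein) > nchar(refProtein) && !frameshift) {
    ins <- substr(altProtein, i, i + (nchar(altProtein) - nchar(refProtein)) - 1L)
    return(list(name = sprintf("%s%dins%s", refAa, i, ins), synonymous = FALSE))
  }
  # mixed in-frame change: report as substitution block at first difference
  list(name = sprintf("%s%d%s", refAa, i, altAa), synonymous = FALSE)
}

# Build the ProteinIsoformPair for one transcript + one sample's variants.
# Returns NULL (with attribute "skipped") when no variant changes the
# protein or the alternate protein is untranslatable (start codon disrupted).
buildIsoformPair <- function(genome, model, variants, sample = "sample") {
  tid <- as.character(mcols(model)$transcript_id[1])
  gid <- as.character(mcols(model)$gene_id[1])
  refCds <- extractCdsSequence(genome, model)
  refProt <- translateCds(refCds)
  inj <- injectVariants(refCds, model, variants)
  skipped <- inj$skipped
  if (!nrow(inj$applied))
    return(list(pair = NULL, skipped = skipped))
  altCds <- inj$cds
  altProt <- translateCds(altCds)

  app <- inj$applied
  # per-variant names from single-variant injection
  names_ <- character(nrow(app)); syn <- logical(nrow(app))
  fs <- abs(nchar(app$txAlt) - nchar(app$txRef)) %% 3L != 0L
  for (i in seq_len(nrow(app))) {
    one <- injectVariants(refCds, model, app[i, c("chrom", "pos", "ref", "alt"), drop = FALSE])
    nm <- nameProteinVariant(refProt, translateCds(one$cds), frameshift = fs[i])
    names_[i] <- nm$name
    syn[i] <- nm$synonymous
  }
  if (all(syn)) {
    keep <- intersect(colnames(app), setdiff(colnames(skipped), "reason"))
    return(list(pair = NULL, skipped = rbind(skipped,
      cbind(app[, keep, drop = FALSE], reason = "synonymous"))))
  }
  if (!nzchar(altProt) || substr(altProt, 1, 1) != "M" || altProt == refProt) {
    reason <- if (!nzchar(altProt) || substr(altProt, 1, 1) != "M")
      "start codon disrupted" else "protein identical to reference"
    keep <- intersect(colnames(app), setdiff(colnames(skipped), "reason"))
    return(list(pair = NULL, skipped = rbind(skipped,
      cbind(app[, keep, drop = FALSE], reason = reason))))
  }

  # amino acid spans: reference from transcript coords; alternate shifted by
  # upstream indel offsets
  shift <- cumsum(c(0L, (nchar(app$txAlt) - nchar(app$txRef))[-nrow(app)]))
  refAaStart <- (app$txStart - 1L) %/% 3L + 1L
  refAaEnd <- (app$txEnd - 1L) %/% 3L + 1L
  altT1 <- app$txStart + shift
  altT2 <- altT1 + nchar(app$txAlt) - 1L
  altAaStart <- (altT1 - 1L) %/% 3L + 1L
  altAaEnd <- (altT2 - 1L) %/% 3L + 1L
  # frameshifts disturb everything downstream of the change
  altAaEnd[fs] <- max(nchar(altProt), altAaEnd[fs])
  refAaEnd[fs] <- nchar(refProt)
  # clip to translated lengths (early stops may truncate)
  clip <- function(x, n) pmin(pmax(x, 1L), n)
  vt <- data.frame(
    chrom = app$chrom, pos = app$pos, ref = app$ref, alt = app$alt,
    zygosity = if ("zygosity" %in% names(app)) app$zygosity else "unknown",
    txStart = app$txStart, txEnd = app$txEnd,
    refAaStart = clip(refAaStart, nchar(refProt)),
    refAaEnd = clip(refAaEnd, nchar(refProt)),
    altAaStart = clip(altAaStart, nchar(altProt)),
    altAaEnd = clip(altAaEnd, nchar(altProt)),
    name = names_, synonymous = syn,
    stringsAsFactors = FALSE
  )
  pair <- new("ProteinIsoformPair", transcriptId = tid, geneId = gid,
              sample = sample, referenceProtein = refProt,
              alternateProtein = altProt, variants = vt)
  list(pair = pair, skipped = skipped)
}
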