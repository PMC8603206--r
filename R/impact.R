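# Impact annotation of variant protein isoforms: S/T/Y loss/gain, kinase
# motif loss/gain, overlap with known phosphosites / cancer variant sites /
# cancer gene lists, Levenshtein similarity, and the summed "+1" impact
# score with its scaled form and ranking.

STY <- c("S", "T", "Y")

countLetters <- function(span, letters) {
  v <- strsplit(span, "")[[1]]
  vapply(letters, function(l) sum(v == l), integer(1))
}

#' Classify the S/T/Y change of a variant span
#'
#' Compares the phosphorylatable residue content (serine, threonine,
#' tyrosine) of the reference and alternate spans of a variant.
#'
#' @param refSpan,altSpan amino acid strings covering the variant on each
#'   sequence (single residues for substitutions).
#' @return one of \code{"loss"}, \code{"gain"}, \code{"loss_and_gain"},
#'   \code{"none"}.
#' @examples
#' styChange("S", "L")  # loss
#' styChange("F", "I")  # none
#' styChange("S", "T")  # loss_and_gain
#' @export
styChange <- function(refSpan, altSpan) {
  rc <- countLetters(refSpan, STY)
  ac <- countLetters(altSpan, STY)
  loss <- any(rc > ac)
  gain <- any(ac > rc)
  if (loss && gain) "loss_and_gain"
  else if (loss) "loss"
  else if (gain) "gain"
  else "none"
}

# all (overlapping) match start positions of a motif (x = wildcard) in seq
motifMatches <- function(seq, motif) {
  pat <- paste0("(?=", gsub("x", ".", motif, fixed = TRUE), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Kinase motif loss/gain at a variant
#'
#' Slides each motif (wildcard \code{x} matches any residue) along both
#' sequences. A motif occurrence in the reference that overlaps the variant
#' span and has no counterpart occurrence (same offset relative to the span
#' start) in the alternate is a loss; the symmetric case is a gain.
#' Occurrences not overlapping the variant span are ignored.
#'
#' @param refProtein,altProtein full protein strings.
#' @param refSpan,altSpan integer vectors \code{c(start, end)} of the variant
#'   span on each sequence (1-based).
#' @param motifs data.frame(kinase, motif).
#' @return data.frame(kinase, motif, change) with change in
#'   \code{"loss"/"gain"/"none"} per motif row.
#' @export
motifChange <- function(refProtein, altProtein, refSpan, altSpan, motifs) {
  if (!nrow(motifs))
    return(data.frame(kinase = character(0), motif = character(0),
                      change = character(0)))
  change <- character(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    mo <- motifs$motif[i]
    w <- nchar(mo)
    rm_ <- motifMatches(refProtein, mo)
    am_ <- motifMatches(altProtein, mo)
    # occurrences overlapping the variant span, keyed by offset to span start
    rOv <- rm_[rm_ <= refSpan[2] & (rm_ + w - 1L) >= refSpan[1]] - refSpan[1]
    aOv <- am_[am_ <= altSpan[2] & (am_ + w - 1L) >= altSpan[1]] - altSpan[1]
    loss <- length(setdiff(rOv, aOv)) > 0L
    gain <- length(setdiff(aOv, rOv)) > 0L
    change[i] <- if (loss && gain) "loss_and_gain"
      else if (loss) "loss" else if (gain) "gain" else "none"
  }
  data.frame(kinase = motifs$kinase, motif = motifs$motif, change = change,
             stringsAsFactors = FALSE)
}

#' Levenshtein similarity of two protein sequences
#'
#' \code{1 - editDistance / max(nchar(a), nchar(b))}; alternate isoforms with
#' similarity below 0.90 are flagged as heavily disrupted downstream.
#'
#' @param a,b nonempty amino acid strings.
#' @return numeric in [0, 1].
#' @examples
#' levenshteinSimilarity("MKR", "MQR")  # 2/3
#' @export
levenshteinSimilarity <- function(a, b) {
  assertThat(nzchar(a) && nzchar(b), "sequences must be nonempty")
  1 - as.numeric(adist(a, b)) / max(nchar(a), nchar(b))
}

# Per-variant resource overlap flags for one isoform pair.
resourceFlagsOne <- function(pair, vrow, resources) {
  gid <- pair@geneId
  refPos <- seq(vrow$refAaStart, vrow$refAaEnd)
  sty <- styChange(substr(pair@referenceProtein, vrow$refAaStart, vrow$refAaEnd),
                   substr(pair@alternateProtein, vrow$altAaStart, vrow$altAaEnd))
  ph <- resources$knownPhosphosites
  phHere <- nrow(ph) && any(ph$protein == gid & ph$position %in% refPos)
  mv <- resources$melanomaVariants
  cv <- resources$cancerVariants
  list(
    sty_loss = sty %in% c("loss", "loss_and_gain"),
    sty_gain = sty %in% c("gain", "loss_and_gain"),
    known_phosphosite_loss = isTRUE(phHere && sty %in% c("loss", "loss_and_gain")),
    known_phosphosite_gain = isTRUE(phHere && sty %in% c("gain", "loss_and_gain")),
    known_melanoma_variant = nrow(mv) > 0 && any(mv$gene == gid & mv$position %in% refPos),
    known_cancer_variant = nrow(cv) > 0 && any(cv$gene == gid & cv$position %in% refPos),
    cancer_gene = gid %in% resources$cancerGenes,
    resistance_gene = gid %in% resources$resistanceGenes
  )
}

#' Resource overlap flags for an isoform pair
#'
#' Overlaps every injected variant of the pair with the annotation resources
#' and ORs the per-variant flags into isoform-level flags.
#'
#' @param pair a \code{\link{ProteinIsoformPair-class}}.
#' @param resources an \code{\link{annotationResources}} bundle.
#' @return named logical list: \code{known_phosphosite_loss/gain},
#'   \code{known_melanoma_variant}, \code{known_cancer_variant},
#'   \code{cancer_gene}, \code{resistance_gene}.
#' @export
resourceOverlap <- function(pair, resources) {
  vt <- variantTable(pair)
  vt <- vt[!vt$synonymous, , drop = FALSE]
  keys <- c("known_phosphosite_loss", "known_phosphosite_gain",
            "known_melanoma_variant", "known_cancer_variant",
            "cancer_gene", "resistance_gene")
  if (!nrow(vt)) return(setNames(as.list(rep(FALSE, length(keys))), keys))
  per <- lapply(seq_len(nrow(vt)), function(i)
    resourceFlagsOne(pair, vt[i, , drop = FALSE], resources))
  setNames(lapply(keys, function(k)
    any(vapply(per, function(x) isTRUE(x[[k]]), logical(1)))), keys)
}

#' Default impact category sets
#'
#' The two scoring strategies differ only in which impact categories receive
#' the per-residue "+1": the phospho strategy scores disruption of
#' phosphorylation-mediated signaling, the resistance strategy scores cancer
#' and drug-resistance relevance.
#'
#' @param strategy \code{"phospho"} or \code{"resistance"}.
#' @return character vector of category names.
#' @export
impactCategories <- function(strategy = c("phospho", "resistance")) {
  strategy <- match.arg(strategy)
  if (strategy == "phospho")
    c("sty_loss", "sty_gain", "motif_loss", "motif_gain",
      "known_phosphosite_loss", "known_phosphosite_gain",
      "known_melanoma_variant", "cancer_gene")
  else
    c("known_melanoma_variant", "known_cancer_variant",
      "cancer_gene", "resistance_gene")
}

#' Summed per-residue impact score
#'
#' Every alternate-sequence residue accumulates +1 for each impact annotation
#' overlapping it; the maximum over the sequence is the isoform's score, and
#' the scaled score divides by the number of configured categories.
#'
#' @param altLength length of the alternate protein.
#' @param impacts data.frame with columns \code{start}, \code{end} (alternate
#'   amino acid span) and \code{category}; one row per firing annotation.
#' @param categories character vector of configured category names; rows of
#'   \code{impacts} outside this list are ignored. Each category marks a
#'   residue at most once, so the summed score is bounded by the category
#'   count and the scaled score stays in [0, 1] even when several variants'
#'   spans pile onto one residue (e.g. after a truncating stop gain).
#' @return list(\code{perResidue} integer vector, \code{maxScore},
#'   \code{scaledScore}).
#' @export
computeImpactScore <- function(altLength, impacts, categories) {
  assertThat(length(categories) > 0L, "category list must be nonempty")
  score <- integer(altLength)
  if (nrow(impacts)) {
    impacts <- impacts[impacts$category %in% categories, , drop = FALSE]
    for (cat in unique(impacts$category)) {
      mask <- logical(altLength)
      rows <- impacts[impacts$category == cat, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        idx <- seq(max(1L, rows$start[i]), min(altLength, rows$end[i]))
        mask[idx] <- TRUE
      }
      score <- score + mask
    }
  }
  maxScore <- if (altLength) max(score) else 0L
  list(perResidue = score, maxScore = maxScore,
       scaledScore = maxScore / length(categories))
}

# Per-variant firing categories -> impact span rows on the alternate protein.
impactRowsOne <- function(pair, vrow, resources) {
  flags <- resourceFlagsOne(pair, vrow, resources)
  mot <- motifChange(pair@referenceProtein, pair@alternateProtein,
                     c(vrow$refAaStart, vrow$refAaEnd),
                     c(vrow$altAaStart, vrow$altAaEnd),
                     resources$kinaseMotifs)
  flags$motif_loss <- any(mot$change %in% c("loss", "loss_and_gain"))
  flags$motif_gain <- any(mot$change %in% c("gain", "loss_and_gain"))
  fire <- names(flags)[vapply(flags, isTRUE, logical(1))]
  if (!length(fire))
    return(data.frame(start = integer(0), end = integer(0),
                      category = character(0)))
  data.frame(start = vrow$altAaStart, end = vrow$altAaEnd, category = fire,
             stringsAsFactors = FALSE)
}

#' Annotate a variant database for impact and rank its isoforms
#'
#' Runs the full impact annotation over every alternate isoform of a
#' \code{\link{VariantDB-class}}: S/T/Y and kinase motif loss/gain, overlap
#' with known phosphosites and cancer resources, Levenshtein similarity with
#' the <0.90 disruption flag, the summed/scaled impact score and the final
#' ranking (scaled score descending, ties broken by similarity ascending —
#' more disrupted first — then by isoform id).
#'
#' @param db a \code{\link{VariantDB-class}}.
#' @param resources an \code{\link{annotationResources}} bundle.
#' @param strategy \code{"phospho"} or \code{"resistance"} (see
#'   \code{\link{impactCategories}}).
#' @param categories optional explicit category vector overriding
#'   \code{strategy}.
#' @return data.frame, one row per (sample, transcript) isoform: flags,
#'   \code{similarity}, \code{low_similarity}, \code{max_score},
#'   \code{scaled_score}, \code{rank}.
#' @export
annotateImpact <- function(db, resources, strategy = c("phospho", "resistance"),
                           categories = NULL) {
  if (is.null(categories)) categories <- impactCategories(match.arg(strategy))
  rows <- list()
  for (s in names(isoformPairs(db))) {
    for (pair in isoformPairs(db)[[s]]) {
      vt <- variantTable(pair)
      vt <- vt[!vt$synonymous, , drop = FALSE]
      imp <- do.call(rbind, c(
        list(data.frame(start = integer(0), end = integer(0), category = character(0))),
        lapply(seq_len(nrow(vt)), function(i)
          impactRowsOne(pair, vt[i, , drop = FALSE], resources))))
      sc <- computeImpactScore(nchar(alternateProtein(pair)), imp, categories)
      sim <- levenshteinSimilarity(referenceProtein(pair), alternateProtein(pair))
      flagOf <- function(k) k %in% imp$category
      rows[[length(rows) + 1L]] <- data.frame(
        isoform = sprintf("%s|%s", pair@transcriptId, s),
        transcript_id = pair@transcriptId, gene_id = pair@geneId, sample = s,
        variant_names = paste(variantNames(pair), collapse = ";"),
        sty_loss = flagOf("sty_loss"), sty_gain = flagOf("sty_gain"),
        motif_loss = flagOf("motif_loss"), motif_gain = flagOf("motif_gain"),
        known_phosphosite_loss = flagOf("known_phosphosite_loss"),
        known_phosphosite_gain = flagOf("known_phosphosite_gain"),
        known_melanoma_variant = flagOf("known_melanoma_variant"),
        known_cancer_variant = flagOf("known_cancer_variant"),
        cancer_gene = flagOf("cancer_gene"),
        resistance_gene = flagOf("resistance_gene"),
        similarity = sim, low_similarity = sim < 0.90,
        max_score = sc$maxScore, scaled_score = sc$scaledScore,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame())
  tab <- do.call(rbind, rows)
  rankIsoforms(tab)
}

#' Rank scored isoforms
#'
#' Orders isoforms by scaled score descending, breaking ties by similarity
#' ascending (the more disrupted isoform first) and then by isoform id, and
#' assigns ranks 1..n.
#'
#' @param tab data.frame with columns \code{isoform}, \code{scaled_score},
#'   \code{similarity}.
#' @return the table sorted with a \code{rank} column added.
#' @export
rankIsoforms <- function(tab) {
  assertThat(nrow(tab) >= 1L, "at least one scored isoform required")
  o <- order(-tab$scaled_score, tab$similarity, tab$isoform)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
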