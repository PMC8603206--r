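# Quantitative comparison stages: phosphosite normalization, s0-moderated
# two-sample test with permutation-based FDR, Fisher exact
# overrepresentation, and the SILAC twofold filter.

#' Normalize phosphosite intensities by parent protein intensities
#'
#' Subtracts, per sample, the parent protein log2 intensity from each
#' phosphosite log2 intensity, so downstream tests measure phosphorylation
#' changes beyond protein abundance changes. Sites whose parent protein is
#' missing from the protein matrix are dropped (logged in the result).
#'
#' @param sites numeric matrix of log2 site intensities (rows = sites,
#'   columns = samples).
#' @param proteins numeric matrix of log2 protein intensities with matching
#'   sample columns.
#' @param parent character vector mapping each site row to its parent protein
#'   (a rowname of \code{proteins}).
#' @return list(matrix = normalized site matrix, dropped = character vector
#'   of dropped site ids).
#' @export
normalizePhospho <- function(sites, proteins, parent) {
  assertThat(length(parent) == nrow(sites),
             "one parent protein per site row required")
  assertThat(identical(colnames(sites), colnames(proteins)),
             "site and protein matrices must share sample columns")
  keep <- parent %in% rownames(proteins)
  dropped <- rownames(sites)[!keep]
  out <- sites[keep, , drop = FALSE] -
    proteins[parent[keep], , drop = FALSE]
  rownames(out) <- rownames(sites)[keep]
  list(matrix = out, dropped = dropped)
}

#' Test parameters for the moderated two-sample test
#'
#' @param s0 fudge constant added to the standard error of the difference
#'   (default 0.1); stabilizes near-zero-variance features.
#' @param fdrThreshold permutation FDR cutoff (0.05 for proteome-style data,
#'   0.10 for phosphoproteome-style data).
#' @param nPermutations random relabelings drawn when exhaustive enumeration
#'   exceeds 100 distinct relabelings.
#' @param seed RNG seed for random relabelings.
#' @return list of parameters.
#' @export
testParams <- function(s0 = 0.1, fdrThreshold = 0.05, nPermutations = 250L,
                       seed = 1L) {
  assertThat(s0 >= 0, "s0 must be nonnegative")
  assertThat(fdrThreshold > 0 && fdrThreshold < 1, "fdrThreshold must be in (0,1)")
  list(s0 = s0, fdrThreshold = fdrThreshold,
       nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

# SAM-type statistic per row: (meanA - meanB) / (pooled SE + s0)
samStatistic <- function(mat, isA, s0) {
  nA <- sum(isA); nB <- sum(!isA)
  mA <- rowMeans(mat[, isA, drop = FALSE])
  mB <- rowMeans(mat[, !isA, drop = FALSE])
  vA <- apply(mat[, isA, drop = FALSE], 1, stats::var)
  vB <- apply(mat[, !isA, drop = FALSE], 1, stats::var)
  sp <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2))
  se <- sp * sqrt(1 / nA + 1 / nB)
  (mA - mB) / (se + s0)
}

# all distinct group-A index sets of size nA out of n (as a list), or NULL
# when there are more than `limit`
exhaustiveRelabelings <- function(n, nA, limit = 100L) {
  if (choose(n, nA) > limit) return(NULL)
  asplit(combn(n, nA), 2)
}

#' Moderated two-sample test with permutation-based FDR
#'
#' Computes the SAM-type statistic \code{d = (meanA - meanB) / (pooledSE +
#' s0)} per feature (rows must be complete cases: features with missing
#' values in the tested samples must be filtered out beforehand), builds a
#' permutation null by relabeling the group assignment — exhaustively when at
#' most 100 distinct relabelings exist, otherwise with
#' \code{nPermutations} seeded random relabelings — and flags features whose
#' permutation FDR is at most the threshold. The FDR at cutoff c is the
#' median count of permuted |d| >= c divided by the observed count of
#' |d| >= c (monotonized from the most extreme cutoff down). Per-feature
#' permutation p-values are the fraction of relabelings with |d_perm| >=
#' |d_obs| for that feature.
#'
#' @param mat numeric matrix of log2 intensities, complete cases only.
#' @param groups character/factor vector over columns with exactly two
#'   levels; the first level is group A.
#' @param params \code{\link{testParams}}.
#' @return data.frame(feature, difference, statistic, p_value, fdr,
#'   significant).
#' @export
moderatedTTest <- function(mat, groups, params = testParams()) {
  groups <- as.factor(groups)
  assertThat(nlevels(groups) == 2L, "exactly two groups required")
  assertThat(all(table(groups) >= 2L), "each group needs at least two samples")
  assertThat(!anyNA(mat), "matrix must be complete cases (filter first)")
  isA <- groups == levels(groups)[1]
  n <- ncol(mat); nA <- sum(isA)

  dObs <- samStatistic(mat, isA, params$s0)
  diff <- rowMeans(mat[, isA, drop = FALSE]) - rowMeans(mat[, !isA, drop = FALSE])

  labelings <- exhaustiveRelabelings(n, nA)
  if (is.null(labelings)) {
    labelings <- withSeed(params$seed, lapply(seq_len(params$nPermutations),
                                              function(i) sample(n, nA)))
  }
  dPerm <- vapply(labelings, function(idx) {
    lab <- rep(FALSE, n); lab[idx] <- TRUE
    samStatistic(mat, lab, params$s0)
  }, numeric(nrow(mat)))
  dPerm <- matrix(dPerm, nrow = nrow(mat))

  absObs <- abs(dObs)
  absPerm <- abs(dPerm)
  # per-feature permutation p: share of relabelings at least as extreme
  pVal <- rowMeans(absPerm >= absObs - 1e-12)

  # FDR at each observed cutoff: median permuted exceedance / observed count
  o <- order(-absObs)
  cuts <- absObs[o]
  obsCount <- seq_along(cuts)
  permCount <- vapply(cuts, function(c0)
    median(colSums(absPerm >= c0 - 1e-12)), numeric(1))
  fdrAt <- pmin(1, permCount / obsCount)
  # q-value convention: best FDR over all cutoffs still including the feature
  fdrAt <- rev(cummin(rev(fdrAt)))
  fdr <- numeric(length(dObs))
  fdr[o] <- fdrAt
  zero <- absObs < 1e-12                     # d == 0 can never be called
  fdr[zero] <- 1

  data.frame(
    feature = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
              else rownames(mat),
    difference = diff, statistic = dObs, p_value = pVal, fdr = fdr,
    significant = fdr <= params$fdrThreshold & !zero,
    stringsAsFactors = FALSE)
}

#' Filter a quantitative matrix to complete cases
#'
#' Drops features not quantified in all tested samples (the complete-case
#' policy; no imputation).
#'
#' @param mat numeric matrix with NAs for missing values.
#' @return the filtered matrix.
#' @export
filterComplete <- function(mat) {
  mat[stats::complete.cases(mat), , drop = FALSE]
}

#' Fisher exact overrepresentation with BH adjustment
#'
#' One-sided hypergeometric test per category for overrepresentation of the
#' significant set against the background of all identified entries, with
#' Benjamini-Hochberg adjustment; the enrichment factor is
#' \code{(k/n)/(K/N)}.
#'
#' @param significant character vector, subset of \code{background}.
#' @param background character vector of all tested entries.
#' @param categories named list of character vectors (category -> members).
#' @param fdrThreshold report flag cutoff on the adjusted value (e.g. 0.2
#'   for resistance-style studies, 0.1 for interaction-style studies).
#' @return data.frame(category, k, n, K, N, odds_ratio, p_value, fdr,
#'   enrichment_factor, significant).
#' @export
fisherEnrichment <- function(significant, background, categories,
                             fdrThreshold = 0.2) {
  significant <- unique(significant)
  background <- unique(background)
  assertThat(all(significant %in% background),
             "significant entries must be a subset of the background")
  if (!length(significant) || !length(categories))
    return(data.frame(category = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      enrichment_factor = numeric(0), significant = logical(0)))
  n <- length(significant); N <- length(background)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(unique(categories[[cat]]), background)
    K <- length(members)
    k <- length(intersect(significant, members))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    orv <- (k * (N - K - n + k)) / max(1e-300, (K - k) * (n - k))
    data.frame(category = cat, k = k, n = n, K = K, N = N,
               odds_ratio = orv, p_value = p,
               enrichment_factor = if (K > 0) (k / n) / (K / N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$fdr <= fdrThreshold
  tab <- tab[order(tab$p_value, tab$category),
             c("category", "k", "n", "K", "N", "odds_ratio", "p_value",
               "fdr", "enrichment_factor", "significant")]
  rownames(tab) <- NULL
  tab
}

#' SILAC twofold ratio filter
#'
#' Averages the log2 ratios of independent replicates and flags entries whose
#' mean absolute log2 ratio reaches the twofold cutoff (|mean log2| >= 1).
#' Entries quantified in fewer than \code{minReplicates} replicates are
#' excluded (mean NA, flag NA).
#'
#' @param ratios numeric vector or matrix (rows = entries) of linear ratios,
#'   or log2 ratios when \code{log2Input = TRUE}; NAs mark missing replicates.
#' @param minReplicates required replicate count (default 3).
#' @param log2Input whether the input is already log2-transformed.
#' @return data.frame(mean_log2_ratio, n_replicates, significant).
#' @export
silacRatioFilter <- function(ratios, minReplicates = 3L, log2Input = FALSE) {
  if (is.vector(ratios)) ratios <- matrix(ratios, nrow = 1)
  lg <- if (log2Input) ratios else log2(ratios)
  nrep <- rowSums(!is.na(lg))
  m <- rowMeans(lg, na.rm = TRUE)
  ok <- nrep >= minReplicates
  m[!ok] <- NA_real_
  data.frame(
    entry = if (is.null(rownames(ratios))) as.character(seq_len(nrow(ratios)))
            else rownames(ratios),
    mean_log2_ratio = m, n_replicates = nrep,
    significant = ifelse(ok, abs(m) >= 1, NA),
    stringsAsFactors = FALSE)
}
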