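# Independent brute-force oracles and small in-code fixtures shared by the
# test files. None of these call the package functions they are used to
# check.

# --- tiny genome/model builders ---------------------------------------------

toyGenome <- function(...) Biostrings::DNAStringSet(c(...))

toyModel <- function(chrom, starts, ends, strand = "+", tid = "t1",
                     gid = "g1", phase = 0L) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                              strand = strand)
  S4Vectors::mcols(g)$transcript_id <- tid
  S4Vectors::mcols(g)$gene_id <- gid
  S4Vectors::mcols(g)$phase <- phase
  g
}

# a ready isoform pair around a single substitution, built through the
# package constructors (used where the pair is scaffolding, not the thing
# under test)
toyPair <- function(refCodons, altCodon, codonIndex, sample = "S1") {
  cds <- paste(refCodons, collapse = "")
  genome <- toyGenome(chr1 = cds)
  model <- toyModel("chr1", 1, nchar(cds))
  refCodon <- refCodons[codonIndex]
  p <- which(strsplit(refCodon, "")[[1]] != strsplit(altCodon, "")[[1]])[1]
  gpos <- (codonIndex - 1L) * 3L + p
  v <- data.frame(chrom = "chr1", pos = gpos,
                  ref = substr(refCodon, p, p), alt = substr(altCodon, p, p),
                  zygosity = "homozygous", sample = sample)
  db <- buildDatabases(genome, list(t1 = model), setNames(list(v), sample))
  isoformPairs(db)[[sample]][["t1"]]
}

# --- edit distance oracle ----------------------------------------------------

# plain recursive Levenshtein with memoisation (scalar)
editDistOracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- as.integer(substr(a, i, i) != substr(b, j, j))
    val <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
               rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- val
    val
  }
  rec(nchar(a), nchar(b))
}

# all strings of length 1..maxLen over an alphabet, plus the full pairwise
# edit distance matrix filled by the same recurrence (vectorised via
# drop-last-character parents)
editDistMatrixOracle <- function(alphabet, maxLen) {
  strs <- ""
  parent <- NA_integer_
  lastch <- NA_character_
  for (l in seq_len(maxLen)) {
    prev <- which(nchar(strs) == l - 1L)
    for (ch in alphabet) {
      strs <- c(strs, paste0(strs[prev], ch))
      parent <- c(parent, prev)
      lastch <- c(lastch, rep(ch, length(prev)))
    }
  }
  n <- length(strs)
  D <- matrix(NA_integer_, n, n)
  D[1, ] <- nchar(strs)
  D[, 1] <- nchar(strs)
  ord <- order(nchar(strs))
  for (i in ord) {
    if (i == 1L) next
    for (j in ord) {
      if (j == 1L) next
      cost <- as.integer(lastch[i] != lastch[j])
      D[i, j] <- min(D[parent[i], j] + 1L, D[i, parent[j]] + 1L,
                     D[parent[i], parent[j]] + cost)
    }
  }
  list(strings = strs, dist = D)
}

# --- peptide classification oracle ------------------------------------------

# every occurrence of `pep` in `protein` that is a valid tryptic peptide
# (trypsin/P context, bounded missed cleavages/length), as start positions
trypticOccurrences <- function(pep, protein, maxMissed = 2L, minLen = 7L,
                               maxLen = 52L) {
  L <- nchar(pep)
  if (L < minLen || L > maxLen) return(integer(0))
  hits <- integer(0)
  st <- 1L
  repeat {
    p <- regexpr(pep, substr(protein, st, nchar(protein)), fixed = TRUE)
    if (p == -1L) break
    s <- st + as.integer(p) - 1L
    e <- s + L - 1L
    prevOk <- s == 1L || substr(protein, s - 1L, s - 1L) %in% c("K", "R")
    endOk <- e == nchar(protein) || substr(protein, e, e) %in% c("K", "R")
    internal <- sum(strsplit(substr(protein, s, e - 1L), "")[[1]] %in% c("K", "R"))
    if (prevOk && endOk && internal <= maxMissed) hits <- c(hits, s)
    st <- s + 1L
    if (st > nchar(protein)) break
  }
  hits
}

# brute-force classification: substring occurrences (tryptic-valid) on both
# full sequences intersected with variant positions
classifyOracle <- function(pep, refProt, altProt, refVarPos, altVarPos,
                           maxMissed = 2L, minLen = 7L, maxLen = 52L) {
  rs <- trypticOccurrences(pep, refProt, maxMissed, minLen, maxLen)
  as <- trypticOccurrences(pep, altProt, maxMissed, minLen, maxLen)
  L <- nchar(pep)
  covers <- function(starts, varPos)
    any(vapply(starts, function(s)
      any(varPos >= s & varPos <= s + L - 1L), logical(1)))
  cr <- length(rs) > 0 && covers(rs, refVarPos)
  ca <- length(as) > 0 && covers(as, altVarPos)
  if (ca && cr) "unspecific"
  else if (ca) "alternate"
  else if (cr) "reference"
  else if (length(rs) || length(as)) "unspecific"
  else NA_character_
}

# --- betweenness oracle ------------------------------------------------------

# unnormalised betweenness by explicit enumeration of all shortest paths
# (endpoints excluded), for small undirected graphs given as an edge matrix
betweennessOracle <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(x) character(0)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  allPaths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      tail <- path[length(path)]
      if (tail == to) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (nb in adj[[tail]]) if (!nb %in% path) grow(c(path, nb))
    }
    grow(from)
    out
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- allPaths(nodes[i], nodes[j])
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      inner <- p[-c(1, length(p))]
      for (v in inner) btw[v] <- btw[v] + 1 / sigma
    }
  }
  btw
}

# --- misc --------------------------------------------------------------------

# Benjamini-Hochberg step-up written out longhand
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# classical two-sample pooled-variance t statistic, longhand
classicalT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
}
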