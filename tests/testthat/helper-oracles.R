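# Independent oracles used across tests. Each is a deliberately naive
# re-derivation (explicit loops, enumeration) kept separate from the
# package's implementation path.

# ssGSEA score by explicit cumulative sums over every gene position
bruteSsgseaScore <- function(ranks, geneSet, alpha) {
  genes <- names(ranks)
  ord <- order(ranks, decreasing = TRUE)
  walked <- genes[ord]
  members <- walked %in% geneSet
  totalW <- sum(abs(ranks[ord][members])^alpha)
  nOut <- sum(!members)
  es <- 0
  pin <- 0
  pout <- 0
  for (i in seq_along(walked)) {
    if (members[i]) pin <- pin + abs(ranks[ord][i])^alpha / totalW
    else pout <- pout + 1 / nOut
    es <- es + (pin - pout)
  }
  unname(es)
}

# quantile normalization via explicit per-column sort/replace (untied data)
bruteQuantileNormalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m)))
    out[, j] <- ref[rank(m[, j])]
  out
}

# BH step-up: q_(i) = min over j >= i of p_(j) * m / j, capped at 1
bruteBH <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(ps)
  q <- numeric(k)
  for (i in seq_len(k))
    q[i] <- min(1, min(ps[i:k] * m / (i:k)))
  out <- numeric(k)
  out[ord] <- q
  out
}

# hypergeometric upper tail by enumerating all DEG-sized subsets of the
# background (feasible for |background| <= 12)
bruteHyperTail <- function(background, category, degSize, observedOverlap) {
  subsets <- utils::combn(background, degSize, simplify = FALSE)
  hits <- vapply(subsets, function(s)
    length(intersect(s, category)) >= observedOverlap, TRUE)
  mean(hits)
}

# plain (unadjusted) Rand index between two labelings
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / total
}

# small hand-built count set: 3 endogenous, 2 housekeeping, 2 negative
smallCountSet <- function(counts = NULL) {
  genes <- c("G1", "G2", "G3", "HK1", "HK2", "N1", "N2")
  if (is.null(counts)) {
    counts <- matrix(c(10, 3, 50, 20, 80, 4, 6,
                       12, 5, 40, 20, 80, 0, 0),
                     nrow = 7, dimnames = list(genes, c("S1", "S2")))
  }
  PanelCountSet(counts,
                probeClass = c("endogenous", "endogenous", "endogenous",
                               "housekeeping", "housekeeping",
                               "negative_control", "negative_control"))
}

# tiny valid annotation: nPatients patients, pre+post each
smallAnnotation <- function(nPatients = 4,
                            response = rep("NR", nPatients)) {
  patients <- paste0("P", seq_len(nPatients))
  validateSampleAnnotation(data.frame(
    sample_id = as.vector(t(outer(patients, c("pre", "post"), paste,
                                  sep = "_"))),
    patient_id = rep(patients, each = 2),
    timepoint = rep(c("pre", "post"), nPatients),
    response = rep(response, each = 2),
    hr_status = "Pos", her2_status = "Neg",
    stringsAsFactors = FALSE))
}
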