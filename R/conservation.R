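# Conservation scoring of alignment columns (scorecons-style sum of pairs),
# alignment diversity metrics and the two-tier conserved-site rule.

# normalized pairwise similarity with unit diagonal:
# m'(a,b) = m01(a,b) / sqrt(m01(a,a) * m01(b,b)), clamped to [0, 1]
SIM_NORM <- local({
  m <- BLOSUM62_01
  d <- sqrt(diag(m))
  s <- m / outer(d, d)
  pmin(pmax(s, 0), 1)
})

#' @keywords internal
sim_norm <- function(a, b) {
  out <- numeric(length(a))
  ok <- a %in% AA1 & b %in% AA1
  if (any(ok)) out[ok] <- SIM_NORM[cbind(a[ok], b[ok])]
  out
}

# Valdar-style sequence weights: w_i proportional to the mean distance of
# sequence i from the others (distance = 1 - fractional identity over
# columns where both sequences are ungapped). Weights sum to 1; identical
# sequences fall back to uniform weights.
#' @keywords internal
msa_weights <- function(msa) {
  ali <- msa$ali
  n <- nrow(ali)
  if (n == 1L) return(1)
  gap <- ali == "-"
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !gap[i, ] & !gap[j, ]
      nc <- sum(both)
      ident <- if (nc == 0L) 0 else sum(ali[i, both] == ali[j, both]) / nc
      d[i, j] <- d[j, i] <- 1 - ident
    }
  }
  w <- rowSums(d) / (n - 1L)
  if (sum(w) <= 0) return(rep(1 / n, n))
  w / sum(w)
}

#' Per-column conservation profile (scorecons-style)
#'
#' Valdar-style weighted sum-of-pairs score per alignment column: the
#' weighted mean pairwise similarity of the column's residues under a
#' BLOSUM62-derived similarity rescaled to `[0, 1]` with unit diagonal, a
#' linear gap penalty (pairs involving a gap score 0 but stay in the
#' denominator), and distance-based sequence weights. A column identical
#' across all sequences scores exactly 1; an all-gap column scores 0.
#' Column scores map to query residue numbers via the ungapped query.
#'
#' @param msa an [msa()].
#' @param weights `"valdar"` (default) or `"uniform"`.
#' @param query_start residue number of the first query residue.
#' @return an object of class `conservation_profile`: data.frame with
#'   columns `column`, `score` in `[0, 1]` and `position` (query residue
#'   number, `NA` for query-gap columns).
#' @export
scorecons_profile <- function(msa, weights = c("valdar", "uniform"),
                              query_start = 1L) {
  weights <- match.arg(weights)
  ali <- msa$ali
  n <- nrow(ali); L <- ncol(ali)
  w <- if (weights == "valdar") msa_weights(msa) else rep(1 / n, n)
  score <- numeric(L)
  if (n == 1L) {
    score <- as.numeric(ali[1, ] != "-")
  } else {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ww <- w[pr[, 1]] * w[pr[, 2]]
    sw <- sum(ww)
    for (c in seq_len(L)) {
      col <- ali[, c]
      if (all(col == "-")) { score[c] <- 0; next }
      score[c] <- sum(ww * sim_norm(col[pr[, 1]], col[pr[, 2]])) / sw
    }
  }
  q <- ali[msa$query, ]
  position <- rep(NA_integer_, L)
  ng <- q != "-"
  position[ng] <- query_start - 1L + cumsum(ng)[ng]
  out <- data.frame(column = seq_len(L), score = score, position = position)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Effective number of sequences at 80 percent identity
#'
#' Number of single-linkage clusters of the alignment's sequences at
#' pairwise identity >= `identity` (identity = matching aligned residues /
#' shorter ungapped length). Sequences are scanned in input order and every
#' cluster linked to the incoming sequence is merged, so the result equals
#' the number of connected components of the identity graph.
#'
#' @param msa an [msa()].
#' @param identity clustering threshold (default 0.80).
#' @return number of clusters (1 <= Neff <= depth).
#' @export
neff_80 <- function(msa, identity = 0.80) {
  ali <- msa$ali
  n <- nrow(ali)
  if (n == 1L) return(1)
  gap <- ali == "-"
  len <- rowSums(!gap)
  cluster <- integer(n)           # 0 = unassigned
  nclust <- 0L
  for (i in seq_len(n)) {
    linked <- integer(0)
    for (j in seq_len(i - 1L)) {
      both <- !gap[i, ] & !gap[j, ]
      matches <- sum(ali[i, both] == ali[j, both])
      shorter <- min(len[i], len[j])
      idt <- if (shorter == 0L) 0 else matches / shorter
      if (idt >= identity) linked <- c(linked, cluster[j])
    }
    linked <- unique(linked)
    if (length(linked) == 0L) {
      nclust <- nclust + 1L
      cluster[i] <- nclust
    } else {
      keep <- min(linked)
      cluster[i] <- keep
      cluster[cluster %in% linked] <- keep
    }
  }
  length(unique(cluster))
}

#' Diversity of positions (DOPs)
#'
#' 100 times the number of distinct column conservation scores (rounded to
#' `digits` decimals) divided by the number of columns. A flat profile
#' gives `100 / L`; all-distinct scores give 100.
#'
#' @param profile a [scorecons_profile()].
#' @param digits rounding precision used when counting distinct scores.
#' @return DOPs in `[0, 100]`.
#' @export
dops <- function(profile, digits = 2) {
  stopifnot(nrow(profile) >= 1L)
  100 * length(unique(round(profile$score, digits))) / nrow(profile)
}

#' Percentage of conserved columns
#'
#' 100 times the fraction of columns whose conservation score is at or
#' above `threshold`.
#'
#' @param profile a [scorecons_profile()].
#' @param threshold column-score threshold (default 0.9).
#' @return percentage in `[0, 100]`.
#' @export
percent_scorecons <- function(profile, threshold = 0.9) {
  stopifnot(nrow(profile) >= 1L)
  100 * mean(profile$score >= threshold)
}

#' Alignment diversity metrics
#'
#' Neff (sequence clusters at 80 percent identity), DOPs, percent
#' scorecons and the number of distinct taxa found in the sequence
#' metadata (sequences without a taxon id are ignored for that count).
#'
#' @param msa an [msa()].
#' @param profile optional precomputed [scorecons_profile()].
#' @param pct_threshold threshold for [percent_scorecons()].
#' @return list with `neff`, `dops`, `percent_scorecons`, `n_taxa`.
#' @export
diversity_metrics <- function(msa, profile = NULL, pct_threshold = 0.9) {
  if (is.null(profile)) profile <- scorecons_profile(msa)
  list(neff = neff_80(msa),
       dops = dops(profile),
       percent_scorecons = percent_scorecons(profile, pct_threshold),
       n_taxa = length(unique(msa$taxon[!is.na(msa$taxon)])))
}

#' Two-tier conserved-site rule
#'
#' Tier 1: residue positions whose column score is at or above `cons_high`
#' (default 0.8). Tier 2: positions with score strictly above `cons_mid`
#' (default 0.65) having at least one tier-1 position within the
#' neighborhood. Returns the union. Unmapped (query-gap) columns are
#' skipped.
#'
#' @param profile a [scorecons_profile()] mapped to model numbering.
#' @param neighbors a `neighbor_map` (pass a strict-`<` map to follow the
#'   strict tier-2 neighborhood reading).
#' @param cons_high tier-1 threshold (inclusive).
#' @param cons_mid tier-2 column threshold (strict).
#' @return sorted integer vector of conserved residue numbers.
#' @export
conserved_sites <- function(profile, neighbors, cons_high = 0.8,
                            cons_mid = 0.65) {
  mapped <- !is.na(profile$position)
  pos <- profile$position[mapped]
  sc <- profile$score[mapped]
  s1 <- pos[sc >= cons_high]
  cand <- pos[sc > cons_mid]
  s2 <- cand[vapply(cand, function(p)
    any(neighbors_of(neighbors, p) %in% s1), TRUE)]
  sort(unique(c(s1, s2)))
}
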