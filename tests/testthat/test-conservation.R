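# Conservation scores, diversity metrics and the two-tier conserved-site rule.

test_that("scorecons anchors: identical column scores 1, all-gap column scores 0", {
  x <- msa(c("a", "b", "c"), c("AAC-", "AAD-", "AAW-"))
  pr <- scorecons_profile(x)
  expect_equal(pr$score[1], 1)
  expect_equal(pr$score[2], 1)
  expect_lt(pr$score[3], 1)
  expect_equal(pr$score[4], 0)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("column-to-residue mapping skips query gaps and respects query_start", {
  x <- msa(c("q", "h"), c("A-CD", "AECD"))
  pr <- scorecons_profile(x, query_start = 10L)
  expect_equal(pr$position, c(10L, NA, 11L, 12L))
  expect_true(all(diff(na.omit(pr$position)) > 0))
})

test_that("with uniform weights the score equals the unweighted sum of pairs", {
  x <- msa(letters[1:4], c("ACDE", "ACDF", "AWDE", "AC-E"))
  pr <- scorecons_profile(x, weights = "uniform")
  S <- structvar:::SIM_NORM
  hand <- function(col) {
    v <- strsplit(col, "")[[1]]
    tot <- 0; np <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      np <- np + 1
      if (v[i] != "-" && v[j] != "-") tot <- tot + S[v[i], v[j]]
    }
    tot / np
  }
  cols <- apply(x$ali, 2, paste, collapse = "")
  expect_equal(pr$score, unname(vapply(cols, hand, 0)), tolerance = 1e-12)
})

test_that("scorecons with weights is invariant under sequence permutation", {
  aln <- make_msa(15, 8, conserved_columns = 1:4, identity_target = 0.5, seed = 11)
  pr <- scorecons_profile(aln)
  set.seed(1)
  perm <- sample(aln$depth)
  # keep the query first so the column mapping is unchanged
  perm <- c(1, setdiff(perm, 1))
  shuf <- msa(aln$ids[perm], apply(aln$ali[perm, ], 1, paste, collapse = ""),
              taxon = aln$taxon[perm])
  expect_equal(scorecons_profile(shuf)$score, pr$score, tolerance = 1e-12)
})

test_that("Neff: degenerate cases and the connected-components oracle", {
  k <- msa(paste0("s", 1:5), rep("ACDEFG", 5))
  expect_equal(neff_80(k), 1)
  two <- msa(c("a", "b"), c("AAAA", "CCCC"))
  expect_equal(neff_80(two), 2)
  # oracle: connected components of the >= 0.8 identity graph via BFS
  cc_oracle <- function(x, thr = 0.8) {
    n <- x$depth
    gap <- x$ali == "-"
    len <- rowSums(!gap)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      both <- !gap[i, ] & !gap[j, ]
      idt <- if (min(len[i], len[j]) == 0) 0 else
        sum(x$ali[i, both] == x$ali[j, both]) / min(len[i], len[j])
      adj[i, j] <- adj[j, i] <- idt >= thr
    }
    seen <- rep(FALSE, n); ncomp <- 0
    for (i in 1:n) {
      if (seen[i]) next
      ncomp <- ncomp + 1
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        queue <- c(queue, which(adj[v, ] & !seen))
      }
    }
    ncomp
  }
  for (s in 1:8) {
    aln <- make_msa(25, 20, conserved_columns = 1:18,
                    identity_target = 0.85, seed = s)
    expect_equal(neff_80(aln), cc_oracle(aln), info = paste("seed", s))
  }
})

test_that("Neff is bounded by depth and never increased by duplicating a sequence", {
  aln <- make_msa(20, 10, identity_target = 0.4, seed = 3)
  n0 <- neff_80(aln)
  expect_gte(n0, 1); expect_lte(n0, aln$depth)
  dup <- msa(c(aln$ids, "dup"),
             c(apply(aln$ali, 1, paste, collapse = ""),
               paste(aln$ali[2, ], collapse = "")),
             taxon = c(aln$taxon, NA))
  expect_lte(neff_80(dup), n0)
})

test_that("DOPs counts distinct rounded column scores", {
  mkprof <- function(s) {
    structure(data.frame(column = seq_along(s), score = s,
                         position = seq_along(s)),
              class = c("conservation_profile", "data.frame"))
  }
  expect_equal(dops(mkprof(rep(1, 8))), 100 / 8)
  expect_equal(dops(mkprof(seq(0.1, 0.8, by = 0.1))), 100)
  expect_equal(dops(mkprof(c(0.50, 0.50, 0.80, 1.00))), 75)
})

test_that("percent scorecons is the fraction of columns at or above the threshold", {
  mkprof <- function(s) {
    structure(data.frame(column = seq_along(s), score = s,
                         position = seq_along(s)),
              class = c("conservation_profile", "data.frame"))
  }
  expect_equal(percent_scorecons(mkprof(rep(1, 4))), 100)
  expect_equal(percent_scorecons(mkprof(rep(0, 4))), 0)
  expect_equal(percent_scorecons(mkprof(c(0.95, 0.5, 0.91, 0.2)), 0.9), 50)
})

test_that("two-tier conserved sites: tier rules and the brute-force oracle", {
  m <- toy_model(list(c(0, 0, 0), c(4, 0, 0), c(10, 0, 0), c(16, 0, 0)))
  nb <- residue_neighbors(m, 5, inclusive = FALSE)
  prof <- structure(data.frame(column = 1:4, score = c(0.85, 0.70, 0.70, 0.85),
                               position = 1:4),
                    class = c("conservation_profile", "data.frame"))
  cs <- conserved_sites(prof, nb)
  expect_true(1 %in% cs)           # tier 1, isolated
  expect_true(2 %in% cs)           # 0.70 with a 0.85 neighbor at 4 A
  expect_false(3 %in% cs)          # nearest tier-1 position is 6 A away
  expect_true(4 %in% cs)

  for (s in 1:10) {
    mm <- make_structure(40, "coil", seed = 200 + s)
    set.seed(s)
    pr <- structure(data.frame(column = 1:40, score = runif(40),
                               position = mm$residues$number),
                    class = c("conservation_profile", "data.frame"))
    nbs <- residue_neighbors(mm, 5, inclusive = FALSE)
    expect_equal(conserved_sites(pr, nbs),
                 naive_conserved(mm, pr), info = paste("seed", s))
  }
})

test_that("conserved_sites is monotone in the score profile", {
  m <- make_structure(30, "coil", seed = 31)
  set.seed(2)
  sc <- runif(30)
  prof <- structure(data.frame(column = 1:30, score = sc,
                               position = m$residues$number),
                    class = c("conservation_profile", "data.frame"))
  nb <- residue_neighbors(m, 5, inclusive = FALSE)
  s0 <- conserved_sites(prof, nb)
  prof$score[7] <- min(1, prof$score[7] + 0.3)
  s1 <- conserved_sites(prof, nb)
  expect_true(all(s0 %in% s1))
})

test_that("diversity metrics bundle Neff, DOPs, percent scorecons and taxa", {
  aln <- make_msa(20, 10, conserved_columns = 1:6, identity_target = 0.6,
                  seed = 5)
  dm <- diversity_metrics(aln)
  expect_gte(dm$neff, 1); expect_lte(dm$neff, 10)
  expect_gte(dm$dops, 0); expect_lte(dm$dops, 100)
  expect_gte(dm$percent_scorecons, 0)
  expect_equal(dm$n_taxa, length(unique(aln$taxon)))
  no_tax <- msa(c("a", "b"), c("AC", "AC"))
  expect_equal(diversity_metrics(no_tax)$n_taxa, 0L)
})
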