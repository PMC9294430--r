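# Disease-versus-polymorphism contrasts: Table-style percentage summary,
# Mann-Whitney tests and amino-acid composition enrichment.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The p-value is exact
#' (by enumeration of the U distribution) when the combined sample size is
#' at most 14 and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y numeric samples (each of size >= 1).
#' @return list with `U` (the statistic of `x` relative to `y`), `p`
#'   (two-sided), `n1`, `n2` and `exact`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 14L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y), exact = exact)
}

#' Amino-acid composition enrichment
#'
#' Relative enrichment of each amino acid in a sample of (mutant) residues
#' against a background frequency vector, with a seeded bootstrap p-value:
#' `ratio = (f_sample - f_background) / f_background`; the two-sided p is
#' the fraction of `n_boot` multinomial resamples of the background (at the
#' sample's own size) whose frequency deviates from the background at least
#' as much as observed (with an add-one correction so p stays in (0, 1]).
#' Unknown residues (`X`) are excluded. A background frequency of zero for
#' an observed amino acid yields an undefined (`NA`) ratio.
#'
#' @param sample_aa character vector of one-letter residues, or a named
#'   count vector.
#' @param background named background frequencies (must sum to 1); default
#'   is the bundled SwissProt composition.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param bh logical; add Benjamini-Hochberg adjusted p-values.
#' @return data.frame with one row per amino acid: `aa`, `count`,
#'   `f_sample`, `f_background`, `ratio`, `p` (and `p_adj` when `bh`).
#' @export
composition_enrichment <- function(sample_aa, background = SWISSPROT_FREQ,
                                   n_boot = 10000, seed = 1L, bh = FALSE) {
  if (is.null(names(sample_aa))) {
    sample_aa <- sample_aa[sample_aa %in% AA1]
    counts <- table(factor(sample_aa, levels = AA1))
  } else {
    counts <- setNames(rep(0, 20), AA1)
    counts[names(sample_aa)] <- sample_aa
  }
  counts <- as.numeric(counts)
  n <- sum(counts)
  stopifnot(n >= 1)
  bg <- background[AA1]
  stopifnot(abs(sum(bg) - 1) < 1e-6)
  fs <- counts / n
  ratio <- ifelse(bg > 0, (fs - bg) / bg, NA_real_)
  obs_dev <- abs(fs - bg)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  boot <- rmultinom(n_boot, size = n, prob = bg) / n   # 20 x n_boot
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  exceed <- rowSums(abs(boot - bg) >= obs_dev - 1e-12)
  p <- (1 + exceed) / (1 + n_boot)
  out <- data.frame(aa = AA1, count = counts, f_sample = fs,
                    f_background = unname(bg), ratio = ratio, p = p)
  if (bh) out$p_adj <- stats::p.adjust(p, method = "BH")
  rownames(out) <- NULL
  out
}

# percentage helper: NA when the denominator is empty
#' @keywords internal
pct <- function(flag) {
  flag <- flag[!is.na(flag)]
  if (length(flag) == 0L) NA_real_ else 100 * mean(flag)
}

#' Compare disease-associated mutations against polymorphisms
#'
#' Builds the cohort contrast from quality-gated verdicts: per class, the
#' percentage of mutations (and of unique residue positions) that are in or
#' near a predicted functional site, destabilizing (FoldX `ddG > 1`),
#' buried (`RSA < 20`) and pathogenic (`score > 0.611`); Mann-Whitney tests
#' on the pathogenicity score, RSA and ddG distributions; and composition
#' enrichment of the disease-class mutant residues against a background.
#'
#' @param verdicts a `mutation_verdicts` data.frame (rows of both classes,
#'   typically concatenated over proteins).
#' @param mode `"mutations"` (default) or `"positions"`: the observation
#'   unit for the Mann-Whitney tests. Percentages are always reported at
#'   both granularities.
#' @param background background composition for
#'   [composition_enrichment()].
#' @param n_boot,seed bootstrap settings for the enrichment.
#' @param config a [default_config()] (not used for re-thresholding -- the
#'   verdict flags are taken as rendered -- only recorded).
#' @return object of class `cohort_summary`: list with `percentages`
#'   (data.frame: metric, disease, polymorphism, at both granularities),
#'   `denominators`, `tests` (Mann-Whitney results per metric),
#'   `enrichment`, `mode` and the raw gated per-class values.
#' @export
compare_cohorts <- function(verdicts, mode = c("mutations", "positions"),
                            background = SWISSPROT_FREQ, n_boot = 10000,
                            seed = 1L, config = default_config()) {
  mode <- match.arg(mode)
  v <- verdicts[verdicts$quality_ok & verdicts$category %in%
                  c("disease", "polymorphism"), , drop = FALSE]
  cls <- split(v, factor(v$category, levels = c("disease", "polymorphism")))
  if (any(vapply(cls, nrow, 1L) == 0L))
    warning("empty class: percentages undefined for it")

  near_fun <- function(d) d$near_ligand | d$near_interface | d$near_conserved
  per_class <- function(d, unit) {
    if (unit == "positions") {
      agg <- function(flag) {
        tapply(flag, paste(d$accession, d$position), function(z) any(z, na.rm = TRUE))
      }
      data.frame(
        near_functional_site = pct(agg(near_fun(d))),
        destabilizing = pct(agg(d$destabilizing_foldx)),
        buried = pct(agg(d$buried)),
        pathogenic = pct(agg(d$pathogenic)),
        n = length(unique(paste(d$accession, d$position)))
      )
    } else {
      data.frame(
        near_functional_site = pct(near_fun(d)),
        destabilizing = pct(d$destabilizing_foldx),
        buried = pct(d$buried),
        pathogenic = pct(d$pathogenic),
        n = nrow(d)
      )
    }
  }
  mk_table <- function(unit) {
    di <- per_class(cls$disease, unit)
    po <- per_class(cls$polymorphism, unit)
    data.frame(metric = c("near_functional_site", "destabilizing", "buried",
                          "pathogenic"),
               disease = as.numeric(di[1, 1:4]),
               polymorphism = as.numeric(po[1, 1:4]),
               unit = unit)
  }
  percentages <- rbind(mk_table("mutations"), mk_table("positions"))
  denominators <- c(
    disease_mutations = nrow(cls$disease),
    polymorphism_mutations = nrow(cls$polymorphism),
    disease_positions = length(unique(paste(cls$disease$accession,
                                            cls$disease$position))),
    polymorphism_positions = length(unique(paste(cls$polymorphism$accession,
                                                 cls$polymorphism$position)))
  )
  vals <- function(d, col) {
    x <- d[[col]]
    if (mode == "positions") {
      x <- tapply(x, paste(d$accession, d$position),
                  function(z) mean(z, na.rm = TRUE))
      x <- as.numeric(x)
    }
    x[!is.na(x)]
  }
  tests <- lapply(c(pathogenicity = "patho_score", rsa = "rsa",
                    ddg = "foldx_ddg"),
                  function(col) {
                    x <- vals(cls$disease, col); y <- vals(cls$polymorphism, col)
                    if (length(x) == 0L || length(y) == 0L)
                      return(list(U = NA, p = NA, n1 = length(x),
                                  n2 = length(y), exact = FALSE))
                    mann_whitney(x, y)
                  })
  enrichment <- if (nrow(cls$disease) > 0)
    composition_enrichment(cls$disease$mutant_aa, background, n_boot, seed)
  else NULL
  structure(list(percentages = percentages, denominators = denominators,
                 tests = tests, enrichment = enrichment, mode = mode,
                 disease = cls$disease, polymorphism = cls$polymorphism),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> quality-gated mutations: disease",
      x$denominators["disease_mutations"], "/ polymorphism",
      x$denominators["polymorphism_mutations"], "\n")
  p <- x$percentages[x$percentages$unit == "mutations", 1:3]
  p$disease <- round(p$disease, 1); p$polymorphism <- round(p$polymorphism, 1)
  print(p, row.names = FALSE)
  cat("Mann-Whitney two-sided p:",
      paste(names(x$tests),
            vapply(x$tests, function(t) format.pval(t$p, digits = 3), ""),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cohort_summary <- function(object, ...) {
  enr <- object$enrichment
  sig <- if (!is.null(enr)) enr$aa[enr$p < 0.05 & enr$ratio > 0] else character(0)
  out <- list(percentages = object$percentages,
              denominators = object$denominators,
              p_values = vapply(object$tests, `[[`, 0, "p"),
              enriched_aa = sig)
  class(out) <- "summary.cohort_summary"
  out
}

#' @export
print.summary.cohort_summary <- function(x, ...) {
  print(x$percentages, row.names = FALSE)
  cat("p-values:", paste(names(x$p_values),
                         format.pval(x$p_values, digits = 3),
                         sep = "=", collapse = ", "), "\n")
  cat("enriched mutant residues (p<0.05):",
      paste(x$enriched_aa, collapse = " "), "\n")
  invisible(x)
}

#' Density plots of the cohort contrast
#'
#' Draws the distribution of pathogenicity scores, FoldX ddG and relative
#' solvent accessibility for the disease and polymorphism classes, with the
#' decision cutoffs (0.611, 1 and 20 under the defaults) as dashed lines.
#'
#' @param x a `cohort_summary`.
#' @param config a [default_config()] supplying the cutoff lines.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.cohort_summary <- function(x, config = default_config(), ...) {
  panels <- list(
    list(col = "patho_score", cut = config$patho_cut, lab = "pathogenicity score"),
    list(col = "foldx_ddg", cut = config$foldx_cut, lab = "ddG (kcal/mol)"),
    list(col = "rsa", cut = config$rsa_cut, lab = "RSA (%)")
  )
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (p in panels) {
    d <- x$disease[[p$col]]; q <- x$polymorphism[[p$col]]
    d <- d[!is.na(d)]; q <- q[!is.na(q)]
    if (length(d) < 2 || length(q) < 2) next
    dd <- stats::density(d); dq <- stats::density(q)
    graphics::plot(dd, col = "blue", main = p$lab, xlab = p$lab,
                   ylim = range(0, dd$y, dq$y))
    graphics::lines(dq, col = "red")
    graphics::abline(v = p$cut, lty = 2)
    graphics::legend("topright", legend = c("disease", "polymorphism"),
                     col = c("blue", "red"), lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
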