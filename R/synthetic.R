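# Synthetic input bundles with known ground truth: toy structures, paired
# second models, alignments with controlled conservation, predictor tables
# and labelled mutation cohorts with planted effects. Ground-truth labels
# are computed at generation time by direct application of the decision
# rules (plain distance checks and threshold comparisons, independent of
# the pipeline's cell-list/annotation code) and stored alongside the data.

# run expr with a private RNG stream; the caller's stream is untouched
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# documented per-protein seed fan-out: depends only on the global seed and
# the protein index, so bundles are stable when n_proteins changes
#' @keywords internal
fanout_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

#' @keywords internal
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# CA trace builders ---------------------------------------------------------

#' @keywords internal
ca_helix <- function(n) {
  # ideal alpha-helix: rise 1.5 A, twist 100 degrees; radius chosen so the
  # CA-CA distance is exactly 3.8 A
  rise <- 1.5; twist <- 100 * pi / 180
  r <- sqrt(3.8^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(n) - 1
  cbind(r * cos(i * twist), r * sin(i * twist), rise * i)
}

#' @keywords internal
ca_sheet_pair <- function(n) {
  k <- ceiling(n / 2)
  s1 <- cbind(3.8 * (seq_len(k) - 1), 0, 0)
  s2 <- cbind(3.8 * ((n - k):1 - 1), 4.8, 0)
  rbind(s1, s2)
}

#' @keywords internal
ca_compact_coil <- function(n) {
  # compact self-avoiding walk: 3.8 A steps, >= 3.65 A from earlier CAs,
  # confined near the running centroid so a globule with a buried core forms
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- 0
  # confinement tuned so roughly a fifth of residues end up buried
  # (RSA < 20), the burial background typical of globular domains
  rconf <- 3.9 * n^(1 / 3) + 2
  for (i in 2:n) {
    placed <- FALSE
    best <- NULL; best_d <- -Inf
    ctr <- colMeans(pos[seq_len(i - 1), , drop = FALSE])
    for (try in seq_len(250)) {
      u <- unit_vec(rnorm(3))
      cand <- pos[i - 1, ] + 3.8 * u
      dmin <- if (i > 2)
        sqrt(min(rowSums(sweep(pos[seq_len(i - 2), , drop = FALSE], 2, cand)^2)))
      else Inf
      if (dmin > best_d) { best_d <- dmin; best <- cand }
      if (dmin >= 3.65 && sqrt(sum((cand - ctr)^2)) <= rconf) {
        pos[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) pos[i, ] <- best   # bounded relaxation keeps determinism
  }
  pos
}

#' Generate a synthetic structure model
#'
#' Builds an ideal-geometry backbone (CA-CA 3.8 Angstrom) with N, C, O and
#' CB pseudo-atoms (no CB for glycine) in one of three folds, and draws
#' per-residue confidence from a two-regime profile: a high-confidence core
#' (normal, mean 85, sd 5) and low-confidence termini (mean 55, sd 8),
#' clipped to `[0, 100]`. Coordinates are rounded to 3 decimals and
#' confidences to 2, so written PDB files round-trip exactly.
#'
#' @param n_res number of residues (>= 5).
#' @param fold `"helix"`, `"sheet-pair"` or `"coil"` (a compact globule
#'   with a buried core).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param start first residue number.
#' @param termini_frac total fraction of residues in the low-confidence
#'   termini (split between the two ends).
#' @param model_id identifier.
#' @param sequence optional one-letter sequence (random if `NULL`).
#' @return a [protein_model()] (alphafold-like) with an integer vector
#'   attribute `termini` marking the low-confidence residue numbers.
#' @export
make_structure <- function(n_res, fold = c("helix", "sheet-pair", "coil"),
                           seed = 1L, start = 1L, termini_frac = 0.2,
                           model_id = paste0("synth_", fold, "_", seed),
                           sequence = NULL) {
  fold <- match.arg(fold)
  stopifnot(n_res >= 5L)
  with_seed(seed, {
    ca <- switch(fold,
                 "helix" = ca_helix(n_res),
                 "sheet-pair" = ca_sheet_pair(n_res),
                 "coil" = ca_compact_coil(n_res))
    if (is.null(sequence)) {
      sequence <- paste(sample(AA1, n_res, replace = TRUE), collapse = "")
    }
    aa <- strsplit(sequence, "")[[1]]
    stopifnot(length(aa) == n_res)

    k <- max(1L, round(termini_frac * n_res / 2))
    low <- c(seq_len(k), (n_res - k + 1L):n_res)
    conf <- numeric(n_res)
    conf[-low] <- rnorm(n_res - length(low), 85, 5)
    conf[low] <- rnorm(length(low), 55, 8)
    conf <- round(pmin(100, pmax(0, conf)), 2)

    atoms <- vector("list", n_res)
    for (i in seq_len(n_res)) {
      p <- ca[i, ]
      t <- unit_vec(if (i == 1) ca[2, ] - ca[1, ]
                    else if (i == n_res) ca[n_res, ] - ca[n_res - 1, ]
                    else ca[i + 1, ] - ca[i - 1, ])
      ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      n1 <- unit_vec(cross3(t, ref))
      n2 <- cross3(t, n1)
      xyz <- rbind(
        N  = p - 1.20 * t + 0.60 * n1,
        CA = p,
        C  = p + 1.20 * t + 0.60 * n1,
        O  = p + 1.80 * t + 0.60 * n1 + 1.23 * n2,
        CB = p - 0.60 * t - 0.80 * n1 + 1.10 * n2
      )
      nm <- rownames(xyz)
      if (aa[i] == "G") { xyz <- xyz[-5, , drop = FALSE]; nm <- nm[-5] }
      atoms[[i]] <- data.frame(
        resno = start - 1L + i, resid = unname(AA1TO3[aa[i]]), elety = nm,
        element = substr(nm, 1, 1),
        x = round(xyz[, 1], 3), y = round(xyz[, 2], 3), z = round(xyz[, 3], 3),
        b = conf[i])
    }
    m <- protein_model(model_id, "alphafold-like", do.call(rbind, atoms))
    attr(m, "termini") <- start - 1L + low
    m
  })
}

#' Perturb a model into a synthetic second prediction
#'
#' Applies a random rigid motion plus per-atom Gaussian noise calibrated so
#' the CA RMSD after Kabsch superposition hits `target_rmsd` (the noise sd
#' is `target / sqrt(3 (1 - 2/n))`, the expected fitted RMSD of iid
#' noise). Confidences are rounded to whole numbers without crossing the
#' 70-gate (so both models gate identically), and the result is tagged
#' `rosettafold-like` so it is written on the 0--1 confidence scale.
#'
#' @param model a [protein_model()].
#' @param target_rmsd requested CA RMSD in Angstrom.
#' @param seed integer seed.
#' @param model_id identifier for the new model.
#' @return a [protein_model()].
#' @export
perturb_model <- function(model, target_rmsd = 1.7, seed = 1L,
                          model_id = paste0(model$model_id, "_m2")) {
  with_seed(seed, {
    a <- model$atoms
    X <- as.matrix(a[, c("x", "y", "z")])
    n_ca <- sum(a$elety == "CA")
    s <- target_rmsd / sqrt(3 * (1 - 2 / n_ca))
    # random proper rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- runif(3, -20, 20)
    N <- matrix(rnorm(length(X), 0, s), ncol = 3)
    base <- X %*% R + matrix(shift, nrow(X), 3, byrow = TRUE)
    # rescale the drawn noise so the realized fitted CA RMSD hits the target
    ca <- a$elety == "CA"
    r1 <- kabsch_rmsd(X[ca, , drop = FALSE], (base + N)[ca, , drop = FALSE])$rmsd
    N <- N * (target_rmsd / r1)
    Y <- base + N
    a$x <- round(Y[, 1], 3); a$y <- round(Y[, 2], 3); a$z <- round(Y[, 3], 3)
    conf <- model$residues$confidence
    conf2 <- ifelse(conf >= 70, pmax(70, round(conf)), pmin(69, round(conf)))
    a$b <- conf2[match(a$resno, model$residues$number)] / 100
    m <- protein_model(model_id, "rosettafold-like", a)
    attr(m, "termini") <- attr(model, "termini")
    m
  })
}

#' Generate a synthetic alignment with controlled conservation
#'
#' The query is the given (or random) sequence; `conserved_columns` are
#' kept invariant across all sequences, `hyper_variable` columns are
#' mutated at rate 0.9, and the remaining columns are mutated per sequence
#' at the rate that makes the expected mean pairwise identity equal
#' `identity_target` (or at `variable_rate` when given). Sequences carry
#' deterministic `TaxID` metadata drawn from a shared pool.
#'
#' @param length number of columns.
#' @param depth number of sequences (>= 2).
#' @param conserved_columns integer column indices kept invariant.
#' @param identity_target expected mean pairwise identity in `[0, 1]`.
#' @param seed integer seed.
#' @param query optional query sequence (length `length`).
#' @param hyper_variable column indices forced to near-maximal variability.
#' @param variable_rate optional explicit per-column mutation rate
#'   overriding the one derived from `identity_target`.
#' @return an [msa()].
#' @export
make_msa <- function(length, depth, conserved_columns = integer(0),
                     identity_target = 0.5, seed = 1L, query = NULL,
                     hyper_variable = integer(0), variable_rate = NULL) {
  stopifnot(depth >= 2L, length >= 1L)
  with_seed(seed, {
    if (is.null(query)) query <- paste(sample(AA1, length, replace = TRUE),
                                       collapse = "")
    q <- strsplit(query, "")[[1]]
    stopifnot(base::length(q) == length)
    fc <- base::length(setdiff(conserved_columns, hyper_variable)) / length
    if (is.null(variable_rate)) {
      tp <- (identity_target - fc) / max(1e-9, 1 - fc)
      tp <- min(1, max(0, tp))
      disc <- 1 - (20 / 19) * (1 - tp)
      r <- if (disc <= 0) 1 else (1 - sqrt(disc)) * 19 / 20
    } else r <- variable_rate
    ali <- matrix(rep(q, depth), nrow = depth, byrow = TRUE)
    var_cols <- setdiff(seq_len(length), conserved_columns)
    rate <- ifelse(var_cols %in% hyper_variable, 0.9, r)
    for (s in 2:depth) {
      mut <- var_cols[runif(base::length(var_cols)) < rate]
      if (base::length(mut)) {
        ali[s, mut] <- vapply(q[mut], function(w)
          sample(setdiff(AA1, w), 1L), "")
      }
    }
    ids <- c("query", paste0("hom", seq_len(depth - 1L) + 1L))
    pool <- max(2L, round(depth * 0.7))
    taxon <- 1000L + (seq_len(depth) * 13L) %% pool
    msa(ids, apply(ali, 1L, paste, collapse = ""), taxon = taxon)
  })
}

#' Cohort generation settings
#'
#' Defines the study conditions for a synthetic disease/polymorphism
#' cohort: sizes, planted effect sizes and the global seed. The defaults
#' are the conditions the package's own validation runs on: 20 proteins,
#' 200 disease and 200 polymorphism mutations, a 0.6 probability that a
#' disease mutation is placed at a buried residue, a +1.5 kcal/mol ddG
#' shift for the disease class, class-specific pathogenicity Beta
#' distributions, and 60 percent of disease mutations placed within 5
#' Angstrom of a planted functional site.
#'
#' @param n_proteins number of proteins.
#' @param n_res residue-count range per protein (length-2 integer).
#' @param depth alignment depth.
#' @param n_disease,n_polymorphism total mutation counts per class.
#' @param burial_bias probability a disease mutation is placed buried.
#' @param ddg_shift additive ddG shift (kcal/mol) for the disease class.
#' @param ddg_base_mean,ddg_base_sd baseline (polymorphism) ddG normal
#'   parameters.
#' @param patho_beta_disease,patho_beta_polymorphism `c(shape1, shape2)` of
#'   the per-class pathogenicity Beta distributions.
#' @param fraction_near_site fraction of disease mutations placed within 5
#'   Angstrom of a planted site.
#' @param fraction_near_site_polymorphism same placement fraction for the
#'   polymorphism class (lower by default: neutral variants sit near
#'   functional sites less often).
#' @param ungated_frac fraction of mutations placed at low-confidence
#'   residues (excluded by the quality gate downstream).
#' @param identity_target alignment identity for variable columns.
#' @param model2_rmsd target CA RMSD of the perturbed second model.
#' @param frac_model2_extra fraction of proteins given one extra planted
#'   interface site visible only to the second model (consensus
#'   "additional" explanations).
#' @param noiseless logical; force clear margins around every decision
#'   threshold so pipeline verdicts equal the stored ground truth exactly.
#' @param seed global seed; per-protein seeds are fanned out as
#'   `(seed * 1000003 + i * 7919) mod (2^31 - 1)`.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_proteins = 20L, n_res = c(90L, 130L), depth = 30L,
                        n_disease = 200L, n_polymorphism = 200L,
                        burial_bias = 0.6, ddg_shift = 1.5,
                        ddg_base_mean = 0.35, ddg_base_sd = 1,
                        patho_beta_disease = c(5, 2.4),
                        patho_beta_polymorphism = c(2, 3),
                        fraction_near_site = 0.6,
                        fraction_near_site_polymorphism = 0.4,
                        ungated_frac = 0.1,
                        identity_target = 0.45, model2_rmsd = 1.7,
                        frac_model2_extra = 0.15, noiseless = FALSE,
                        seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_proteins >= 1, all(n_res >= 50), n_disease >= 0,
            n_polymorphism >= 0,
            burial_bias >= 0, burial_bias <= 1,
            fraction_near_site >= 0, fraction_near_site <= 1,
            fraction_near_site_polymorphism >= 0,
            fraction_near_site_polymorphism <= 1,
            ungated_frac >= 0, ungated_frac <= 1,
            model2_rmsd > 0)
  class(spec) <- c("cohort_spec", "list")
  spec
}

# mutant residues: disease mutants mildly favor the residue types enriched
# among human disease mutations (C, H, P, R, S, W)
#' @keywords internal
draw_mutant <- function(wild, category) {
  pool <- setdiff(AA1, wild)
  w <- rep(1, length(pool))
  if (category == "disease")
    w[pool %in% c("C", "H", "P", "R", "S", "W")] <- 2.5
  sample(pool, 1L, prob = w / sum(w))
}

# direct (brute-force) check: residues within `radius` (heavy-atom) of any
# site member, site members included; independent of the cell-list code
#' @keywords internal
direct_near_set <- function(model, site, radius = 5.0) {
  if (length(site) == 0L) return(integer(0))
  res <- model$residues$number
  sc <- lapply(site, function(s) residue_coords(model, s))
  near <- vapply(res, function(p) {
    if (p %in% site) return(TRUE)
    a <- residue_coords(model, p)
    for (b in sc) {
      d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
      if (min(d2) <= radius^2) return(TRUE)
    }
    FALSE
  }, TRUE)
  res[near]
}

# margin-forcing for noiseless bundles: push values away from a threshold
#' @keywords internal
force_margin <- function(x, threshold, margin) {
  lo <- x <= threshold & x > threshold - margin
  hi <- x > threshold & x < threshold + margin
  x[lo] <- threshold - margin
  x[hi] <- threshold + margin
  x
}

#' Generate predictor tables for a synthetic protein
#'
#' Ligand-binding probabilities are high (clearly above 0.5) on the
#' planted ligand residues and low elsewhere; interface scores likewise
#' around the 0.34 operating point; disorder probabilities are high on the
#' low-confidence termini. Per-mutation ddG values are normal with the
#' class shift from the cohort spec (FoldX convention; the DynaMut2 column
#' is anti-correlated with it), and pathogenicity scores are Beta-drawn
#' per class. In noiseless mode every value keeps a clear margin from its
#' decision threshold.
#'
#' @param model a [protein_model()] (with the `termini` attribute from
#'   [make_structure()]).
#' @param planted_ligand,planted_interface integer residue sets.
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param mutations optional [mutation_table()]; when given, the
#'   per-mutation ddG/pathogenicity tables cover exactly its rows.
#' @return a [predictor_tables()].
#' @export
make_predictors <- function(model, planted_ligand = integer(0),
                            planted_interface = integer(0),
                            spec = cohort_spec(), seed = 1L,
                            mutations = NULL) {
  with_seed(seed, {
    res <- model$residues$number
    termini <- attr(model, "termini")
    if (is.null(termini)) termini <- integer(0)
    lig <- runif(length(res), 0.01, 0.40)
    lig[res %in% planted_ligand] <- runif(sum(res %in% planted_ligand), 0.60, 0.95)
    ifc <- runif(length(res), 0.00, 0.25)
    ifc[res %in% planted_interface] <- runif(sum(res %in% planted_interface), 0.45, 0.90)
    dis <- runif(length(res), 0.02, 0.45)
    dis[res %in% termini] <- runif(sum(res %in% termini), 0.55, 0.95)
    if (is.null(mutations)) {
      mutations <- mutation_table(data.frame(
        accession = model$model_id, position = res,
        wild_aa = model$residues$aa,
        mutant_aa = vapply(model$residues$aa, function(w)
          sample(setdiff(AA1, w), 1L), ""),
        category = "unclassified", disease_name = "",
        stringsAsFactors = FALSE))
    }
    nmut <- nrow(mutations)
    ddg <- rnorm(nmut, spec$ddg_base_mean, spec$ddg_base_sd) +
      ifelse(mutations$category == "disease", spec$ddg_shift, 0)
    pb <- ifelse(mutations$category == "disease",
                 list(spec$patho_beta_disease),
                 list(spec$patho_beta_polymorphism))
    patho <- vapply(pb, function(b) rbeta(1, b[1], b[2]), 0)
    dyn <- -0.6 * ddg + rnorm(nmut, 0, 0.4)
    if (isTRUE(spec$noiseless)) {
      ddg <- force_margin(ddg, 1, 0.2)
      patho <- pmin(0.999, pmax(0.001, force_margin(patho, 0.611, 0.02)))
      dyn <- force_margin(dyn, 0, 0.1)
    }
    predictor_tables(
      ligand_prob = setNames(round(lig, 4), res),
      interface_score = setNames(round(ifc, 4), res),
      foldx_ddg = data.frame(position = mutations$position,
                             mutant = mutations$mutant_aa,
                             value = round(ddg, 4)),
      dynamut_ddg = data.frame(position = mutations$position,
                               mutant = mutations$mutant_aa,
                               value = round(dyn, 4)),
      pathogenicity = data.frame(position = mutations$position,
                                 mutant = mutations$mutant_aa,
                                 value = round(patho, 4)),
      disorder_prob = setNames(round(dis, 4), res),
      model = model)
  })
}

# spatially contiguous planted site: a seed residue plus its k nearest
# residues by CA distance. Seeds are drawn from high-confidence residues,
# preferring solvent-exposed ones: ligand pockets and interfaces are
# surface features.
#' @keywords internal
plant_site <- function(model, k, exclude = integer(0), rsa = NULL) {
  res <- model$residues
  ca <- model$atoms[model$atoms$elety == "CA", ]
  core <- res$number[res$confidence >= 70 & !(res$number %in% exclude)]
  if (length(core) == 0L) core <- res$number
  if (!is.null(rsa)) {
    exposed <- core[rsa[match(core, res$number)] >= 30]
    if (length(exposed) > 0L) core <- exposed
  }
  seed_res <- sample(core, 1L)
  p0 <- as.numeric(ca[ca$resno == seed_res, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(as.matrix(ca[, c("x", "y", "z")]), 2, p0)^2))
  cand <- ca$resno[order(d)]
  cand <- cand[!(cand %in% exclude)]
  sort(head(cand, k))
}

#' Generate a complete synthetic cohort bundle
#'
#' For each protein: a compact-globule structure model with a
#' two-regime confidence profile, a perturbed second model (target CA RMSD
#' from the spec, rosettafold-like 0--1 confidence scale), an alignment
#' whose planted conserved columns score 1, predictor tables with planted
#' ligand/interface sites, and disease/polymorphism mutations placed
#' according to the spec's effect sizes. A stored ground-truth table marks,
#' for every mutation, whether it should be explained under the decision
#' rules (computed by direct distance/threshold checks, not by the
#' pipeline), whether it passes the confidence gate, and whether it was
#' planted as a second-model-only ("additional") explanation.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort_bundle` with `spec` and `proteins`, a
#'   named list whose elements hold `model1`, `model2`, `msa`, `tables1`,
#'   `tables2`, `mutations`, `segment`, `planted` and `truth`; plus a
#'   combined `truth` data.frame.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  np <- spec$n_proteins
  nd <- split_count(spec$n_disease, np)
  npl <- split_count(spec$n_polymorphism, np)
  fam <- rep(c("CATH", "Pfam", "unassigned"), length.out = np)
  proteins <- vector("list", np)
  names(proteins) <- sprintf("SYN%03d", seq_len(np))
  for (i in seq_len(np)) {
    proteins[[i]] <- make_cohort_protein(
      accession = names(proteins)[i], spec = spec,
      seed = fanout_seed(spec$seed, i),
      n_disease = nd[i], n_polymorphism = npl[i], family_class = fam[i],
      plant_extra_model2 = i <= ceiling(spec$frac_model2_extra * np))
  }
  truth <- do.call(rbind, lapply(proteins, `[[`, "truth"))
  rownames(truth) <- NULL
  structure(list(spec = spec, proteins = proteins, truth = truth),
            class = "cohort_bundle")
}

#' @rdname make_cohort
#' @export
simulate_cohort <- make_cohort

#' @keywords internal
split_count <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + as.integer(seq_len(k) <= extra)
}

#' @keywords internal
make_cohort_protein <- function(accession, spec, seed, n_disease,
                                n_polymorphism, family_class,
                                plant_extra_model2 = FALSE) {
  model1 <- local({
    nr <- with_seed(seed, sample(seq(spec$n_res[1], spec$n_res[2]), 1L))
    make_structure(nr, "coil", seed = seed, model_id = accession)
  })
  res <- model1$residues
  n_res <- nrow(res)

  with_seed(seed + 1L, {
    acc_prof <- accessibility_profile(model1, n_points = 240)
    buried_set <- acc_prof$number[!is.na(acc_prof$rsa) & acc_prof$rsa < 20]

    lig <- plant_site(model1, 4L, rsa = acc_prof$rsa)
    ifc <- plant_site(model1, 6L, exclude = lig, rsa = acc_prof$rsa)
    extra_cons <- plant_site(model1, 4L, exclude = c(lig, ifc),
                             rsa = acc_prof$rsa)
    cons <- sort(unique(c(sample(lig, 2L), sample(ifc, 2L), extra_cons)))
    planted_all <- sort(unique(c(lig, ifc, cons)))

    gated <- res$number[res$confidence >= 70]
    ungated <- setdiff(res$number, gated)
    near_set <- direct_near_set(model1, planted_all, 5.0)
    far_set <- setdiff(res$number, near_set)

    if ((n_disease > 0 && spec$fraction_near_site > 0 ||
         n_polymorphism > 0 && spec$fraction_near_site_polymorphism > 0) &&
        length(intersect(gated, near_set)) == 0L)
      stop("infeasible placement: no quality-gated residue lies within ",
           "5 A of a planted site")

    place_one <- function(category) {
      pool <- if (runif(1) < spec$ungated_frac && length(ungated) > 0)
        ungated
      else gated
      f_near <- if (category == "disease") spec$fraction_near_site
                else spec$fraction_near_site_polymorphism
      want_near <- runif(1) < f_near
      sub <- intersect(pool, if (want_near) near_set else far_set)
      if (length(sub) == 0L) sub <- pool
      if (category == "disease") {
        rsa_sub <- acc_prof$rsa[match(sub, acc_prof$number)]
        if (runif(1) < spec$burial_bias) {
          b <- intersect(sub, buried_set)
          # no buried residue available: take the most buried one instead
          sub <- if (length(b) > 0L) b else sub[which.min(rsa_sub)]
        } else {
          u <- setdiff(sub, buried_set)
          sub <- if (length(u) > 0L) u else sub[which.max(rsa_sub)]
        }
      }
      pool <- sub
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }

    rows <- list()
    for (k in seq_len(n_disease + n_polymorphism)) {
      category <- if (k <= n_disease) "disease" else "polymorphism"
      for (try in 1:50) {
        p <- place_one(category)
        w <- res$aa[res$number == p]
        m <- draw_mutant(w, category)
        key <- paste(p, m)
        if (!key %in% names(rows)) break
      }
      rows[[key]] <- data.frame(accession = accession, position = p,
                                wild_aa = w, mutant_aa = m,
                                category = category, disease_name = "",
                                stringsAsFactors = FALSE)
    }
    mut <- do.call(rbind, unname(rows))
    # disease labels: mutations near the same planted site share a disease
    is_d <- mut$category == "disease"
    near_lig <- mut$position %in% direct_near_set(model1, lig, 5.0)
    near_ifc <- mut$position %in% direct_near_set(model1, ifc, 5.0)
    lab <- rep("", nrow(mut))
    lab[is_d & near_lig] <- paste0("DIS-", accession, "-A")
    lab[is_d & !near_lig & near_ifc] <- paste0("DIS-", accession, "-B")
    solo <- which(is_d & lab == "")
    lab[solo] <- paste0("DIS-", accession, "-S", seq_along(solo))
    mut$disease_name <- lab
    mut <- mutation_table(mut)

    mrate <- if (isTRUE(spec$noiseless)) 0.8 else NULL
    hv <- if (isTRUE(spec$noiseless))
      setdiff(unique(mut$position), c(cons, direct_near_set(model1, cons, 5.0)))
    else integer(0)
    aln <- make_msa(n_res, spec$depth,
                    conserved_columns = cons - res$number[1] + 1L,
                    identity_target = spec$identity_target,
                    seed = seed + 2L,
                    query = paste(res$aa, collapse = ""),
                    hyper_variable = hv - res$number[1] + 1L,
                    variable_rate = mrate)

    tables1 <- make_predictors(model1, lig, ifc, spec, seed + 3L, mut)
    model2 <- perturb_model(model1, spec$model2_rmsd, seed + 4L,
                            model_id = paste0(accession, "_m2"))

    # second-model site predictions: same planted sites, redrawn noise --
    # optionally plus one extra interface site covering a disease mutation
    # that has no other evidence, so only the second model explains it
    lig2 <- lig; ifc2 <- ifc
    extra_pos <- integer(0)
    if (plant_extra_model2) {
      fx <- tables1$foldx_ddg; pt <- tables1$pathogenicity
      no_evid <- is_d & !(mut$position %in% near_set) &
        !(lookup_mutation_value(fx, mut$position, mut$mutant_aa) > 1) &
        !(lookup_mutation_value(pt, mut$position, mut$mutant_aa) > 0.611) &
        mut$position %in% gated
      if (any(no_evid)) {
        extra_pos <- mut$position[which(no_evid)[1]]
        ifc2 <- sort(unique(c(ifc2, extra_pos)))
      }
    }
    t2 <- make_predictors(model2, lig2, ifc2, spec, seed + 5L, mut)
    # per-mutation predictors are sequence-level: share them across models
    tables2 <- predictor_tables(t2$ligand_prob, t2$interface_score,
                                tables1$foldx_ddg, tables1$dynamut_ddg,
                                tables1$pathogenicity, t2$disorder_prob,
                                model = model2)

    segment <- domain_segment(accession,
                              cbind(res$number[1], res$number[n_res]),
                              family_class)

    # ground truth by direct rule application (no pipeline code)
    fx <- lookup_mutation_value(tables1$foldx_ddg, mut$position, mut$mutant_aa)
    pt <- lookup_mutation_value(tables1$pathogenicity, mut$position, mut$mutant_aa)
    near_cons <- mut$position %in% direct_near_set(model1, cons, 5.0)
    gate_ok <- mut$position %in% gated & mean(res$confidence) >= 70
    truth <- data.frame(
      accession = accession, position = mut$position,
      mutant_aa = mut$mutant_aa, category = mut$category,
      quality_ok = gate_ok,
      near_ligand = near_lig, near_interface = near_ifc,
      near_conserved = near_cons,
      destabilizing = fx > 1, pathogenic = pt > 0.611,
      should_be_explained = near_lig | near_ifc | near_cons |
        fx > 1 | pt > 0.611,
      model2_extra = mut$position %in% extra_pos & mut$category == "disease",
      stringsAsFactors = FALSE)

    list(accession = accession, model1 = model1, model2 = model2, msa = aln,
         tables1 = tables1, tables2 = tables2, mutations = mut,
         segment = segment,
         planted = list(ligand = lig, interface = ifc, conserved = cons,
                        ligand2 = lig2, interface2 = ifc2,
                        extra_positions = extra_pos),
         truth = truth)
  })
}

#' Write / read a cohort bundle as plain-text files
#'
#' Writes, per protein, the exact formats the readers consume: two PDB
#' models (the second on the 0--1 confidence scale), an aligned FASTA, the
#' six predictor TSVs per model, and the mutation TSV; plus a ground-truth
#' sidecar JSON and the spec as YAML at the bundle root. Output is
#' byte-deterministic for a given spec.
#'
#' @param bundle from [make_cohort()].
#' @param dir output directory.
#' @return `dir` (for `write_bundle`) or a `cohort_bundle` (for
#'   `read_bundle`), where `read_bundle` restores models, alignments,
#'   tables, mutations and the ground-truth table.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in bundle$proteins) {
    pd <- file.path(dir, p$accession)
    dir.create(pd, showWarnings = FALSE)
    write_structure(p$model1, file.path(pd, "model1.pdb"))
    write_structure(p$model2, file.path(pd, "model2.pdb"), scale_out = "0-1")
    write_msa(p$msa, file.path(pd, "msa.fasta"))
    write_predictors(p$tables1, file.path(pd, "predictors1"))
    write_predictors(p$tables2, file.path(pd, "predictors2"))
    write_mutations(p$mutations, file.path(pd, "mutations.tsv"))
    seg <- data.frame(start = p$segment$ranges[, 1], end = p$segment$ranges[, 2],
                      family_class = p$segment$family_class)
    write.table(seg, file.path(pd, "segment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(p$planted, file.path(pd, "planted.json"),
                         auto_unbox = FALSE, digits = NA)
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  sp <- bundle$spec
  class(sp) <- NULL
  yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  sp <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  spec <- do.call(cohort_spec, sp)
  accs <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  tr <- as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                          simplifyVector = TRUE))
  proteins <- lapply(accs, function(a) {
    pd <- file.path(dir, a)
    seg <- read.delim(file.path(pd, "segment.tsv"))
    model1 <- read_structure(file.path(pd, "model1.pdb"), "alphafold-like", a)
    model2 <- read_structure(file.path(pd, "model2.pdb"), "rosettafold-like",
                             paste0(a, "_m2"))
    planted <- jsonlite::read_json(file.path(pd, "planted.json"),
                                   simplifyVector = TRUE)
    list(accession = a, model1 = model1, model2 = model2,
         msa = read_msa(file.path(pd, "msa.fasta")),
         tables1 = read_predictors(file.path(pd, "predictors1"), model1),
         tables2 = read_predictors(file.path(pd, "predictors2"), model2),
         mutations = suppressWarnings(read_mutations(file.path(pd, "mutations.tsv"))),
         segment = domain_segment(a, cbind(seg$start, seg$end),
                                  seg$family_class[1]),
         planted = planted,
         truth = tr[tr$accession == a, , drop = FALSE])
  })
  names(proteins) <- accs
  structure(list(spec = spec, proteins = proteins, truth = tr),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d proteins, %d mutations (%d disease / %d polymorphism), seed %d\n",
              length(x$proteins), nrow(x$truth),
              sum(x$truth$category == "disease"),
              sum(x$truth$category == "polymorphism"), x$spec$seed))
  invisible(x)
}
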