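# The explanation engine: site sets, annotations, verdicts, consensus,
# overlap partition and same-disease clustering.

# small deterministic scaffold shared by several blocks
mk_scaffold <- function(seed = 1, n = 40) {
  m <- make_structure(n, "coil", seed = seed)
  cfg <- default_config()
  nb <- residue_neighbors(m, cfg$radius)
  nb_strict <- residue_neighbors(m, cfg$radius, inclusive = FALSE)
  q <- domain_quality(m)
  acc <- accessibility_profile(m, n_points = 240)
  list(m = m, cfg = cfg, nb = nb, nb_strict = nb_strict, q = q, acc = acc)
}

test_that("site sets apply the printed boundary rules", {
  sc <- mk_scaffold()
  res <- sc$m$residues$number
  lig <- setNames(rep(0.1, length(res)), res)
  lig[c("3", "4")] <- c(0.5, 0.49)
  ifc <- setNames(rep(0.0, length(res)), res)
  ifc[c("7", "8")] <- c(0.34, 0.3399)
  tb <- predictor_tables(lig, ifc,
                         data.frame(position = 1L, mutant = "V", value = 0),
                         data.frame(position = 1L, mutant = "V", value = 0),
                         data.frame(position = 1L, mutant = "V", value = 0.5),
                         setNames(rep(0.1, length(res)), res))
  prof <- structure(data.frame(column = seq_along(res), score = 0.1,
                               position = res),
                    class = c("conservation_profile", "data.frame"))
  ss <- site_sets(tb, prof, sc$nb_strict, sc$cfg)
  expect_equal(ss$ligand, 3L)        # >= 0.5 inclusive, 0.49 excluded
  expect_equal(ss$interface, 7L)     # >= 0.34 inclusive
  expect_length(ss$conserved, 0)
  # random tables equal a direct set comprehension
  set.seed(5)
  for (k in 1:10) {
    lp <- setNames(runif(length(res)), res)
    is_ <- setNames(runif(length(res)), res)
    tbl <- predictor_tables(lp, is_,
                            data.frame(position = 1L, mutant = "V", value = 0),
                            data.frame(position = 1L, mutant = "V", value = 0),
                            data.frame(position = 1L, mutant = "V", value = 0.5),
                            setNames(rep(0.1, length(res)), res))
    sk <- site_sets(tbl, prof, sc$nb_strict, sc$cfg)
    expect_equal(sk$ligand, sort(res[lp >= 0.5]))
    expect_equal(sk$interface, sort(res[is_ >= 0.34]))
  }
})

test_that("position annotation: on-site distance zero, gate blocks verdicts", {
  sc <- mk_scaffold(seed = 2)
  sites <- list(ligand = c(10L, 11L), interface = integer(0),
                conserved = integer(0))
  ann <- annotate_positions(c(10L, 20L), sc$m, sites, sc$nb, sc$acc, sc$q,
                            sc$cfg)
  expect_true(ann$near_ligand[ann$position == 10])
  expect_equal(ann$dist_ligand[ann$position == 10], 0)
  # empty site class: flags false, distance infinite
  expect_false(any(ann$near_interface))
  expect_true(all(is.infinite(ann$dist_interface)))
  # a low-confidence residue fails the gate and gets no verdict downstream
  low <- sc$m$residues$number[sc$m$residues$confidence < 70][1]
  ann2 <- annotate_positions(low, sc$m, sites, sc$nb, sc$acc, sc$q, sc$cfg)
  expect_false(ann2$quality_ok)
  mt <- mutation_table(data.frame(accession = "P", position = low,
                                  wild_aa = sc$m$residues$aa[sc$m$residues$number == low],
                                  mutant_aa = "W", category = "disease",
                                  disease_name = "d"))
  tb <- make_predictors(sc$m, spec = cohort_spec(), seed = 4, mutations = mt)
  verd <- judge_mutations(mt, ann2, tb, sc$cfg)
  expect_true(is.na(verd$explained))
})

test_that("annotation flags equal a naive recomputation on random configurations", {
  sc <- mk_scaffold(seed = 3)
  res <- sc$m$residues$number
  set.seed(31)
  for (k in 1:5) {
    sites <- list(ligand = sort(sample(res, 3)),
                  interface = sort(sample(res, 4)),
                  conserved = sort(sample(res, 3)))
    pos <- sample(res, 8)
    ann <- annotate_positions(pos, sc$m, sites, sc$nb, sc$acc, sc$q, sc$cfg)
    for (i in seq_along(pos)) {
      for (cls in names(sites)) {
        direct <- pos[i] %in% sites[[cls]] ||
          any(vapply(sites[[cls]], function(s)
            min_heavy_atom_distance(residue_coords(sc$m, pos[i]),
                                    residue_coords(sc$m, s)) <= 5, TRUE))
        expect_equal(ann[[paste0("near_", sub("ligand", "ligand", cls))]][i],
                     direct, info = paste(k, pos[i], cls))
      }
    }
  }
})

test_that("verdict rule: destabilizing-only explanation, strict ddG boundary", {
  sc <- mk_scaffold(seed = 4)
  p <- sc$m$residues$number[sc$m$residues$confidence >= 70][1:2]
  mt <- mutation_table(data.frame(
    accession = "P", position = p,
    wild_aa = sc$m$residues$aa[match(p, sc$m$residues$number)],
    mutant_aa = c("W", "W"), category = "disease", disease_name = "d"))
  sites <- list(ligand = integer(0), interface = integer(0),
                conserved = integer(0))
  ann <- annotate_positions(p, sc$m, sites, sc$nb, sc$acc, sc$q, sc$cfg)
  res <- sc$m$residues$number
  tb <- predictor_tables(
    setNames(rep(0, length(res)), res), setNames(rep(0, length(res)), res),
    foldx_ddg = data.frame(position = p, mutant = "W", value = c(1.5, 1.0)),
    dynamut_ddg = data.frame(position = p, mutant = "W", value = c(-0.5, 0.2)),
    pathogenicity = data.frame(position = p, mutant = "W", value = c(0.3, 0.3)),
    setNames(rep(0.1, length(res)), res))
  v <- judge_mutations(mt, ann, tb, sc$cfg)
  expect_true(v$explained[1])
  expect_equal(v$evidence[1], "destabilizing")
  expect_true(v$destabilizing_dynamut[1])
  expect_false(v$destabilizing_foldx[2])   # ddG exactly 1 is not destabilizing
  expect_false(v$explained[2])
  expect_equal(v$evidence[2], "")
})

test_that("explained equals a set-algebra recomputation on a synthetic cohort", {
  b <- make_cohort(tiny_spec(seed = 6))
  p <- b$proteins[[1]]
  ex <- explain_mutations(p$model1, p$msa, p$tables1, p$mutations,
                          segment = p$segment)
  v <- ex$verdicts
  recomputed <- v$near_ligand | v$near_interface | v$near_conserved |
    (!is.na(v$foldx_ddg) & v$foldx_ddg > 1) |
    (!is.na(v$patho_score) & v$patho_score > 0.611)
  expect_equal(v$explained[v$quality_ok], recomputed[v$quality_ok])
  expect_true(all(is.na(v$explained[!v$quality_ok])))
  # evidence tags are consistent with explained
  expect_equal(v$explained[v$quality_ok], (v$evidence != "")[v$quality_ok])
})

test_that("explained is monotone: adding evidence never unexplains", {
  b <- make_cohort(tiny_spec(seed = 7))
  p <- b$proteins[[1]]
  ex1 <- explain_mutations(p$model1, p$msa, p$tables1, p$mutations,
                           segment = p$segment)
  # lower the ligand threshold: strictly more evidence
  cfg2 <- default_config(ligand_prob = 0.2)
  ex2 <- explain_mutations(p$model1, p$msa, p$tables1, p$mutations,
                           segment = p$segment, config = cfg2)
  e1 <- ex1$verdicts$explained; e2 <- ex2$verdicts$explained
  expect_true(all(e2[!is.na(e1) & e1]))
})

test_that("impossible thresholds reduce the explained set to the conserved channel, then to nothing", {
  b <- make_cohort(tiny_spec(seed = 8))
  p <- b$proteins[[1]]
  cfg <- default_config(ligand_prob = 1.1, interface_cut = Inf,
                        foldx_cut = Inf, patho_cut = 1.1)
  ex <- explain_mutations(p$model1, p$msa, p$tables1, p$mutations,
                          segment = p$segment, config = cfg)
  v <- ex$verdicts
  expect_equal(v$explained[v$quality_ok], v$near_conserved[v$quality_ok])
  cfg0 <- default_config(ligand_prob = 1.1, interface_cut = Inf,
                         foldx_cut = Inf, patho_cut = 1.1,
                         cons_high = 1.1, cons_mid = 1.1)
  ex0 <- explain_mutations(p$model1, p$msa, p$tables1, p$mutations,
                           segment = p$segment, config = cfg0)
  expect_false(any(ex0$verdicts$explained[ex0$verdicts$quality_ok]))
})

test_that("consensus: model-2-only evidence is additional, overlap is not, union holds", {
  mkv <- function(expl, gated, near = expl) {
    structure(data.frame(
      accession = "P", position = 1:3, wild_aa = "A",
      mutant_aa = c("V", "W", "Y"), category = "disease", disease_name = "d",
      quality_ok = gated, near_ligand = near, near_interface = FALSE,
      near_conserved = FALSE,
      evidence = ifelse(near, "ligand", ""),
      explained = ifelse(gated, expl, NA)),
      class = c("mutation_verdicts", "data.frame"))
  }
  v1 <- mkv(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE))
  v2 <- mkv(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
  cm <- consensus_merge(list(v1, v2))
  # mutation 2: explained only by model 2; mutation 3: only gated in model 2
  expect_equal(cm$n_additional, 2L)
  # mutation 1 is explained by both: in the site overlap, not additional
  expect_equal(cm$n_overlap_site, 1L)
  expect_true(all(cm$merged$explained))
  # consensus-explained is a superset of each single-model explained set
  for (v in list(v1, v2)) {
    single <- v[!is.na(v$explained) & v$explained, ]
    k <- paste(single$accession, single$position, single$mutant_aa)
    km <- paste(cm$merged$accession, cm$merged$position, cm$merged$mutant_aa)
    expect_true(all(cm$merged$explained[match(k, km)]))
  }
})

test_that("Venn partition counts and the inclusion-exclusion oracle", {
  mkv <- function(L, I, C) {
    structure(data.frame(near_ligand = L, near_interface = I,
                         near_conserved = C),
              class = c("mutation_verdicts", "data.frame"))
  }
  v <- mkv(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE))
  oc <- overlap_counts(v)
  expect_equal(unname(oc$regions[c("ligand", "interface", "conserved")]),
               c(1L, 1L, 1L))
  expect_equal(sum(oc$regions), 3L)
  v2 <- mkv(TRUE, TRUE, FALSE)
  expect_equal(unname(overlap_counts(v2)$regions["ligand+interface"]), 1L)
  set.seed(17)
  for (k in 1:10) {
    n <- 30
    v3 <- mkv(runif(n) < 0.4, runif(n) < 0.4, runif(n) < 0.4)
    oc3 <- overlap_counts(v3)
    # regions partition the >=1-tag set
    expect_equal(sum(oc3$regions), oc3$n_any_site)
    expect_equal(oc3$n_any_site,
                 sum(v3$near_ligand | v3$near_interface | v3$near_conserved))
    # inclusion-exclusion over the three site classes
    L <- v3$near_ligand; I <- v3$near_interface; C <- v3$near_conserved
    expect_equal(oc3$n_any_site,
                 sum(L) + sum(I) + sum(C) - sum(L & I) - sum(L & C) -
                   sum(I & C) + sum(L & I & C))
    expect_equal(oc3$multiple_evidence_fraction,
                 sum((L + I + C) >= 2) / oc3$n_any_site)
  }
})

test_that("same-disease clustering: pairs, singletons and planted fractions", {
  # helix: residue i and i+1 are ~3.8 A apart; i and i+5 are farther than 5 A
  m <- make_structure(60, "helix", seed = 44)
  nb <- residue_neighbors(m, 5)
  mk <- function(pos, dis) mutation_table(data.frame(
    accession = "P", position = pos, wild_aa = "A", mutant_aa = "W",
    category = "disease", disease_name = dis))
  close_pair <- mk(c(10L, 11L), c("d1", "d1"))
  expect_equal(same_disease_clustering(close_pair, nb)$fraction, 1.0)
  far_pair <- mk(c(10L, 40L), c("d1", "d1"))
  expect_equal(same_disease_clustering(far_pair, nb)$fraction, 0.0)
  # a single-residue disease is excluded from the denominator
  with_singleton <- mk(c(10L, 11L, 50L), c("d1", "d1", "d2"))
  r <- same_disease_clustering(with_singleton, nb)
  expect_equal(r$n_eligible, 2L)
  expect_equal(r$fraction, 1.0)
  # planted mixture: one clustered pair + one dispersed pair -> 0.5
  mix <- mk(c(10L, 11L, 30L, 55L), c("d1", "d1", "d2", "d2"))
  expect_equal(same_disease_clustering(mix, nb)$fraction, 0.5)
})
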