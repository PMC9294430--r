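# The mutation-explanation engine: functional-site sets, per-position
# evidence, per-mutation verdicts, multi-model consensus and same-disease
# spatial clustering.

#' Predicted functional-site sets
#'
#' Ligand-binding positions (predicted probability at or above
#' `ligand_prob`), interface positions (score at or above `interface_cut`)
#' and conserved positions (two-tier rule, see [conserved_sites()]).
#'
#' @param tables a [predictor_tables()].
#' @param profile a [scorecons_profile()] mapped to model numbering.
#' @param neighbors_tier2 `neighbor_map` used for the tier-2 conserved-site
#'   neighborhood (a strict-`<` map under the default configuration).
#' @param config a [default_config()].
#' @return list with integer vectors `ligand`, `interface`, `conserved`.
#' @export
site_sets <- function(tables, profile, neighbors_tier2,
                      config = default_config()) {
  lig <- as.integer(names(tables$ligand_prob))[
    tables$ligand_prob >= config$ligand_prob]
  ifc <- as.integer(names(tables$interface_score))[
    tables$interface_score >= config$interface_cut]
  cons <- conserved_sites(profile, neighbors_tier2,
                          cons_high = config$cons_high,
                          cons_mid = config$cons_mid)
  list(ligand = sort(lig), interface = sort(ifc), conserved = cons)
}

# minimum heavy-atom distance from a position to a site (0 if on it,
# Inf if the site is empty)
#' @keywords internal
site_distance <- function(model, position, site) {
  if (length(site) == 0L) return(Inf)
  if (position %in% site) return(0)
  a <- residue_coords(model, position)
  min(vapply(site, function(s)
    min_heavy_atom_distance(a, residue_coords(model, s)), 0))
}

#' Per-position evidence annotation
#'
#' For each queried position: proximity flags and minimum heavy-atom
#' distances to the three site classes, burial, and the quality gate
#' (domain is a good model AND the residue's own confidence passes).
#' `near_*` is `FALSE` whenever the corresponding site set is empty.
#'
#' @param positions integer residue numbers to annotate.
#' @param model a [protein_model()].
#' @param sites from [site_sets()].
#' @param neighbors inclusive `neighbor_map` used for proximity.
#' @param access an [accessibility_profile()].
#' @param quality a [domain_quality()] report.
#' @param config a [default_config()].
#' @return data.frame of class `position_annotation` with one row per
#'   position: `position`, `quality_ok`, `near_ligand`, `near_interface`,
#'   `near_conserved`, `dist_ligand`, `dist_interface`, `dist_conserved`,
#'   `rsa`, `buried`.
#' @export
annotate_positions <- function(positions, model, sites, neighbors, access,
                               quality, config = default_config()) {
  positions <- as.integer(positions)
  stopifnot(all(positions %in% model$residues$number))
  rsa <- access$rsa[match(positions, access$number)]
  pass <- unname(quality$residue_pass[as.character(positions)])
  out <- data.frame(
    position = positions,
    quality_ok = quality$good_model & pass,
    near_ligand = vapply(positions, near_site, TRUE,
                         site = sites$ligand, neighbors = neighbors),
    near_interface = vapply(positions, near_site, TRUE,
                            site = sites$interface, neighbors = neighbors),
    near_conserved = vapply(positions, near_site, TRUE,
                            site = sites$conserved, neighbors = neighbors),
    dist_ligand = vapply(positions, site_distance, 0,
                         model = model, site = sites$ligand),
    dist_interface = vapply(positions, site_distance, 0,
                            model = model, site = sites$interface),
    dist_conserved = vapply(positions, site_distance, 0,
                            model = model, site = sites$conserved),
    rsa = rsa,
    buried = is_buried(rsa, config$rsa_cut)
  )
  class(out) <- c("position_annotation", "data.frame")
  out
}

#' Per-mutation verdicts
#'
#' Joins mutation records with their position annotations and the
#' per-mutation predictor values, and applies the explanation rule: a
#' mutation is explained iff it is on or near a predicted ligand-binding,
#' interface or conserved site, or is destabilizing by the FoldX
#' convention (`ddG > 1`), or is predicted pathogenic (`score > 0.611`).
#' DynaMut2 agreement (`ddG < 0`) is recorded but does not enter the
#' explanation; burial is descriptive. Verdicts are only rendered for
#' quality-gated residues: `explained` is `NA` below the gate. Missing
#' predictor entries leave the corresponding flag `FALSE` and are noted.
#'
#' @param records a [mutation_table()] (one protein).
#' @param annotations [annotate_positions()] covering the records'
#'   positions.
#' @param tables a [predictor_tables()].
#' @param config a [default_config()].
#' @return data.frame of class `mutation_verdicts`: the records plus
#'   annotation columns, `foldx_ddg`, `dynamut_ddg`, `patho_score`,
#'   `destabilizing_foldx`, `destabilizing_dynamut`, `pathogenic`,
#'   `evidence` (comma-joined tags) and `explained`.
#' @export
judge_mutations <- function(records, annotations, tables,
                            config = default_config()) {
  i <- match(records$position, annotations$position)
  if (any(is.na(i))) stop("annotations missing for some mutation positions")
  ann <- annotations[i, , drop = FALSE]
  fx <- lookup_mutation_value(tables$foldx_ddg, records$position, records$mutant_aa)
  dm <- lookup_mutation_value(tables$dynamut_ddg, records$position, records$mutant_aa)
  pt <- lookup_mutation_value(tables$pathogenicity, records$position, records$mutant_aa)
  n_missing <- sum(is.na(fx)) + sum(is.na(pt)) + sum(is.na(dm))
  if (n_missing > 0)
    message(n_missing, " missing predictor value(s): flags treated as FALSE")
  destab_fx <- !is.na(fx) & fx > config$foldx_cut
  destab_dm <- !is.na(dm) & dm < config$dynamut_cut
  patho <- !is.na(pt) & pt > config$patho_cut
  expl <- ann$near_ligand | ann$near_interface | ann$near_conserved |
    destab_fx | patho
  evidence <- vapply(seq_len(nrow(records)), function(k) {
    tags <- c("ligand", "interface", "conserved", "destabilizing", "pathogenic")[
      c(ann$near_ligand[k], ann$near_interface[k], ann$near_conserved[k],
        destab_fx[k], patho[k])]
    paste(tags, collapse = ",")
  }, "")
  out <- cbind(
    as.data.frame(records),
    ann[, setdiff(names(ann), "position"), drop = FALSE],
    data.frame(foldx_ddg = fx, dynamut_ddg = dm, patho_score = pt,
               destabilizing_foldx = destab_fx,
               destabilizing_dynamut = destab_dm,
               pathogenic = patho,
               evidence = evidence,
               explained = ifelse(ann$quality_ok, expl, NA))
  )
  rownames(out) <- NULL
  class(out) <- c("mutation_verdicts", "data.frame")
  out
}

#' Merge verdicts across structure models
#'
#' Verdicts are keyed by (accession, position, mutant). For every mutation
#' the merged evidence is the union over the models in which the residue
#' passed the quality gate; a mutation counts as an *additional*
#' explanation when the merged verdict explains it but the first model's
#' verdict does not (low confidence there, or no evidence there). The
#' site-evidence overlap counts mutations near a functional site in both
#' of the first two models.
#'
#' @param verdict_list list of `mutation_verdicts`, first model first.
#' @return list with `merged` (data.frame: key columns, per-model explained
#'   flags, merged `evidence` and `explained`), `n_additional` and
#'   `n_overlap_site`.
#' @export
consensus_merge <- function(verdict_list) {
  stopifnot(length(verdict_list) >= 1L)
  key <- function(v) paste(v$accession, v$position, v$mutant_aa, sep = "|")
  keys <- unique(unlist(lapply(verdict_list, key)))
  split_tags <- function(s) if (is.na(s) || s == "") character(0) else
    strsplit(s, ",", fixed = TRUE)[[1]]
  m <- length(verdict_list)
  expl <- matrix(NA, length(keys), m)
  gated <- matrix(FALSE, length(keys), m)
  near_any <- matrix(FALSE, length(keys), m)
  evid <- vector("list", length(keys))
  base <- NULL
  for (j in seq_len(m)) {
    v <- verdict_list[[j]]
    idx <- match(key(v), keys)
    expl[idx, j] <- v$explained
    gated[idx, j] <- v$quality_ok
    near_any[idx, j] <- v$near_ligand | v$near_interface | v$near_conserved
    for (r in seq_along(idx)) {
      if (v$quality_ok[r])
        evid[[idx[r]]] <- union(evid[[idx[r]]], split_tags(v$evidence[r]))
    }
    kb <- v[, c("accession", "position", "wild_aa", "mutant_aa",
                "category", "disease_name")]
    base <- if (is.null(base)) kb else
      rbind(base, kb[!(key(v) %in% key(base)), , drop = FALSE])
  }
  any_gated <- rowSums(gated) > 0
  merged_expl <- ifelse(any_gated, lengths(evid) > 0, NA)
  ord <- match(keys, paste(base$accession, base$position, base$mutant_aa,
                           sep = "|"))
  merged <- cbind(base[ord, , drop = FALSE], data.frame(
    evidence = vapply(evid, function(e) paste(sort(e), collapse = ","), ""),
    explained = merged_expl
  ))
  for (j in seq_len(m)) merged[[paste0("explained_model", j)]] <- expl[, j]
  rownames(merged) <- NULL
  expl1 <- expl[, 1]
  n_additional <- sum(merged_expl & (!expl1 | is.na(expl1)), na.rm = TRUE)
  n_overlap_site <- if (m >= 2L)
    sum(near_any[, 1] & near_any[, 2] & gated[, 1] & gated[, 2]) else NA_integer_
  list(merged = merged, n_additional = n_additional,
       n_overlap_site = n_overlap_site)
}

#' Venn partition of site evidence
#'
#' Counts the seven regions of the ligand/interface/conserved Venn diagram
#' over mutations carrying at least one site tag, plus the fraction with
#' multiple (>= 2) site classes.
#'
#' @param verdicts a `mutation_verdicts` data.frame (or the merged table
#'   from [consensus_merge()], which carries the same flags via tags).
#' @return list with `regions` (named counts: `ligand`, `interface`,
#'   `conserved`, `ligand+interface`, `ligand+conserved`,
#'   `interface+conserved`, `ligand+interface+conserved`),
#'   `n_any_site` and `multiple_evidence_fraction`.
#' @export
overlap_counts <- function(verdicts) {
  if (all(c("near_ligand", "near_interface", "near_conserved") %in%
          names(verdicts))) {
    L <- verdicts$near_ligand; I <- verdicts$near_interface
    C <- verdicts$near_conserved
  } else {
    tags <- strsplit(ifelse(is.na(verdicts$evidence), "", verdicts$evidence),
                     ",", fixed = TRUE)
    L <- vapply(tags, function(t) "ligand" %in% t, TRUE)
    I <- vapply(tags, function(t) "interface" %in% t, TRUE)
    C <- vapply(tags, function(t) "conserved" %in% t, TRUE)
  }
  regions <- c(
    "ligand" = sum(L & !I & !C),
    "interface" = sum(!L & I & !C),
    "conserved" = sum(!L & !I & C),
    "ligand+interface" = sum(L & I & !C),
    "ligand+conserved" = sum(L & !I & C),
    "interface+conserved" = sum(!L & I & C),
    "ligand+interface+conserved" = sum(L & I & C)
  )
  n_any <- sum(L | I | C)
  n_multi <- sum((L + I + C) >= 2)
  list(regions = regions, n_any_site = n_any,
       multiple_evidence_fraction = if (n_any > 0) n_multi / n_any else NA_real_)
}

#' Same-disease structural clustering
#'
#' For one protein's disease mutations: the fraction of labelled residue
#' positions having at least one other residue with the same disease label
#' within the neighbor map's radius. Diseases represented by a single
#' residue position are excluded from the denominator (they cannot have a
#' same-disease neighbor).
#'
#' @param records a [mutation_table()] restricted to one protein; rows with
#'   empty disease names are ignored.
#' @param neighbors a `neighbor_map` for that protein's model.
#' @return list with `fraction` (`NA` when no eligible residues),
#'   `n_clustered` and `n_eligible`.
#' @export
same_disease_clustering <- function(records, neighbors) {
  d <- records[records$category == "disease" &
                 !is.na(records$disease_name) & records$disease_name != "", ,
               drop = FALSE]
  d <- unique(d[, c("disease_name", "position")])
  counts <- table(d$disease_name)
  eligible <- d[d$disease_name %in% names(counts)[counts >= 2L], , drop = FALSE]
  if (nrow(eligible) == 0L)
    return(list(fraction = NA_real_, n_clustered = 0L, n_eligible = 0L))
  clustered <- vapply(seq_len(nrow(eligible)), function(k) {
    same <- eligible$position[eligible$disease_name == eligible$disease_name[k]]
    same <- setdiff(same, eligible$position[k])
    any(same %in% neighbors_of(neighbors, eligible$position[k]))
  }, TRUE)
  list(fraction = mean(clustered), n_clustered = sum(clustered),
       n_eligible = nrow(eligible))
}

#' Explain the mutations of one protein
#'
#' End-to-end annotation for a single protein bundle: quality gating,
#' conservation profile, functional-site sets, per-position evidence and
#' per-mutation verdicts, optionally merged with a second structure model
#' of the same domain.
#'
#' @param model a [protein_model()] (primary model).
#' @param msa an [msa()] whose query matches the model sequence.
#' @param tables a [predictor_tables()] for the primary model.
#' @param mutations a [mutation_table()] for this protein.
#' @param segment optional [domain_segment()] (defaults to whole model).
#' @param model2 optional second [protein_model()].
#' @param tables2 predictor tables for `model2` (defaults to `tables`;
#'   the per-mutation ddG/pathogenicity tables are shared either way).
#' @param config a [default_config()].
#' @param query_start residue number of the first alignment query column.
#' @return object of class `mutation_explanations`: list with `verdicts`
#'   (primary model), `verdicts2` (or `NULL`), `consensus` (from
#'   [consensus_merge()]), `sites`, `annotations`, `quality`, `profile`,
#'   `diversity`, `disorder`, `accessibility`, `clustering` (from
#'   [same_disease_clustering()]) and `rmsd` between the models (or `NA`).
#' @export
explain_mutations <- function(model, msa, tables, mutations, segment = NULL,
                              model2 = NULL, tables2 = NULL,
                              config = default_config(), query_start = 1L) {
  if (is.null(segment)) {
    acc <- if (nrow(mutations) > 0L) mutations$accession[1] else model$model_id
    segment <- domain_segment(acc,
                              cbind(min(model$residues$number),
                                    max(model$residues$number)),
                              "CATH")
  }
  one_model <- function(mdl, tbl) {
    quality <- domain_quality(mdl, segment, conf_gate = config$conf_gate,
                              inclusive = config$conf_inclusive)
    nb <- residue_neighbors(mdl, config$radius, inclusive = config$near_inclusive)
    nb2 <- if (config$cons_tier2_strict)
      residue_neighbors(mdl, config$radius, inclusive = FALSE) else nb
    profile <- scorecons_profile(msa, query_start = query_start)
    sites <- site_sets(tbl, profile, nb2, config)
    access <- accessibility_profile(mdl, probe = config$sasa_probe,
                                    n_points = config$sasa_points)
    ann <- annotate_positions(unique(mutations$position), mdl, sites, nb,
                              access, quality, config)
    verdicts <- judge_mutations(mutations, ann, tbl, config)
    list(quality = quality, neighbors = nb, profile = profile, sites = sites,
         access = access, annotations = ann, verdicts = verdicts)
  }
  m1 <- one_model(model, tables)
  out <- list(
    verdicts = m1$verdicts, verdicts2 = NULL,
    consensus = NULL, sites = m1$sites, annotations = m1$annotations,
    quality = m1$quality, profile = m1$profile,
    diversity = diversity_metrics(msa, m1$profile,
                                  pct_threshold = config$scorecons_pct_cut),
    disorder = disorder_summary(tables$disorder_prob, segment,
                                config$disorder_cut, config$high_disorder),
    accessibility = m1$access,
    clustering = same_disease_clustering(mutations, m1$neighbors),
    rmsd = NA_real_
  )
  if (!is.null(model2)) {
    m2 <- one_model(model2, tables2 %||% tables)
    out$verdicts2 <- m2$verdicts
    out$consensus <- consensus_merge(list(m1$verdicts, m2$verdicts))
    out$rmsd <- model_rmsd(model, model2)$rmsd
  } else {
    out$consensus <- consensus_merge(list(m1$verdicts))
  }
  class(out) <- "mutation_explanations"
  out
}

#' @export
print.mutation_explanations <- function(x, ...) {
  v <- x$verdicts
  g <- sum(v$quality_ok)
  cat(sprintf("<mutation_explanations> %d mutations, %d quality-gated, %d explained (%.0f%% of gated)\n",
              nrow(v), g, sum(v$explained, na.rm = TRUE),
              if (g > 0) 100 * sum(v$explained, na.rm = TRUE) / g else NA))
  if (!is.null(x$verdicts2))
    cat(sprintf("  consensus with second model: %d additional explanation(s), %d site-evidence overlap(s)\n",
                x$consensus$n_additional, x$consensus$n_overlap_site))
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
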