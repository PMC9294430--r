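#' Default run configuration
#'
#' Every threshold used by the pipeline lives here, with the defaults the
#' analysis was designed around. Boundary inclusivity follows the printed
#' rules: ligand probability is inclusive (`>= 0.5`), FoldX destabilization
#' is strict (`ddG > 1`), pathogenicity is strict (`> 0.611`), burial is
#' strict (`RSA < 20`), the confidence gate is inclusive (`>= 70`), disorder
#' is strict (`> 0.5`) and the tier-2 conserved-site neighborhood is strict
#' (`< 5` Angstrom) while functional-site proximity is inclusive
#' (`<= 5` Angstrom). Each switch can be overridden.
#'
#' @param ... named overrides for any configuration entry.
#' @return a named list of class `structvar_config`.
#' @examples
#' cfg <- default_config(radius = 4.5)
#' cfg$radius
#' @export
default_config <- function(...) {
  cfg <- list(
    radius          = 5.0,    # Angstrom, heavy-atom neighborhood
    near_inclusive  = TRUE,   # functional-site proximity: <= radius
    conf_gate       = 70,     # pLDDT gate, 0-100 scale
    conf_inclusive  = TRUE,   # gate: >= conf_gate
    ligand_prob     = 0.5,    # ligand-binding call, inclusive
    interface_cut   = 0.34,   # interface score call, inclusive
    foldx_cut       = 1.0,    # destabilizing iff ddG > foldx_cut
    dynamut_cut     = 0.0,    # destabilizing iff ddG < dynamut_cut
    patho_cut       = 0.611,  # pathogenic iff score > patho_cut
    rsa_cut         = 20,     # buried iff RSA < rsa_cut (percent)
    cons_high       = 0.8,    # tier-1 conserved column, inclusive
    cons_mid        = 0.65,   # tier-2 column score, strict >
    cons_tier2_strict = TRUE, # tier-2 neighborhood: < radius
    disorder_cut    = 0.5,    # disordered iff probability > cut
    high_disorder   = 40,     # percent; high iff strictly greater
    scorecons_pct_cut = 0.9,  # column counts as conserved for percent_scorecons
    sasa_probe      = 1.4,    # Angstrom
    sasa_points     = 960,    # quadrature points per atom
    neff_identity   = 0.80,   # clustering identity for Neff
    seed            = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  class(cfg) <- c("structvar_config", "list")
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(
    cfg$radius > 0,
    cfg$conf_gate >= 0, cfg$conf_gate <= 101,
    cfg$ligand_prob >= 0,
    cfg$rsa_cut >= 0,
    cfg$cons_high >= 0, cfg$cons_high <= 1.1,
    cfg$cons_mid >= 0, cfg$cons_mid <= 1.1,
    cfg$disorder_cut >= 0,
    cfg$sasa_points >= 96,
    cfg$sasa_probe > 0,
    cfg$neff_identity > 0, cfg$neff_identity <= 1
  )
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip exactly: `read_config(write_config(cfg, f))`
#' equals `cfg`.
#'
#' @param path file path.
#' @param cfg a configuration from [default_config()].
#' @return `read_config` returns a `structvar_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
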