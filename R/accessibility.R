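# Shrake-Rupley solvent-accessible surface area, relative solvent
# accessibility and burial classification.

# Deterministic Fibonacci sphere: n approximately uniform points on the
# unit sphere.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Places a deterministic Fibonacci-sphere quadrature of `n_points` test
#' points on each atom's solvent-exposed sphere (radius `r_atom + probe`)
#' and counts the fraction not occluded by any other atom's expanded
#' sphere; the per-atom area is that fraction times
#' `4 * pi * (r_atom + probe)^2`. Van der Waals radii come from the bundled
#' element table (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom); unknown
#' elements fall back to the carbon radius with a warning.
#'
#' @param model a [protein_model()].
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom (>= 96).
#' @return numeric vector of per-atom SASA (Angstrom^2), in atom order,
#'   with the atom table's residue numbers as the `resno` attribute.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  stopifnot(n_points >= 96, probe > 0)
  el <- model$atoms$element
  r <- VDW_RADII[el]
  if (any(is.na(r))) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = " "),
            ": using carbon radius")
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  r <- unname(r) + probe
  X <- as.matrix(model$atoms[, c("x", "y", "z")])
  n <- nrow(X)
  S <- fibonacci_sphere(n_points)
  # candidate occluders: centers closer than the sum of expanded radii
  d2 <- outer(rowSums(X^2), rep(1, n)) + outer(rep(1, n), rowSums(X^2)) -
    2 * tcrossprod(X)
  rsum2 <- outer(r, r, "+")^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    occ <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    if (length(occ) == 0L) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    # nearest occluders first for early exit
    occ <- occ[order(d2[i, occ])]
    P <- S * r[i]
    px <- P[, 1] + X[i, 1]; py <- P[, 2] + X[i, 2]; pz <- P[, 3] + X[i, 3]
    free <- rep(TRUE, n_points)
    for (j in occ) {
      idx <- which(free)
      if (length(idx) == 0L) break
      dj2 <- (px[idx] - X[j, 1])^2 + (py[idx] - X[j, 2])^2 +
        (pz[idx] - X[j, 3])^2
      free[idx[dj2 < r[j]^2]] <- FALSE
    }
    area[i] <- sum(free) / n_points * 4 * pi * r[i]^2
  }
  attr(area, "resno") <- model$atoms$resno
  attr(area, "probe") <- probe
  attr(area, "n_points") <- n_points
  area
}

#' Per-residue relative solvent accessibility
#'
#' Sums per-atom SASA within each residue and normalizes by the residue
#' type's maximum accessible surface area (Tien et al. 2013 theoretical
#' table, swappable): `RSA = 100 * SASA / maxASA`. Nonstandard residues
#' (`X`) get `NA` RSA and are excluded from burial statistics.
#'
#' @param model a [protein_model()].
#' @param atom_sasa per-atom areas from [sasa()]; computed if `NULL`.
#' @param max_asa named maximum-ASA table (Angstrom^2, one-letter names).
#' @param probe,n_points passed to [sasa()] when `atom_sasa` is `NULL`.
#' @return an object of class `accessibility_profile`: data.frame with
#'   columns `number`, `aa`, `sasa`, `rsa`.
#' @export
accessibility_profile <- function(model, atom_sasa = NULL,
                                  max_asa = MAX_ASA_TIEN,
                                  probe = 1.4, n_points = 960) {
  if (is.null(atom_sasa)) atom_sasa <- sasa(model, probe = probe, n_points = n_points)
  res_sasa <- rowsum(as.numeric(atom_sasa), group = attr(atom_sasa, "resno"))
  num <- as.integer(rownames(res_sasa))
  ord <- match(model$residues$number, num)
  s <- as.numeric(res_sasa)[ord]
  aa <- model$residues$aa
  mx <- max_asa[aa]
  rsa <- 100 * s / unname(mx)          # NA for nonstandard residues
  out <- data.frame(number = model$residues$number, aa = aa,
                    sasa = s, rsa = rsa)
  attr(out, "probe") <- attr(atom_sasa, "probe")
  attr(out, "n_points") <- attr(atom_sasa, "n_points")
  class(out) <- c("accessibility_profile", "data.frame")
  out
}

#' Burial classification
#'
#' A residue is buried iff its relative solvent accessibility is strictly
#' below the cutoff (default 20 percent).
#'
#' @param rsa numeric RSA values (percent); `NA` propagates.
#' @param cut burial cutoff (percent).
#' @return logical vector.
#' @export
is_buried <- function(rsa, cut = 20) {
  rsa < cut
}
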