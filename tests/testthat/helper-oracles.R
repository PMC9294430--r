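# Independent oracles and fixture builders. Every oracle here is written
# against the definition, not against the package's implementation path:
# brute-force all-pairs distances, Horn's quaternion superposition,
# Monte-Carlo surface sampling, full permutation enumeration.

# build a protein_model from a list of per-residue atom matrices
toy_model <- function(coords, aa = NULL, conf = NULL, id = "toy",
                      source = "alphafold-like", elety = NULL) {
  n <- length(coords)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(conf)) conf <- rep(90, n)
  rows <- lapply(seq_len(n), function(i) {
    m <- matrix(coords[[i]], ncol = 3)
    ety <- if (is.null(elety)) {
      if (nrow(m) == 1) "CA" else paste0("C", seq_len(nrow(m)))
    } else elety[[i]]
    data.frame(resno = i, resid = unname(structvar:::AA1TO3[aa[i]]),
               elety = ety, element = substr(ety, 1, 1),
               x = m[, 1], y = m[, 2], z = m[, 3], b = conf[i])
  })
  protein_model(id, source, do.call(rbind, rows))
}

# O(n^2) brute-force neighbor map over all atom pairs
brute_neighbors <- function(model, radius, inclusive = TRUE) {
  X <- as.matrix(model$atoms[, c("x", "y", "z")])
  resno <- model$atoms$resno
  D2 <- outer(rowSums(X^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(X)), rowSums(X^2)) - 2 * tcrossprod(X)
  cmp <- if (inclusive) `<=` else `<`
  hit <- which(cmp(D2, radius^2), arr.ind = TRUE)
  ri <- resno[hit[, 1]]; rj <- resno[hit[, 2]]
  keep <- ri != rj
  pairs <- unique(cbind(ri[keep], rj[keep]))
  res <- sort(unique(resno))
  out <- lapply(setNames(res, res), function(r) integer(0))
  if (nrow(pairs)) {
    sp <- split(pairs[, 2], pairs[, 1])
    for (r in names(sp)) out[[r]] <- sort(unique(sp[[r]]))
  }
  out
}

# Horn's quaternion method for least-squares superposition RMSD:
# the optimal rotation is the eigenvector of the 4x4 key matrix with the
# largest eigenvalue. SVD-free, independent of the Kabsch route.
quaternion_rmsd <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3); b <- matrix(as.numeric(b), ncol = 3)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  M <- crossprod(bc, ac)   # sum over points of b_i a_i^T
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(0, msd))
}

# Monte-Carlo SASA of one atom among occluders: uniform random points on
# its expanded sphere, count the unoccluded fraction
mc_atom_sasa <- function(center, radius, occ_centers, occ_radii, probe = 1.4,
                         n = 1e6, seed = 42) {
  set.seed(seed)
  R <- radius + probe
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  P <- cbind(R * r * cos(phi), R * r * sin(phi), R * z)
  P <- sweep(P, 2, center, "+")
  free <- rep(TRUE, n)
  if (length(occ_radii)) {
    occ_centers <- matrix(occ_centers, ncol = 3)
    for (j in seq_along(occ_radii)) {
      dj2 <- (P[, 1] - occ_centers[j, 1])^2 + (P[, 2] - occ_centers[j, 2])^2 +
        (P[, 3] - occ_centers[j, 3])^2
      free <- free & dj2 >= (occ_radii[j] + probe)^2
    }
  }
  mean(free) * 4 * pi * R^2
}

# exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled sample
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- ustat(x, y)
  us <- apply(idx, 2, function(k) ustat(pooled[k], pooled[-k]))
  mu <- n1 * (length(pooled) - n1) / 2
  # two-sided: total probability of |U - mu| >= |u_obs - mu|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# naive two-pass conserved-site construction from raw distances
naive_conserved <- function(model, profile, cons_high = 0.8, cons_mid = 0.65,
                            radius = 5, tier2_strict = TRUE) {
  mapped <- profile[!is.na(profile$position), ]
  s1 <- mapped$position[mapped$score >= cons_high]
  cand <- mapped$position[mapped$score > cons_mid]
  cmp <- if (tier2_strict) `<` else `<=`
  s2 <- Filter(function(p) {
    others <- setdiff(s1, p)
    any(vapply(others, function(q) cmp(
      min_heavy_atom_distance(residue_coords(model, p),
                              residue_coords(model, q)), radius), TRUE))
  }, cand)
  sort(unique(c(s1, unlist(s2))))
}

# random point cloud
rand_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), ncol = 3)
}

# random rigid motion of a point cloud
rigid_motion <- function(x, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(x %*% R, 2, runif(3, -50, 50), "+")
}

# count heavy (non-hydrogen) ATOM records by direct text scan of a PDB file
text_scan_heavy_atoms <- function(path) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM")]
  elem <- trimws(substr(at, 77, 78))
  noelem <- elem == ""
  if (any(noelem)) {
    nm <- trimws(substr(at[noelem], 13, 16))
    elem[noelem] <- substr(gsub("[0-9']", "", nm), 1, 1)
  }
  sum(!(elem %in% c("H", "D")))
}

# small complete bundle for pipeline-level tests
tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_proteins = 2L, n_res = c(60L, 70L), depth = 12L,
              n_disease = 16L, n_polymorphism = 16L, seed = seed, ...)
}
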