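# Spatial primitives: heavy-atom distances, cell-list neighbor search and
# Kabsch least-squares superposition.

#' Heavy-atom coordinates of one residue
#'
#' @param model a [protein_model()].
#' @param number residue number (UniProt numbering).
#' @return numeric matrix (atoms x 3).
#' @export
residue_coords <- function(model, number) {
  a <- model$atoms[model$atoms$resno == number, c("x", "y", "z"), drop = FALSE]
  if (nrow(a) == 0L) stop("residue ", number, " not in model")
  as.matrix(a)
}

#' Minimum heavy-atom distance between two residues
#'
#' Minimum Euclidean distance over all heavy-atom pairs, the distance
#' underlying the 5 Angstrom functional-site neighborhoods.
#'
#' @param a,b numeric matrices (atoms x 3) as from [residue_coords()].
#' @return distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Residue neighbor map via a cell list
#'
#' Two residues i != j are neighbors iff their minimum heavy-atom distance
#' is within `radius` (closed ball by default). Built with the cell-list
#' algorithm: atoms are hashed into a grid of cell edge `radius` and only
#' the 27 adjacent cells are scanned for partners.
#'
#' @param model a [protein_model()].
#' @param radius neighborhood radius in Angstrom (> 0).
#' @param inclusive logical; `TRUE` uses `<= radius` (default), `FALSE`
#'   uses strict `<`.
#' @return an object of class `neighbor_map`: a list with `radius`,
#'   `inclusive` and `nbrs`, a list keyed by residue number holding the
#'   sorted integer neighbor sets. The map is symmetric and irreflexive.
#' @export
residue_neighbors <- function(model, radius = 5.0, inclusive = TRUE) {
  stopifnot(radius > 0)
  resno <- model$atoms$resno
  X <- as.matrix(model$atoms[, c("x", "y", "z")])
  n <- nrow(X)
  empty <- structure(list(radius = radius, inclusive = inclusive,
                          nbrs = setNames(list(), character(0))),
                     class = "neighbor_map")
  if (n == 0L) return(empty)

  lo <- apply(X, 2L, min)
  ci <- floor(sweep(X, 2L, lo) / radius)           # integer cell coords
  dims <- apply(ci, 2L, max) + 1L
  key <- ci[, 1] + dims[1] * (ci[, 2] + dims[2] * ci[, 3])
  cells <- split(seq_len(n), key)
  # precompute cell coordinate per cell
  ckey <- as.numeric(names(cells))
  cx <- ckey %% dims[1]
  cy <- (ckey %/% dims[1]) %% dims[2]
  cz <- ckey %/% (dims[1] * dims[2])
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(cells)) assign(as.character(ckey[i]), i, envir = keymap)

  r2 <- radius^2
  cmp <- if (inclusive) `<=` else `<`
  pi_ <- integer(0); pj_ <- integer(0)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (ic in seq_along(cells)) {
    A <- cells[[ic]]
    # gather atoms of the 27 adjacent cells (self included)
    nk <- (cx[ic] + off[, 1]) + dims[1] * ((cy[ic] + off[, 2]) +
            dims[2] * (cz[ic] + off[, 3]))
    ok <- cx[ic] + off[, 1] >= 0 & cx[ic] + off[, 1] < dims[1] &
          cy[ic] + off[, 2] >= 0 & cy[ic] + off[, 2] < dims[2] &
          cz[ic] + off[, 3] >= 0 & cz[ic] + off[, 3] < dims[3]
    B <- unlist(lapply(as.character(nk[ok]), function(k) {
      j <- keymap[[k]]
      if (is.null(j)) NULL else cells[[j]]
    }), use.names = FALSE)
    XA <- X[A, , drop = FALSE]; XB <- X[B, , drop = FALSE]
    d2 <- outer(rowSums(XA^2), rep(1, length(B))) +
      outer(rep(1, length(A)), rowSums(XB^2)) - 2 * tcrossprod(XA, XB)
    hit <- which(cmp(d2, r2), arr.ind = TRUE)
    if (nrow(hit)) {
      pi_ <- c(pi_, A[hit[, 1]])
      pj_ <- c(pj_, B[hit[, 2]])
    }
  }
  ri <- resno[pi_]; rj <- resno[pj_]
  keep <- ri != rj
  ri <- ri[keep]; rj <- rj[keep]
  pairs <- unique(cbind(ri, rj))                    # symmetric by construction
  res <- sort(unique(resno))
  nbrs <- lapply(setNames(res, res), function(r) integer(0))
  if (nrow(pairs)) {
    sp <- split(pairs[, 2], pairs[, 1])
    for (r in names(sp)) nbrs[[r]] <- sort(unique(sp[[r]]))
  }
  structure(list(radius = radius, inclusive = inclusive, nbrs = nbrs),
            class = "neighbor_map")
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat(sprintf("<neighbor_map> %d residues, radius %.2f A (%s), %d pairs\n",
              length(x$nbrs), x$radius, if (x$inclusive) "<=" else "<",
              sum(lengths(x$nbrs)) / 2))
  invisible(x)
}

#' Neighbors of one residue
#' @param neighbors a `neighbor_map`.
#' @param position residue number.
#' @return integer vector (possibly empty).
#' @export
neighbors_of <- function(neighbors, position) {
  nb <- neighbors$nbrs[[as.character(position)]]
  if (is.null(nb)) integer(0) else nb
}

#' Is a position on or near a site?
#'
#' `TRUE` iff the position is itself a member of `site` ("on") or at least
#' one of its spatial neighbors is ("near", i.e. within the map's radius).
#'
#' @param position residue number.
#' @param site integer vector of residue numbers (possibly empty).
#' @param neighbors a `neighbor_map` from [residue_neighbors()].
#' @return logical.
#' @export
near_site <- function(position, site, neighbors) {
  if (length(site) == 0L) return(FALSE)
  position %in% site || any(neighbors_of(neighbors, position) %in% site)
}

#' Kabsch superposition and RMSD
#'
#' Least-squares rigid superposition of two coordinate sets paired by index
#' (typically CA atoms of shared residues), with the reflection corrected so
#' the rotation is proper (`det = +1`). Used to compare two independently
#' predicted models of the same domain.
#'
#' @param a,b numeric matrices (n x 3), n >= 3, paired by row.
#' @return an object of class `superposition`: list with `rotation` (3 x 3,
#'   applied to row vectors of centered `b`), `translation` (length 3) such
#'   that `b %*% rotation + translation` superposes `b` onto `a`, and
#'   `rmsd` (Angstrom).
#' @export
kabsch_rmsd <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 3L) stop("need at least 3 paired points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2L, ca); bc <- sweep(b, 2L, cb)
  H <- crossprod(bc, ac)                       # t(bc) %*% ac
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1                           # rank-deficient: keep identity sign
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- bc %*% R
  rmsd <- sqrt(mean(rowSums((fit - ac)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A, det(R) = %.6f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' CA-based RMSD between two models of the same domain
#'
#' Pairs CA atoms of residues shared by number between the two models and
#' returns their Kabsch superposition. Models of the same domain share
#' numbering, so no alignment search is needed.
#'
#' @param model1,model2 [protein_model()] objects.
#' @return a `superposition` (see [kabsch_rmsd()]).
#' @export
model_rmsd <- function(model1, model2) {
  ca1 <- model1$atoms[model1$atoms$elety == "CA", ]
  ca2 <- model2$atoms[model2$atoms$elety == "CA", ]
  shared <- intersect(ca1$resno, ca2$resno)
  if (length(shared) < 3L) stop("fewer than 3 shared CA atoms")
  a <- as.matrix(ca1[match(shared, ca1$resno), c("x", "y", "z")])
  b <- as.matrix(ca2[match(shared, ca2$resno), c("x", "y", "z")])
  kabsch_rmsd(a, b)
}
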