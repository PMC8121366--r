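#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimize the (optionally
#' weighted) RMSD between two paired coordinate sets, via singular value
#' decomposition of the cross-covariance matrix with the usual sign
#' correction of the smallest singular value so that the result is always a
#' rotation (determinant +1), never a reflection.
#'
#' @param coords_p,coords_q N x 3 matrices of paired coordinates (angstrom);
#'   the transform maps `coords_p` onto `coords_q`.
#' @param weights Optional non-negative weights of length N.
#' @return A `superposition` object with `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (angstrom, after the transform) and `n_pairs`.
#'   Apply it with `transform_coords()` or `predict()`-style arithmetic
#'   `P %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(coords_p, coords_q, weights = NULL) {
  P <- as.matrix(coords_p); Q <- as.matrix(coords_q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3)
    abort("coordinate sets must be equal-size N x 3 matrices")
  n <- nrow(P)
  if (n < 3) abort("at least 3 point pairs are required")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    abort("weights must be non-negative with positive sum")
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc * sqrt(w))$d
  sv_q <- svd(Qc * sqrt(w))$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1e-12) ||
      sv_q[2] < 1e-8 * max(sv_q[1], 1e-12))
    abort("degenerate (collinear or coincident) point set")
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cq - R %*% cp)
  diffs <- Qc - Pc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums(diffs^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition")
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x An N x 3 coordinate matrix or a `lobe_structure`.
#' @param rotation 3x3 rotation matrix (or a `superposition` object, in
#'   which case `translation` is taken from it).
#' @param translation Length-3 translation vector.
#' @return Object of the same kind as `x`, transformed.
#' @export
transform_coords <- function(x, rotation, translation = c(0, 0, 0)) {
  if (inherits(rotation, "superposition")) {
    translation <- rotation$translation
    rotation <- rotation$rotation
  }
  if (inherits(x, "lobe_structure")) {
    at <- as_tibble(x)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
    at$x <- xyz[, 1] + translation[1]
    at$y <- xyz[, 2] + translation[2]
    at$z <- xyz[, 3] + translation[3]
    return(restore_structure(at, x))
  }
  sweep(as.matrix(x) %*% t(rotation), 2, -translation)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d pairs, RMSD %.4f A>\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
         det_rotation = det(x$rotation))
}

#' Superpose two structures and report RMSD
#'
#' Pairs residues between one chain of each structure (see
#' [pair_residues()]), matches atoms within each residue pair by atom name
#' (hydrogens excluded; alternate locations were already resolved at read
#' time), computes the least-squares superposition on all shared heavy
#' atoms, and reports both the all-heavy-atom RMSD and the C-alpha RMSD
#' under that single transform. This is the conventional "all-atom RMSD"
#' between deposited crystal structures of homologous domains.
#'
#' @param structure_a,structure_b `lobe_structure` objects (a is moved onto b).
#' @param chain_a,chain_b Chain ids (default: first chain of each).
#' @param mode Residue pairing mode, `"sequence"` or `"seq_id"`.
#' @param fit `"heavy"` (default) fits on all shared heavy atoms; `"ca"`
#'   fits on C-alpha atoms only.
#' @return A `superposition_report`: the `superposition` plus `rmsd_all`,
#'   `rmsd_ca`, `n_atom_pairs`, `n_ca_pairs`, `n_residue_pairs`.
#' @export
superpose_structures <- function(structure_a, structure_b,
                                 chain_a = NULL, chain_b = NULL,
                                 mode = c("sequence", "seq_id"),
                                 fit = c("heavy", "ca")) {
  mode <- match.arg(mode); fit <- match.arg(fit)
  chain_a <- chain_a %||% structure_chains(structure_a)[1]
  chain_b <- chain_b %||% structure_chains(structure_b)[1]
  pairs <- pair_residues(structure_a, structure_b, chain_a, chain_b, mode)
  at_a <- filter(as_tibble(remove_hydrogens(structure_a)),
                 .data$chain == !!chain_a)
  at_b <- filter(as_tibble(remove_hydrogens(structure_b)),
                 .data$chain == !!chain_b)
  matched <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ra <- filter(at_a, .data$resno == pairs$resno_a[k],
                 .data$insert == pairs$insert_a[k])
    rb <- filter(at_b, .data$resno == pairs$resno_b[k],
                 .data$insert == pairs$insert_b[k])
    shared <- intersect(ra$elety, rb$elety)
    if (length(shared) == 0) next
    ia <- match(shared, ra$elety); ib <- match(shared, rb$elety)
    matched[[k]] <- tibble(
      elety = shared, is_ca = shared == "CA",
      xa = ra$x[ia], ya = ra$y[ia], za = ra$z[ia],
      xb = rb$x[ib], yb = rb$y[ib], zb = rb$z[ib]
    )
  }
  m <- bind_rows(matched)
  if (nrow(m) < 3) abort("fewer than 3 shared heavy atoms across paired residues")
  P <- as.matrix(m[, c("xa", "ya", "za")])
  Q <- as.matrix(m[, c("xb", "yb", "zb")])
  sel <- if (fit == "ca") m$is_ca else rep(TRUE, nrow(m))
  if (sum(sel) < 3) abort("fewer than 3 atoms in the fitting subset")
  sup <- kabsch_superpose(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
  moved <- sweep(P %*% t(sup$rotation), 2, -sup$translation)
  dev2 <- rowSums((moved - Q)^2)
  out <- sup
  out$rmsd_all <- sqrt(mean(dev2))
  out$rmsd_ca <- if (any(m$is_ca)) sqrt(mean(dev2[m$is_ca])) else NA_real_
  out$n_atom_pairs <- nrow(m)
  out$n_ca_pairs <- sum(m$is_ca)
  out$n_residue_pairs <- nrow(pairs)
  class(out) <- c("superposition_report", "superposition")
  out
}

#' @export
print.superposition_report <- function(x, ...) {
  cat(sprintf(
    "<superposition: %d residue pairs, %d heavy-atom pairs\n  RMSD all-heavy %.3f A, C-alpha %.3f A>\n",
    x$n_residue_pairs, x$n_atom_pairs, x$rmsd_all, x$rmsd_ca))
  invisible(x)
}

#' @export
glance.superposition_report <- function(x, ...) {
  tibble(rmsd_all = x$rmsd_all, rmsd_ca = x$rmsd_ca,
         n_atom_pairs = x$n_atom_pairs, n_ca_pairs = x$n_ca_pairs,
         n_residue_pairs = x$n_residue_pairs)
}
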