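# Small internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Rotation matrix about an arbitrary axis
#'
#' Builds the 3x3 proper rotation matrix for a right-handed rotation of
#' `angle` degrees about `axis` (Rodrigues formula). Used by the assembly
#' builder, the synthetic dimer generator and the rigid-invariance tests.
#'
#' @param axis Numeric length-3 axis (need not be normalized).
#' @param angle Rotation angle in degrees.
#' @return A 3x3 rotation matrix with determinant +1.
#' @export
rotation_about_axis <- function(axis, angle) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) abort("rotation axis must be non-zero")
  u <- axis / n
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < tol
}

# Element symbol from a PDB atom name when the element column is absent:
# strip digits/primes, take the leading alphabetic part; two-letter symbols
# only when they match a known element.
guess_element <- function(elety) {
  raw <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- substr(raw, 1, 2)
  one <- substr(raw, 1, 1)
  ifelse(two %in% names(.vdw_radii) & !(one %in% c("C", "N", "O", "H", "S", "P")),
         two, one)
}

# Uppercase one-letter sequence from a character vector of 3-letter codes;
# unknown residues become "X".
three_to_one <- function(resnames) {
  out <- unname(.aa_three_to_one[toupper(resnames)])
  out[is.na(out)] <- "X"
  out
}
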