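#' SASA estimator parameters
#'
#' Parameter bundle for the Shrake-Rupley solvent-accessible surface area
#' estimator: van der Waals radii per element, probe radius and the number
#' of test points per atom. The default radii are C 1.70, N 1.55, O 1.52,
#' S 1.80 angstrom with a 1.4-angstrom water probe; hydrogens are excluded
#' by default (radii are not inflated to united-atom values), matching
#' common practice for crystal structures deposited without hydrogens.
#'
#' @param probe_radius Solvent probe radius in angstrom (default 1.4).
#' @param n_sphere_points Test points per atom (default 960, minimum 92).
#' @param default_radius Radius used, with a warning, for elements absent
#'   from the table (default 1.80).
#' @param radii Named vector of van der Waals radii overriding the built-in
#'   table.
#' @return A `radii_set` list.
#' @export
radii_set <- function(probe_radius = 1.4, n_sphere_points = 960,
                      default_radius = 1.80, radii = NULL) {
  r <- .vdw_radii
  if (!is.null(radii)) r[toupper(names(radii))] <- radii
  if (any(r <= 0) || default_radius <= 0) abort("radii must be positive")
  if (n_sphere_points < 92) abort("n_sphere_points must be at least 92")
  if (probe_radius < 0) abort("probe_radius must be non-negative")
  structure(list(radii = r, probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 default_radius = default_radius),
            class = "radii_set")
}

# Deterministic quasi-uniform unit-sphere point set (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i          # golden-angle longitude
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom is expanded by the probe radius and covered
#' with a deterministic Fibonacci lattice of test points; points falling
#' inside any neighbouring expanded sphere are occluded, and the accessible
#' fraction times the expanded-sphere area gives the per-atom SASA.
#'
#' @param structure A `lobe_structure`.
#' @param params A [radii_set()].
#' @param include_hydrogens Include hydrogen atoms (default `FALSE`).
#' @return Tibble of the (heavy) atoms with columns `chain`, `resno`,
#'   `insert`, `resname`, `elety`, `element`, `radius` and `sasa`
#'   (angstrom^2). Total SASA is `sum(out$sasa)`.
#' @export
sasa <- function(structure, params = radii_set(), include_hydrogens = FALSE) {
  at <- as_tibble(structure)
  if (!include_hydrogens) at <- filter(at, !.data$element %in% c("H", "D"))
  if (nrow(at) == 0) abort("no atoms to compute SASA for")
  radius <- unname(params$radii[at$element])
  unknown <- unique(at$element[is.na(radius)])
  if (length(unknown) > 0) {
    warn(paste0("unknown element(s) ", paste(unknown, collapse = ", "),
                "; using default radius ", params$default_radius, " A"))
    radius[is.na(radius)] <- params$default_radius
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  rext <- radius + params$probe_radius
  pts <- fibonacci_sphere(params$n_sphere_points)
  area <- numeric(n)
  # neighbour search via squared-distance matrix (structures here are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (rext[i] + rext)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * rext[i]^2
      next
    }
    nb <- nb[order(d2[i, nb])]
    p <- sweep(pts * rext[i], 2, xyz[i, ], `+`)
    alive <- rep(TRUE, nrow(p))
    for (j in nb) {
      idx <- which(alive)
      if (length(idx) == 0) break
      dx <- p[idx, 1] - xyz[j, 1]
      dy <- p[idx, 2] - xyz[j, 2]
      dz <- p[idx, 3] - xyz[j, 3]
      alive[idx[dx * dx + dy * dy + dz * dz < rext[j]^2]] <- FALSE
    }
    area[i] <- 4 * pi * rext[i]^2 * sum(alive) / nrow(p)
  }
  out <- at[, c("chain", "resno", "insert", "resname", "elety", "element")]
  out$radius <- radius
  out$sasa <- area
  out
}
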