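# Principal axis of an ordered C-alpha trace. The raw C-alpha cloud couples
# helical phase with position along the axis, tilting the principal
# component by O(radius / length); averaging over ~one helical turn
# (window 4 ~= 3.6 residues, applied twice when the trace is long enough)
# collapses the points onto the axis, after which the principal component
# is essentially exact for regular helices.
principal_axis <- function(xyz) {
  smooth4 <- function(m) {
    if (nrow(m) < 8) return(m)
    n <- nrow(m) - 3
    (m[1:n, , drop = FALSE] + m[2:(n + 1), , drop = FALSE] +
       m[3:(n + 2), , drop = FALSE] + m[4:(n + 3), , drop = FALSE]) / 4
  }
  pts <- smooth4(smooth4(xyz))
  centered <- sweep(pts, 2, colMeans(pts))
  eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)$vectors[, 1]
}

#' Helix axis by principal component of C-alpha positions
#'
#' Fits the axis of an (ideally long and straight) alpha-helix as the
#' principal eigenvector of the covariance matrix of its C-alpha
#' coordinates, through their centroid, with the sign oriented from the
#' first to the last residue (N to C). The RMS perpendicular distance of
#' the C-alpha atoms from the axis is reported as `fit_rms`; for an ideal
#' helix it equals the C-alpha radius (~2.3 angstrom), and much larger
#' values flag kinked helices for which a single straight axis is a poor
#' model.
#'
#' @param structure A `lobe_structure`.
#' @param chain Chain id (default: first chain).
#' @param residue_range Optional `c(start, end)` author residue numbers;
#'   default: all residues of the chain. At least 5 C-alpha atoms required.
#' @return A `helix_axis`: `point` (centroid), `direction` (unit vector,
#'   N to C), `residue_range`, `fit_rms`, `n_ca`.
#' @export
helix_axis <- function(structure, chain = NULL, residue_range = NULL) {
  at <- as_tibble(structure)
  chain <- chain %||% at$chain[1]
  ca <- filter(at, .data$chain == !!chain, .data$elety == "CA")
  if (!is.null(residue_range)) {
    ca <- filter(ca, .data$resno >= residue_range[1],
                 .data$resno <= residue_range[2])
  }
  ca <- arrange(ca, .data$resno, .data$insert)
  if (nrow(ca) < 5)
    abort(sprintf("need at least 5 C-alpha atoms, found %d", nrow(ca)))
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  dir <- principal_axis(xyz)
  centered <- sweep(xyz, 2, centroid)
  nc <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(dir * nc) < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  proj <- centered %*% dir
  perp2 <- rowSums(centered^2) - proj^2
  structure(list(
    point = centroid, direction = as.numeric(dir),
    residue_range = residue_range %||% range(ca$resno),
    fit_rms = sqrt(mean(pmax(perp2, 0))), n_ca = nrow(ca)
  ), class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf(
    "<helix axis: residues %d-%d (%d CA), direction (%.3f, %.3f, %.3f), fit RMS %.2f A>\n",
    x$residue_range[1], x$residue_range[2], x$n_ca,
    x$direction[1], x$direction[2], x$direction[3], x$fit_rms))
  invisible(x)
}

#' Crossing angle between two helix axes
#'
#' Angle in degrees between the directed (N-to-C) axes, in `[0, 180]`.
#' Because the axes are directed, an obtuse packing (e.g. ~140 degrees)
#' is distinguishable from its supplement.
#'
#' @param axis_a,axis_b `helix_axis` objects (or unit 3-vectors).
#' @return Angle in degrees.
#' @export
cross_angle <- function(axis_a, axis_b) {
  da <- if (inherits(axis_a, "helix_axis")) axis_a$direction else axis_a
  db <- if (inherits(axis_b, "helix_axis")) axis_b$direction else axis_b
  da <- da / sqrt(sum(da^2)); db <- db / sqrt(sum(db^2))
  rad2deg(acos(clamp(sum(da * db), -1, 1)))
}

#' Radius of gyration from coordinates
#'
#' `Rg = sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with uniform or
#' atomic-mass weights.
#'
#' @param structure A `lobe_structure` (or N x 3 matrix).
#' @param weighting `"uniform"` or `"mass"`.
#' @return Radius of gyration in angstrom.
#' @export
radius_of_gyration <- function(structure, weighting = c("uniform", "mass")) {
  weighting <- match.arg(weighting)
  if (inherits(structure, "lobe_structure")) {
    xyz <- coords_matrix(structure)
    w <- if (weighting == "mass") {
      m <- .atomic_masses[as_tibble(structure)$element]
      m[is.na(m)] <- mean(.atomic_masses)
      m
    } else rep(1, nrow(xyz))
  } else {
    xyz <- as.matrix(structure)
    w <- rep(1, nrow(xyz))
  }
  if (nrow(xyz) < 1) abort("at least one atom required")
  w <- w / sum(w)
  centroid <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, centroid)^2)))
}

#' Pair-distance distribution P(r)
#'
#' Histogram of all interatomic distances, normalized to unit area: the
#' real-space counterpart of a small-angle scattering curve. `dmax` is the
#' maximum interatomic distance and the radius of gyration is recovered
#' from the second moment, `Rg^2 = integral(r^2 P(r) dr) / 2`.
#'
#' @param structure A `lobe_structure` (>= 2 atoms).
#' @param bin_width Histogram bin width in angstrom (default 1).
#' @return A `distance_distribution`: tibble of bin centers `r` and density
#'   `p`, with attributes `dmax`, `rg`, `bin_width`.
#' @export
distance_distribution <- function(structure, bin_width = 1) {
  xyz <- if (inherits(structure, "lobe_structure")) coords_matrix(structure)
         else as.matrix(structure)
  if (nrow(xyz) < 2) abort("at least two atoms required")
  d <- as.numeric(dist(xyz))
  dmax <- max(d)
  nbins <- max(1L, ceiling(dmax / bin_width))
  idx <- pmin(floor(d / bin_width) + 1L, nbins)  # right edge closes last bin
  counts <- tabulate(idx, nbins)
  p <- counts / (length(d) * bin_width)  # integrates to 1 over r
  out <- tibble(r = (seq_len(nbins) - 0.5) * bin_width, p = p)
  # second-moment Rg; the (N-1)/N factor accounts for the self-pairs that a
  # finite point set excludes from its distance histogram
  n_at <- nrow(xyz)
  rg <- sqrt(sum(out$r^2 * out$p * bin_width) * (n_at - 1) / n_at / 2)
  structure(out, dmax = dmax, rg = rg, bin_width = bin_width,
            class = c("distance_distribution", class(tibble())))
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<P(r): dmax %.2f A, Rg %.2f A, %d bins of %.2f A>\n",
              attr(x, "dmax"), attr(x, "rg"), nrow(x), attr(x, "bin_width")))
  NextMethod()
}

#' @export
glance.distance_distribution <- function(x, ...) {
  tibble(dmax = attr(x, "dmax"), rg = attr(x, "rg"),
         bin_width = attr(x, "bin_width"), n_bins = nrow(x))
}
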