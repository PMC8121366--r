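# Seeded generators for every input class the analyses consume: ideal
# helices, two-chain helix dimers with known geometry, alignments with
# controlled per-column entropy / gaps / redundancy, and noisy scattering
# curves. Generators take explicit seeds (never global RNG state) and stash
# their ground truth in attributes for recovery tests.

#' Ideal helix parameters
#'
#' @param n_res Number of residues (>= 5).
#' @param rise Rise per residue in angstrom (default 1.5).
#' @param twist Twist per residue in degrees (default 100).
#' @param ca_radius C-alpha helical radius in angstrom (default 2.3).
#' @param sequence Optional one-letter sequence (recycled/truncated to
#'   `n_res`); default poly-alanine.
#' @return A `helix_spec` list.
#' @export
helix_spec <- function(n_res = 20, rise = 1.5, twist = 100, ca_radius = 2.3,
                       sequence = NULL) {
  if (n_res < 5) abort("n_res must be at least 5")
  if (rise <= 0 || ca_radius <= 0) abort("rise and ca_radius must be positive")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    aa <- strsplit(sequence, "")[[1]]
    bad <- setdiff(unique(aa), names(.aa_one_to_three))
    if (length(bad) > 0)
      abort(paste0("unknown residue(s) in sequence: ", paste(bad, collapse = ", ")))
  }
  structure(list(n_res = as.integer(n_res), rise = rise, twist = twist,
                 ca_radius = ca_radius, sequence = sequence),
            class = "helix_spec")
}

#' Generate an ideal alpha-helix
#'
#' C-alpha-trace mode (default) places residue `i` parametrically on a
#' cylinder along +z at angle `i * twist` and height `i * rise`. With
#' `full_backbone = TRUE` the N, C-alpha, C and O backbone atoms are built
#' from ideal internal coordinates (bond lengths/angles and the canonical
#' helical dihedrals phi = -57, psi = -47 degrees), which reproduces the
#' ~1.5 angstrom rise and ~100 degree twist without using the parametric
#' values. First residue is numbered 1; a helix annotation covering the
#' full range is attached.
#'
#' @param spec A [helix_spec()].
#' @param chain Chain identifier (default "A").
#' @param full_backbone Build N/CA/C/O instead of a C-alpha trace.
#' @return A `lobe_structure`.
#' @export
make_ideal_helix <- function(spec = helix_spec(), chain = "A",
                             full_backbone = FALSE) {
  n <- spec$n_res
  seq1 <- if (is.null(spec$sequence)) rep("A", n)
          else rep(strsplit(spec$sequence, "")[[1]], length.out = n)
  resnames <- unname(.aa_one_to_three[seq1])
  if (!full_backbone) {
    i <- seq_len(n)
    th <- deg2rad(i * spec$twist)
    atoms <- tibble(
      chain = chain, resno = i, resname = resnames, elety = "CA",
      element = "C",
      x = spec$ca_radius * cos(th), y = spec$ca_radius * sin(th),
      z = i * spec$rise
    )
  } else {
    atoms <- ideal_backbone(n, resnames, chain)
  }
  new_structure(atoms,
                helices = tibble(chain = chain, start = 1L, end = n),
                source_id = "ideal-helix")
}

# Next-atom placement from bond length, bond angle (deg) and dihedral (deg)
# relative to three previously placed atoms (natural extension reference
# frame).
nerf_place <- function(a, b, c, length, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(th), length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

ideal_backbone <- function(n, resnames, chain,
                           phi = -57, psi = -47, omega = 180) {
  # bond lengths / angles (angstrom / degrees), standard peptide values
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8
  coords <- list()
  N <- c(0, 0, 0)
  CA <- c(b_n_ca, 0, 0)
  th <- deg2rad(a_n_ca_c)
  C <- CA + b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    O <- nerf_place(N, CA, C, b_c_o, a_ca_c_o, psi + 180)
    coords[[i]] <- rbind(N = N, CA = CA, C = C, O = O)
    if (i < n) {
      N2 <- nerf_place(N, CA, C, b_c_n, a_ca_c_n, psi)
      CA2 <- nerf_place(CA, C, N2, b_n_ca, a_c_n_ca, omega)
      C2 <- nerf_place(C, N2, CA2, b_ca_c, a_n_ca_c, phi)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  atoms <- purrr::map_dfr(seq_len(n), function(i) {
    xyz <- coords[[i]]
    tibble(chain = chain, resno = i, resname = resnames[i],
           elety = rownames(xyz),
           element = substr(rownames(xyz), 1, 1),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  # orient the helix axis along +z for convenience
  ca <- as.matrix(atoms[atoms$elety == "CA", c("x", "y", "z")])
  centroid <- colMeans(ca)
  axis <- principal_axis(ca)
  if (sum(axis * (ca[nrow(ca), ] - ca[1, ])) < 0) axis <- -axis
  z <- c(0, 0, 1)
  v <- c(axis[2] * z[3] - axis[3] * z[2],
         axis[3] * z[1] - axis[1] * z[3],
         axis[1] * z[2] - axis[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(axis * z)
  R <- if (s < 1e-12) diag(3) * sign(cth) else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  xyz <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, centroid) %*% t(R)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Generate a two-helix dimer with known geometry
#'
#' Chain A is an ideal helix with its axis along +z and C-alpha centroid at
#' the origin; chain B is a copy rotated by `cross_angle` degrees about the
#' x axis (the common normal of the two axes) and translated by
#' `separation` angstrom along x. The measured crossing angle between the
#' two N-to-C axes therefore equals `cross_angle` by construction, and the
#' axis-to-axis separation equals `separation`; both are recorded as
#' ground-truth attributes (`true_cross_angle`, `true_separation`).
#'
#' @param spec A [helix_spec()].
#' @param separation Axis-to-axis distance in angstrom (> 0).
#' @param cross_angle Crossing angle in degrees.
#' @param full_backbone Passed to [make_ideal_helix()].
#' @return A two-chain `lobe_structure` with helix annotations.
#' @export
make_helix_dimer <- function(spec = helix_spec(30), separation = 9,
                             cross_angle = 140.7, full_backbone = FALSE) {
  if (separation <= 0) abort("separation must be positive")
  a <- make_ideal_helix(spec, chain = "A", full_backbone = full_backbone)
  at <- as_tibble(a)
  ca <- as.matrix(at[at$elety == "CA", c("x", "y", "z")])
  centroid <- colMeans(ca)
  at$x <- at$x - centroid[1]; at$y <- at$y - centroid[2]
  at$z <- at$z - centroid[3]
  R <- rotation_about_axis(c(1, 0, 0), cross_angle)
  xyz_b <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  bt <- at
  bt$chain <- "B"
  bt$x <- xyz_b[, 1] + separation; bt$y <- xyz_b[, 2]; bt$z <- xyz_b[, 3]
  out <- new_structure(
    bind_rows(at, bt),
    helices = tibble(chain = c("A", "B"), start = 1L, end = spec$n_res),
    source_id = "ideal-helix-dimer"
  )
  attr(out, "true_cross_angle") <- cross_angle
  attr(out, "true_separation") <- separation
  out
}

# Two- to m-residue column distribution hitting a target entropy in [0, 1]:
# one residue carries probability a, the other m - 1 share the rest evenly;
# a is solved so that -sum p log20 p equals the target.
entropy_mixture <- function(target, residues) {
  if (target < 0 || target > 1)
    abort("target entropy must lie in [0, 1] (log-base-20 scale)")
  if (target == 0) return(list(residues = residues[1], probs = 1))
  m <- max(2, ceiling(20^target))
  m <- min(m, 20)
  ent <- function(a) {
    rest <- (1 - a) / (m - 1)
    p <- c(a, rep(rest, m - 1))
    p <- p[p > 0]
    -sum(p * log(p, base = 20))
  }
  if (target >= ent(1 / m) - 1e-12) {
    a <- 1 / m
  } else {
    a <- stats::uniroot(function(a) ent(a) - target,
                        c(1 / m, 1 - 1e-12), tol = 1e-12)$root
  }
  rest <- (1 - a) / (m - 1)
  list(residues = residues[seq_len(m)], probs = c(a, rep(rest, m - 1)))
}

#' Generate a synthetic alignment with controlled statistics
#'
#' Builds an MSA whose columns follow prescribed target entropies (log base
#' 20), gap fractions and near-duplicate redundancy structure. Each column
#' draws residues from a small mixture parameterized to hit the target
#' entropy in expectation; redundancy clusters are near-copies of a seed
#' sequence differing by a fixed number of random point mutations. Ground
#' truth (per-column target profile, mixture, cluster assignment) is stored
#' in attributes `target_profile` and `clusters` for recovery tests.
#'
#' @param n_seq Number of sequences.
#' @param length Alignment width.
#' @param conservation_profile Per-column target entropy in `[0, 1]`
#'   (recycled; default 0.2).
#' @param gap_profile Per-column gap probability (recycled; default 0).
#' @param redundancy Optional `list(n_clusters =, mutations_per_copy =)`;
#'   sequences are then distributed over `n_clusters` clusters of
#'   near-copies.
#' @param seed Mandatory integer seed.
#' @return A `lobe_msa` with ground-truth attributes.
#' @export
make_synthetic_msa <- function(n_seq, length, conservation_profile = 0.2,
                               gap_profile = 0, redundancy = NULL, seed) {
  if (missing(seed)) abort("seed is required")
  if (any(conservation_profile > 1))
    abort("target entropy above 1 is unreachable with 20 residue types")
  withr::local_seed(seed)
  targets <- rep(conservation_profile, length.out = length)
  gaps <- rep(gap_profile, length.out = length)
  mixtures <- lapply(targets, function(s)
    entropy_mixture(s, sample(.aa_standard)))
  draw_seq <- function() {
    vapply(mixtures, function(mx)
      if (length(mx$probs) == 1) mx$residues
      else sample(mx$residues, 1, prob = mx$probs), character(1))
  }
  if (is.null(redundancy)) {
    rows <- t(vapply(seq_len(n_seq), function(i) draw_seq(), character(length)))
    clusters <- seq_len(n_seq)
  } else {
    nc <- redundancy$n_clusters
    mut <- redundancy$mutations_per_copy %||% 1
    if (is.null(nc) || nc < 1 || nc > n_seq)
      abort("redundancy$n_clusters must be in [1, n_seq]")
    seeds <- lapply(seq_len(nc), function(i) draw_seq())
    clusters <- rep(seq_len(nc), length.out = n_seq)
    rows <- t(vapply(seq_len(n_seq), function(i) {
      s <- seeds[[clusters[i]]]
      if (mut > 0) {
        pos <- sample(length, min(mut, length))
        s[pos] <- vapply(s[pos], function(old)
          sample(setdiff(.aa_standard, old), 1), character(1))
      }
      s
    }, character(length)))
  }
  if (any(gaps > 0)) {
    gm <- matrix(runif(n_seq * length) <
                   matrix(gaps, n_seq, length, byrow = TRUE), n_seq, length)
    rows[gm] <- "-"
  }
  out <- msa(sprintf("s%04d", seq_len(n_seq)), apply(rows, 1, paste, collapse = ""))
  attr(out, "target_profile") <- tibble(
    column = seq_len(length), target_entropy = targets, gap_prob = gaps
  )
  attr(out, "mixtures") <- mixtures
  attr(out, "clusters") <- clusters
  out
}

#' Generate a noisy synthetic scattering curve from coordinates
#'
#' Computes the Debye intensity of a structure and applies seeded
#' multiplicative Gaussian noise of relative magnitude `noise_frac`; the
#' sigma column is `noise_frac * I` (omitted when `noise_frac = 0`, in
#' which case the curve equals [debye_intensity()] exactly).
#'
#' @param structure A `lobe_structure`.
#' @param q q grid in inverse angstrom.
#' @param noise_frac Relative noise level (default 0.01).
#' @param seed Mandatory integer seed.
#' @param granularity Passed to [debye_intensity()].
#' @return A [scattering_curve()].
#' @export
make_synthetic_curve <- function(structure, q = seq(0.002, 0.5, by = 0.002),
                                 noise_frac = 0.01, seed,
                                 granularity = "atom") {
  if (missing(seed)) abort("seed is required")
  base <- debye_intensity(structure, q, granularity = granularity)
  if (noise_frac == 0) return(base)
  withr::local_seed(seed)
  noisy <- base$intensity * (1 + rnorm(nrow(base), 0, noise_frac))
  scattering_curve(base$q, noisy, sigma = noise_frac * base$intensity)
}
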