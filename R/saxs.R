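#' Scattering curve container
#'
#' A 1-D small-angle scattering curve: momentum transfer `q` (inverse
#' angstrom, strictly increasing, non-negative), intensity (arbitrary
#' units) and optional uncertainties `sigma`.
#'
#' @param q Numeric vector of q values.
#' @param intensity Numeric vector of intensities.
#' @param sigma Optional numeric vector of 1-sigma uncertainties.
#' @return A `scattering_curve` tibble.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity))
  if (any(q < 0) || any(diff(q) <= 0))
    abort("q grid must be non-negative and strictly increasing")
  out <- tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    out$sigma <- sigma
  }
  structure(out, class = c("scattering_curve", class(tibble())))
}

#' Read / write 3-column scattering data
#'
#' Whitespace- or comma-separated text with columns q, I and optionally
#' sigma; lines starting with `#` are skipped. `q_unit = "nm"` converts an
#' inverse-nanometre grid to inverse angstrom on input.
#'
#' @param path File path.
#' @param q_unit `"A"` (inverse angstrom, default) or `"nm"`.
#' @return A [scattering_curve()].
#' @export
read_saxs_curve <- function(path, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  vals <- suppressWarnings(lapply(fields, as.numeric))
  # tolerate leading non-numeric header lines, but nothing past them
  numeric_ok <- !vapply(vals, anyNA, logical(1))
  first_num <- match(TRUE, numeric_ok)
  if (is.na(first_num)) abort("no numeric data in scattering file")
  keep <- seq(first_num, length(vals))
  if (!all(numeric_ok[keep]))
    abort("non-numeric values in scattering file")
  vals <- vals[keep]
  ncol <- lengths(fields[keep])
  if (any(ncol < 2)) abort("scattering file must have at least 2 columns")
  q <- vapply(vals, `[`, 0, 1)
  i <- vapply(vals, `[`, 0, 2)
  s <- if (all(ncol >= 3)) vapply(vals, `[`, 0, 3) else NULL
  if (q_unit == "nm") q <- q / 10
  scattering_curve(q, i, s)
}

#' @rdname read_saxs_curve
#' @param curve A `scattering_curve`.
#' @export
write_saxs_curve <- function(curve, path) {
  df <- as_tibble(curve)
  readr::write_tsv(df, path, col_names = TRUE)
  invisible(path)
}

#' Debye scattering intensity from coordinates
#'
#' Computes the orientationally averaged scattering intensity
#' `I(q) = sum_ij f_i f_j sin(q d_ij) / (q d_ij)` over point scatterers,
#' with the q -> 0 limit handled analytically (`I(0) = (sum f)^2`).
#' Scattering centers are either all heavy atoms (weight = element electron
#' count) or one center per residue at the C-alpha position (weight =
#' residue electron count), the usual coarse-graining for desk-scale model
#' curves. No hydration shell or excluded-volume term is included, so the
#' result corresponds to the in-vacuo form factor of the model.
#'
#' @param structure A `lobe_structure`.
#' @param q Numeric q grid (inverse angstrom).
#' @param granularity `"atom"` or `"residue"`.
#' @return A [scattering_curve()].
#' @export
debye_intensity <- function(structure, q = seq(0, 0.5, by = 0.005),
                            granularity = c("atom", "residue")) {
  granularity <- match.arg(granularity)
  at <- as_tibble(remove_hydrogens(structure))
  if (granularity == "atom") {
    f <- .atomic_electrons[at$element]
    f[is.na(f)] <- mean(.atomic_electrons)
    xyz <- as.matrix(at[, c("x", "y", "z")])
  } else {
    ca <- filter(at, .data$elety == "CA")
    if (nrow(ca) == 0) abort("no C-alpha atoms for residue-level centers")
    f <- .residue_electrons[three_to_one(ca$resname)]
    f[is.na(f)] <- mean(.residue_electrons)
    xyz <- as.matrix(ca[, c("x", "y", "z")])
  }
  f <- as.numeric(f)
  n <- nrow(xyz)
  i0 <- sum(f)^2
  if (n == 1) return(scattering_curve(q, rep(f^2, length(q))))
  d <- as.numeric(dist(xyz))
  # products f_i f_j for i < j, matching dist() ordering (column-major)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  ff <- f[ij[, 1]] * f[ij[, 2]]
  self <- sum(f^2)
  intensity <- vapply(q, function(qk) {
    if (qk == 0) return(i0)
    x <- qk * d
    self + 2 * sum(ff * sin(x) / x)
  }, numeric(1))
  scattering_curve(q, intensity)
}

#' Guinier fit of the low-q region
#'
#' Iterative linear fit of `ln I` against `q^2` on the largest low-q window
#' satisfying `q * Rg <= qrg_max`, the standard estimate of the radius of
#' gyration and forward scattering from a measured curve:
#' `Rg = sqrt(-3 * slope)`, `I(0) = exp(intercept)`.
#'
#' @param curve A `scattering_curve`.
#' @param qrg_max Upper limit of `q * Rg` for the Guinier regime
#'   (dimensionless, default 1.3).
#' @param min_points Minimum number of points in the window (default 5).
#' @return A `guinier_fit`: `rg`, `i0`, `n_points`, `qmin`, `qmax`,
#'   `residual` (RMS of ln-space residuals). `glance()` returns a one-row
#'   tibble.
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, min_points = 5) {
  df <- as_tibble(curve)
  df <- filter(df, .data$q > 0, .data$intensity > 0)
  if (nrow(df) < min_points) abort("too few usable points for a Guinier fit")
  fit_window <- function(sub) {
    fit <- lm(log(sub$intensity) ~ I(sub$q^2))
    slope <- coef(fit)[[2]]
    list(slope = slope, rg = sqrt(max(-3 * slope, 0)),
         i0 = exp(coef(fit)[[1]]),
         residual = sqrt(mean(stats::residuals(fit)^2)))
  }
  # start from a conservative low-q window, then iterate q * Rg <= qrg_max;
  # a non-negative slope on a short noisy window just means the window is
  # too small to resolve the decay, so it is widened before giving up
  window <- seq_len(max(min_points, min(10, nrow(df))))
  for (iter in 1:50) {
    est <- fit_window(df[window, ])
    if (!is.finite(est$slope) || est$slope >= 0) {
      if (length(window) >= nrow(df))
        abort("non-decaying low-q data: Guinier slope is not negative")
      window <- seq_len(min(nrow(df), 2 * length(window)))
      next
    }
    new_window <- which(df$q * est$rg <= qrg_max)
    if (length(new_window) < min_points)
      new_window <- seq_len(min_points)
    if (identical(new_window, window)) break
    window <- new_window
  }
  if (!is.finite(est$slope) || est$slope >= 0)
    abort("non-decaying low-q data: Guinier slope is not negative")
  structure(list(
    rg = est$rg, i0 = est$i0, n_points = length(window),
    qmin = min(df$q[window]), qmax = max(df$q[window]),
    qrg_max = qrg_max, residual = est$residual
  ), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<Guinier fit: Rg %.2f A, I(0) %.4g, %d points (q %.4f-%.4f, qRg <= %.2f)>\n",
    x$rg, x$i0, x$n_points, x$qmin, x$qmax, x$qrg_max))
  invisible(x)
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(rg = x$rg, i0 = x$i0, n_points = x$n_points,
         qmin = x$qmin, qmax = x$qmax, residual = x$residual)
}

#' Scale a model curve onto experimental data
#'
#' Least-squares fit of `scale * I_model + constant` to an experimental
#' curve with uncertainties, the standard way to compare a model scattering
#' profile computed from coordinates with measured data. The model is
#' linearly interpolated onto the experimental q grid over the overlapping
#' range, and the reduced chi-square
#' `chi2 = sum(((s I_m + c - I_e) / sigma)^2) / (N - p)` is reported.
#'
#' @param model A `scattering_curve` (computed; no sigma needed).
#' @param experiment A `scattering_curve` with a `sigma` column.
#' @param constant Fit an additive background constant (default `TRUE`).
#' @return A `saxs_fit`: `scale`, `constant`, `chi_reduced`, `n`, and the
#'   per-point `fitted` tibble.
#' @export
fit_model_to_curve <- function(model, experiment, constant = TRUE) {
  me <- as_tibble(experiment)
  mm <- as_tibble(model)
  if (!"sigma" %in% names(me) || any(!is.finite(me$sigma)) || any(me$sigma <= 0))
    abort("experiment curve must carry positive uncertainties (sigma)")
  keep <- me$q >= min(mm$q) & me$q <= max(mm$q)
  if (sum(keep) < (2 + constant))
    abort("no (or too little) q-range overlap between model and experiment")
  me <- me[keep, ]
  im <- approx(mm$q, mm$intensity, xout = me$q)$y
  w <- 1 / me$sigma^2
  if (constant) {
    X <- cbind(im, 1)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * me$intensity))
    scale <- beta[1]; const <- beta[2]
  } else {
    scale <- sum(w * im * me$intensity) / sum(w * im^2)
    const <- 0
  }
  resid <- (scale * im + const - me$intensity) / me$sigma
  p <- if (constant) 2 else 1
  chi_reduced <- sum(resid^2) / (nrow(me) - p)
  structure(list(
    scale = as.numeric(scale), constant = as.numeric(const),
    chi_reduced = chi_reduced, n = nrow(me),
    fitted = tibble(q = me$q, intensity = me$intensity, sigma = me$sigma,
                    model = as.numeric(scale * im + const))
  ), class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<model-to-data fit: scale %.4g, constant %.4g, reduced chi^2 %.3f (n = %d)>\n",
              x$scale, x$constant, x$chi_reduced, x$n))
  invisible(x)
}

#' @export
glance.saxs_fit <- function(x, ...) {
  tibble(scale = x$scale, constant = x$constant,
         chi_reduced = x$chi_reduced, n = x$n)
}
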