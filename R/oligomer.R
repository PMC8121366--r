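#' Monomer mass from a protein sequence
#'
#' Average (not monoisotopic) molecular mass: sum of residue masses plus
#' one water, reported in kDa. Ambiguity codes are rejected since they have
#' no defined mass.
#'
#' @param sequence One-letter protein sequence (non-empty, standard
#'   residues only).
#' @return Mass in kDa.
#' @export
monomer_mass_from_sequence <- function(sequence) {
  if (!nzchar(sequence)) abort("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.residue_masses))
  if (length(bad) > 0)
    abort(paste0("non-standard residue symbol(s): ", paste(bad, collapse = ", ")))
  (sum(.residue_masses[aa]) + .water_mass) / 1000
}

#' Molecular mass from an envelope volume
#'
#' Converts the volume of a low-resolution (bead-model) envelope to a mass
#' using a protein-specific volume, `MM [Da] = 1000 * V [nm^3] / v`, with
#' the default `v = 1.21` A^3/Da. The divisor is configurable because
#' bead-model conventions vary.
#'
#' @param volume Envelope volume in nm^3 (positive).
#' @param specific_volume Specific volume in A^3/Da (default 1.21).
#' @return Mass in kDa.
#' @export
mass_from_envelope_volume <- function(volume, specific_volume = 1.21) {
  if (!is.finite(volume) || volume <= 0) abort("volume must be positive")
  if (specific_volume <= 0) abort("specific_volume must be positive")
  1000 * volume / specific_volume / 1000
}

#' @rdname mass_from_envelope_volume
#' @param mass Mass in kDa.
#' @return `envelope_volume_from_mass()`: volume in nm^3.
#' @export
envelope_volume_from_mass <- function(mass, specific_volume = 1.21) {
  if (!is.finite(mass) || mass <= 0) abort("mass must be positive")
  mass * specific_volume
}

# Aggregate relative deviation of mass ratios from each candidate state
# (the decision core shared by call_oligomeric_state and the recovery
# simulation).
state_deviations <- function(ratios, max_states, aggregate) {
  vapply(seq_len(max_states), function(k) {
    dk <- abs(ratios / k - 1)
    if (aggregate == "median") stats::median(dk) else mean(dk)
  }, numeric(1))
}

#' Consensus oligomeric state from mass estimates
#'
#' Infers the number of subunits of a solution assembly from one or more
#' experimental mass estimates (e.g. SEC-MALS, envelope volume, Bayesian
#' scattering estimates) and the sequence-derived monomer mass. For every
#' candidate state `k` the relative deviations `|m_j / (k * monomer) - 1|`
#' are aggregated across estimates and the consensus is the `k` minimizing
#' the aggregate. The default aggregation is the median, which is robust
#' to a single discordant estimate — with several mass estimates of one
#' species it is the majority that should carry the call, not the outlier.
#' The mean is available via `aggregate = "mean"`. Per-estimate nearest
#' states are always reported alongside, and the call is flagged ambiguous
#' when the best aggregate deviation exceeds `dev_threshold` or when the
#' runner-up state comes within `tie_window` of the best.
#'
#' @param estimates Numeric vector of masses in kDa, or a data frame with a
#'   `value` column (optional `method`, `uncertainty`).
#' @param monomer_mass Monomer mass in kDa (positive).
#' @param max_states Largest candidate state (default 8).
#' @param dev_threshold Ambiguity threshold on the best aggregate relative
#'   deviation (default 0.25).
#' @param tie_window Ambiguity window between best and runner-up aggregate
#'   deviations (default 0.02).
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return An `oligomer_call`: `consensus_state`, `ambiguous`,
#'   `monomer_mass`, `max_rel_dev`, per-estimate tibble `estimates`
#'   (`value`, `method`, `ratio`, `nearest_state`, `rel_dev`), and the
#'   per-state aggregate deviations `state_deviation`. `tidy()` returns the
#'   per-estimate table, `glance()` the one-row summary.
#' @export
call_oligomeric_state <- function(estimates, monomer_mass, max_states = 8,
                                  dev_threshold = 0.25, tie_window = 0.02,
                                  aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(estimates)) {
    values <- estimates$value %||% estimates$mass_kda
    methods <- as.character(estimates$method %||% rep("unknown", length(values)))
  } else {
    values <- as.numeric(estimates)
    methods <- rep("unknown", length(values))
  }
  if (length(values) == 0) abort("at least one mass estimate required")
  if (any(!is.finite(values) | values <= 0)) abort("mass estimates must be positive")
  if (!is.finite(monomer_mass) || monomer_mass <= 0)
    abort("monomer_mass must be positive")
  ratios <- values / monomer_mass
  ks <- seq_len(max_states)
  devs <- state_deviations(ratios, max_states, aggregate)
  consensus <- ks[which.min(devs)]
  best <- min(devs)
  runner_up <- min(devs[ks != consensus])
  rel_dev <- abs(ratios / consensus - 1)
  est_tbl <- tibble(
    value = values, method = methods, ratio = ratios,
    nearest_state = pmin(pmax(round(ratios), 1L), max_states),
    rel_dev = rel_dev
  )
  structure(list(
    consensus_state = consensus,
    ambiguous = best > dev_threshold || (runner_up - best) < tie_window,
    monomer_mass = monomer_mass,
    max_rel_dev = max(rel_dev),
    estimates = est_tbl,
    state_deviation = tibble(state = ks, deviation = devs),
    aggregate = aggregate, dev_threshold = dev_threshold,
    tie_window = tie_window
  ), class = "oligomer_call")
}

#' @export
print.oligomer_call <- function(x, ...) {
  nm <- c("1" = "monomer", "2" = "dimer", "3" = "trimer", "4" = "tetramer",
          "5" = "pentamer", "6" = "hexamer", "7" = "heptamer", "8" = "octamer")
  lab <- nm[as.character(x$consensus_state)]
  cat(sprintf(
    "<oligomeric-state call: %d (%s)%s; monomer %.3f kDa, max relative deviation %.3f>\n",
    x$consensus_state, ifelse(is.na(lab), "higher oligomer", lab),
    if (x$ambiguous) " [ambiguous]" else "", x$monomer_mass, x$max_rel_dev))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.oligomer_call <- function(x, ...) x$estimates

#' @export
glance.oligomer_call <- function(x, ...) {
  tibble(consensus_state = x$consensus_state, ambiguous = x$ambiguous,
         monomer_mass = x$monomer_mass, max_rel_dev = x$max_rel_dev,
         n_estimates = nrow(x$estimates), aggregate = x$aggregate)
}

#' Oligomeric-state calls for a table of constructs
#'
#' Applies [call_oligomeric_state()] per construct to a tidy table of mass
#' estimates such as the one shipped with the package (see
#' [darc_mass_table()]).
#'
#' @param masses Data frame with columns `construct`, `method`, `value`
#'   (kDa).
#' @param monomers Data frame with columns `construct`, `monomer_kda`.
#' @param ... Passed to [call_oligomeric_state()].
#' @return Tibble with one row per construct: `construct`, `monomer_kda`,
#'   `consensus_state`, `ambiguous`, `max_rel_dev`, `n_estimates`.
#' @export
call_oligomeric_states <- function(masses, monomers, ...) {
  masses <- as_tibble(masses)
  monomers <- as_tibble(monomers)
  stopifnot(all(c("construct", "value") %in% names(masses)),
            all(c("construct", "monomer_kda") %in% names(monomers)))
  purrr::map_dfr(monomers$construct, function(cn) {
    est <- filter(masses, .data$construct == cn)
    m0 <- monomers$monomer_kda[monomers$construct == cn]
    call <- call_oligomeric_state(est, m0, ...)
    tibble(construct = cn, monomer_kda = m0,
           consensus_state = call$consensus_state,
           ambiguous = call$ambiguous,
           max_rel_dev = call$max_rel_dev,
           n_estimates = nrow(est))
  })
}

#' Solution mass estimates for the fly Arc lobe constructs
#'
#' The published solution mass estimates (SAXS envelope volume, Bayesian
#' scattering estimate, SEC-MALS) and sequence-derived monomer masses for
#' the four isolated lobe constructs of the two Drosophila Arc isoforms,
#' shipped as plain-text package data. These are the worked-example inputs
#' for [call_oligomeric_state()]; the reported solution states are dimer
#' (dArc1-NL), tetramer (dArc2-NL), dimer (dArc1-CL) and dimer (dArc2-CL).
#'
#' @return List of two tibbles: `estimates` (`construct`, `method`,
#'   `value` in kDa) and `monomers` (`construct`, `monomer_kda`, plus the
#'   published `rg_nm`, `dmax_nm`).
#' @export
darc_mass_table <- function() {
  path <- system.file("extdata", "darc_mass_estimates.csv",
                      package = "lobescope", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  list(
    estimates = select(filter(df, .data$method != "monomer_sequence"),
                       "construct", "method", "value"),
    monomers = df |>
      filter(.data$method == "monomer_sequence") |>
      select("construct", monomer_kda = "value", "rg_nm", "dmax_nm")
  )
}

#' Seeded recovery simulation for the consensus caller
#'
#' Draws sets of mass estimates `k * monomer * (1 + e)`, with multiplicative
#' Gaussian noise `e ~ N(0, noise)`, for each true state `k`, and measures
#' how often [call_oligomeric_state()] recovers `k`.
#'
#' @param states True states to simulate (default 1:6).
#' @param n_reps Replicates per state (default 1000).
#' @param n_estimates Estimates per replicate (default 3, as in a typical
#'   mass table combining MALS with two scattering-derived estimates).
#' @param noise Relative noise standard deviation (default 0.08).
#' @param monomer_mass Monomer mass in kDa (default 10; the call is
#'   scale-invariant).
#' @param seed Mandatory integer seed.
#' @param max_states,aggregate As in [call_oligomeric_state()].
#' @return Tibble with `state`, `n_correct`, `recovery`, plus attribute
#'   `overall` (fraction correct across all draws).
#' @export
simulate_state_recovery <- function(states = 1:6, n_reps = 1000,
                                    n_estimates = 3, noise = 0.08,
                                    monomer_mass = 10, seed,
                                    max_states = 8,
                                    aggregate = c("median", "mean")) {
  if (missing(seed)) abort("seed is required")
  aggregate <- match.arg(aggregate)
  withr::local_seed(seed)
  res <- purrr::map_dfr(states, function(k) {
    correct <- 0L
    for (r in seq_len(n_reps)) {
      est <- k * monomer_mass * (1 + rnorm(n_estimates, 0, noise))
      est <- pmax(est, 0.01 * monomer_mass)
      devs <- state_deviations(est / monomer_mass, max_states, aggregate)
      if (which.min(devs) == k) correct <- correct + 1L
    }
    tibble(state = k, n_correct = correct, recovery = correct / n_reps)
  })
  structure(res, overall = sum(res$n_correct) / (length(states) * n_reps))
}
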