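#' Interface contact criteria
#'
#' Distance cutoffs for classifying inter-subunit contacts. Detection is
#' distance-only (no donor-hydrogen angles), since crystal structures of
#' this size are routinely deposited without hydrogens; a salt bridge takes
#' precedence over a hydrogen bond for the same atom pair so nothing is
#' double-counted.
#'
#' @param hbond_max Maximum donor-acceptor N/O distance for a hydrogen bond
#'   (angstrom, default 3.5).
#' @param saltbridge_max Maximum distance between charged-group atoms
#'   (Lys NZ, Arg NE/NH1/NH2, His ND1/NE2 vs Asp OD1/OD2, Glu OE1/OE2;
#'   default 4.0).
#' @param nonpolar_max Maximum carbon-carbon distance for a nonpolar
#'   contact (default 4.0).
#' @return A `contact_criteria` list.
#' @export
contact_criteria <- function(hbond_max = 3.5, saltbridge_max = 4.0,
                             nonpolar_max = 4.0) {
  if (any(c(hbond_max, saltbridge_max, nonpolar_max) <= 0))
    abort("all contact cutoffs must be positive")
  structure(list(hbond_max = hbond_max, saltbridge_max = saltbridge_max,
                 nonpolar_max = nonpolar_max),
            class = "contact_criteria")
}

check_parts <- function(structure, part_a, part_b) {
  chains <- structure_chains(structure)
  if (length(part_a) == 0 || length(part_b) == 0)
    abort("both parts must name at least one chain")
  if (length(intersect(part_a, part_b)) > 0)
    abort("part definitions overlap")
  missing <- setdiff(c(part_a, part_b), chains)
  if (length(missing) > 0)
    abort(paste0("chain(s) not in structure: ", paste(missing, collapse = ", ")))
}

#' Buried surface area of a two-part complex
#'
#' Computes `bsa_total = SASA(A alone) + SASA(B alone) - SASA(AB)`, the
#' solvent-accessible area lost on complex formation summed over both
#' subunits; `interface_area = bsa_total / 2` is the usual one-sided
#' interface area. Interface residues are those losing more than 0.1
#' angstrom^2 of accessible area.
#'
#' @param complex A `lobe_structure` containing both parts.
#' @param part_a,part_b Character vectors of chain ids (disjoint).
#' @param params A [radii_set()].
#' @return An `interface_report` with `bsa_total`, `interface_area` and a
#'   `residues` tibble (`part`, `chain`, `resno`, `insert`, `resname`,
#'   `dsasa`). `glance()` gives the one-row summary.
#' @export
buried_surface_area <- function(complex, part_a, part_b,
                                params = radii_set()) {
  check_parts(complex, part_a, part_b)
  s_ab <- sasa(complex, params)
  s_a <- sasa(select_chains(complex, part_a), params)
  s_b <- sasa(select_chains(complex, part_b), params)
  alone <- bind_rows(s_a, s_b)
  bsa_total <- sum(alone$sasa) - sum(s_ab$sasa)
  per_res <- function(tab) {
    tab |>
      group_by(.data$chain, .data$resno, .data$insert, .data$resname) |>
      summarise(sasa = sum(.data$sasa), .groups = "drop")
  }
  joined <- left_join(per_res(alone), rename(per_res(s_ab), in_complex = "sasa"),
                      by = c("chain", "resno", "insert", "resname")) |>
    mutate(dsasa = .data$sasa - .data$in_complex,
           part = ifelse(.data$chain %in% part_a, "A", "B")) |>
    filter(.data$dsasa > 0.1) |>
    arrange(.data$part, .data$chain, .data$resno, .data$insert) |>
    select("part", "chain", "resno", "insert", "resname", "dsasa")
  structure(list(
    bsa_total = bsa_total, interface_area = bsa_total / 2,
    residues = joined, part_a = part_a, part_b = part_b,
    hbonds = NULL, saltbridges = NULL, nonpolar_contacts = NULL
  ), class = "interface_report")
}

#' Classify inter-subunit contacts
#'
#' Enumerates atom pairs across the interface and classifies them by
#' distance: salt bridges between side-chain charged groups (which take
#' precedence), hydrogen bonds between remaining N/O pairs, and nonpolar
#' carbon-carbon contacts. Output ordering is deterministic
#' (chain, residue number, atom name).
#'
#' @param complex A `lobe_structure`.
#' @param part_a,part_b Character vectors of chain ids (disjoint).
#' @param criteria A [contact_criteria()].
#' @return An `interface_report` with tibbles `hbonds` and `saltbridges`
#'   (donor/acceptor atoms and distances) and the count
#'   `nonpolar_contacts`.
#' @export
classify_interface_contacts <- function(complex, part_a, part_b,
                                        criteria = contact_criteria()) {
  check_parts(complex, part_a, part_b)
  at <- as_tibble(remove_hydrogens(complex))
  A <- filter(at, .data$chain %in% part_a)
  B <- filter(at, .data$chain %in% part_b)
  if (nrow(A) == 0 || nrow(B) == 0) abort("both parts must contain atoms")
  dmat <- sqrt(outer(A$x, B$x, `-`)^2 + outer(A$y, B$y, `-`)^2 +
                 outer(A$z, B$z, `-`)^2)

  is_charged <- function(tab, table) {
    keys <- map2(names(table), table, function(rn, at) paste(rn, at))
    paste(tab$resname, tab$elety) %in% unlist(keys)
  }
  basic_a <- is_charged(A, .saltbridge_basic)
  acidic_a <- is_charged(A, .saltbridge_acidic)
  basic_b <- is_charged(B, .saltbridge_basic)
  acidic_b <- is_charged(B, .saltbridge_acidic)
  sb_pair <- (outer(basic_a, acidic_b, `&`) | outer(acidic_a, basic_b, `&`)) &
    dmat <= criteria$saltbridge_max

  no_a <- A$element %in% c("N", "O")
  no_b <- B$element %in% c("N", "O")
  hb_pair <- outer(no_a, no_b, `&`) & dmat <= criteria$hbond_max & !sb_pair

  cc_pair <- outer(A$element == "C", B$element == "C") &
    dmat <= criteria$nonpolar_max

  pair_table <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(tibble(chain_a = character(), resno_a = integer(),
                    resname_a = character(), atom_a = character(),
                    chain_b = character(), resno_b = integer(),
                    resname_b = character(), atom_b = character(),
                    distance = numeric()))
    }
    tibble(
      chain_a = A$chain[idx[, 1]], resno_a = A$resno[idx[, 1]],
      resname_a = A$resname[idx[, 1]], atom_a = A$elety[idx[, 1]],
      chain_b = B$chain[idx[, 2]], resno_b = B$resno[idx[, 2]],
      resname_b = B$resname[idx[, 2]], atom_b = B$elety[idx[, 2]],
      distance = dmat[idx]
    ) |>
      arrange(.data$chain_a, .data$resno_a, .data$atom_a,
              .data$chain_b, .data$resno_b, .data$atom_b)
  }
  structure(list(
    bsa_total = NULL, interface_area = NULL, residues = NULL,
    part_a = part_a, part_b = part_b,
    hbonds = pair_table(hb_pair),
    saltbridges = pair_table(sb_pair),
    nonpolar_contacts = sum(cc_pair),
    criteria = criteria
  ), class = "interface_report")
}

#' Full interface analysis
#'
#' Convenience wrapper running [buried_surface_area()] and
#' [classify_interface_contacts()] and merging the results.
#'
#' @inheritParams buried_surface_area
#' @param criteria A [contact_criteria()].
#' @return A complete `interface_report`.
#' @export
interface_analysis <- function(complex, part_a, part_b,
                               params = radii_set(),
                               criteria = contact_criteria()) {
  area <- buried_surface_area(complex, part_a, part_b, params)
  contacts <- classify_interface_contacts(complex, part_a, part_b, criteria)
  area$hbonds <- contacts$hbonds
  area$saltbridges <- contacts$saltbridges
  area$nonpolar_contacts <- contacts$nonpolar_contacts
  area$criteria <- contacts$criteria
  area
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface report>\n")
  if (!is.null(x$bsa_total))
    cat(sprintf("  buried surface area (two-sided): %.1f A^2 (interface area %.1f A^2)\n",
                x$bsa_total, x$interface_area))
  if (!is.null(x$residues))
    cat(sprintf("  interface residues: %d (part A) + %d (part B)\n",
                sum(x$residues$part == "A"), sum(x$residues$part == "B")))
  if (!is.null(x$hbonds))
    cat(sprintf("  hydrogen bonds: %d, salt bridges: %d, nonpolar contacts: %d\n",
                nrow(x$hbonds), nrow(x$saltbridges), x$nonpolar_contacts))
  invisible(x)
}

#' @export
tidy.interface_report <- function(x, ...) {
  out <- list()
  if (!is.null(x$hbonds) && nrow(x$hbonds) > 0)
    out$hbond <- mutate(x$hbonds, type = "hbond")
  if (!is.null(x$saltbridges) && nrow(x$saltbridges) > 0)
    out$salt <- mutate(x$saltbridges, type = "saltbridge")
  if (length(out) == 0) {
    return(tibble(chain_a = character(), resno_a = integer(),
                  resname_a = character(), atom_a = character(),
                  chain_b = character(), resno_b = integer(),
                  resname_b = character(), atom_b = character(),
                  distance = numeric(), type = character()))
  }
  bind_rows(out)
}

#' @export
glance.interface_report <- function(x, ...) {
  tibble(
    bsa_total = x$bsa_total %||% NA_real_,
    interface_area = x$interface_area %||% NA_real_,
    n_interface_residues = if (is.null(x$residues)) NA_integer_ else nrow(x$residues),
    n_hbonds = if (is.null(x$hbonds)) NA_integer_ else nrow(x$hbonds),
    n_saltbridges = if (is.null(x$saltbridges)) NA_integer_ else nrow(x$saltbridges),
    n_nonpolar = x$nonpolar_contacts %||% NA_integer_
  )
}
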