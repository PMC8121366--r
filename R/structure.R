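#' Atom-table structure container
#'
#' A structure is a tibble of atoms (one row per atom) with columns
#' `chain`, `resno`, `insert`, `resname`, `elety` (atom name), `element`,
#' `x`, `y`, `z` (angstrom), `occupancy`, `bfactor` and `altloc`, plus three
#' attributes: `helices` (tibble of `chain`, `start`, `end` from HELIX or
#' annotation records), `assembly_ops` (list of rigid operators, each a list
#' with a 3x3 rotation `R` and translation `t`) and `source_id`. Coordinates
#' are kept in angstrom under author residue numbering; no renumbering is
#' ever performed, so residues can be addressed the way structure papers
#' refer to them (e.g. Ser79).
#'
#' @param atoms Data frame with at least `chain`, `resno`, `resname`,
#'   `elety`, `x`, `y`, `z`. Missing `element` is inferred from the atom
#'   name; missing `insert`/`altloc` default to `""`, `occupancy` to 1 and
#'   `bfactor` to 0.
#' @param helices Optional tibble/data frame with `chain`, `start`, `end`
#'   (author `resno` ranges of annotated helices).
#' @param assembly_ops List of assembly operators; defaults to the identity.
#' @param source_id Free-text identifier carried through reports.
#' @return A `lobe_structure` tibble.
#' @export
new_structure <- function(atoms, helices = NULL, assembly_ops = NULL,
                          source_id = "") {
  atoms <- as_tibble(atoms)
  req <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    abort(paste0("atom table lacks column(s): ", paste(miss, collapse = ", ")))
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$elety)
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  atoms$element <- toupper(atoms$element)
  atoms <- atoms[, c("chain", "resno", "insert", "resname", "elety", "element",
                     "x", "y", "z", "occupancy", "bfactor", "altloc")]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("atom coordinates must be finite")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    abort("occupancies must lie in [0, 1]")
  if (is.null(assembly_ops) || length(assembly_ops) == 0)
    assembly_ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  for (op in assembly_ops) {
    if (!is_rotation(op$R))
      abort("assembly operator rotation blocks must be orthonormal (tol 1e-6)")
  }
  if (!is.null(helices)) {
    helices <- as_tibble(helices)
    stopifnot(all(c("chain", "start", "end") %in% names(helices)))
  }
  structure(
    atoms,
    helices = helices,
    assembly_ops = assembly_ops,
    source_id = source_id,
    class = c("lobe_structure", class(tibble()))
  )
}

# Reattach structure attributes after a dplyr verb stripped them.
restore_structure <- function(atoms, template) {
  new_structure(atoms,
    helices = attr(template, "helices"),
    assembly_ops = attr(template, "assembly_ops"),
    source_id = attr(template, "source_id")
  )
}

#' @export
print.lobe_structure <- function(x, ...) {
  nres <- nrow(distinct(as_tibble(x), .data$chain, .data$resno, .data$insert))
  cat(sprintf(
    "<structure%s: %d chain(s), %d residues, %d atoms, %d assembly op(s)>\n",
    if (nzchar(attr(x, "source_id"))) paste0(" ", attr(x, "source_id")) else "",
    length(unique(x$chain)), nres, nrow(x), length(attr(x, "assembly_ops"))
  ))
  NextMethod()
}

#' Read a structure from PDB or mmCIF
#'
#' Parses a coordinate file into the atom-table container. Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' the lexicographically first altloc identifier); hydrogens are retained and
#' can be dropped with [remove_hydrogens()]. HELIX records and biological
#' assembly (BIOMT) operators are captured when present; when no operators
#' are recorded, the identity operator is stored so that
#' [build_assembly()] is always applicable. For multi-model files only the
#' first model is read.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param dialect `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param keep_water Keep water molecules (default `FALSE`).
#' @return A `lobe_structure` tibble; see [new_structure()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           keep_water = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) abort(paste0(
      "could not parse ", path, " as ", dialect, ": ", conditionMessage(e)
    ))
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0)
    abort(paste0("empty structure (no atom records) in ", path))
  atoms <- tibble(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    elety = at$elety,
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             guess_element(at$elety), at$elesy)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, clamp(at$o, 0, 1)),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  if (!keep_water) atoms <- filter(atoms, !.data$resname %in% c("HOH", "WAT", "DOD"))
  if (nrow(atoms) == 0) abort(paste0("empty structure after filtering: ", path))
  # altloc policy: keep the highest-occupancy conformer, tie -> first altloc;
  # file order of the surviving atoms is preserved
  atoms <- atoms |>
    mutate(.ord = row_number()) |>
    arrange(.data$chain, .data$resno, .data$insert, .data$elety,
            dplyr::desc(.data$occupancy), .data$altloc) |>
    distinct(.data$chain, .data$resno, .data$insert, .data$elety,
             .keep_all = TRUE) |>
    arrange(.data$.ord) |>
    select(-".ord")

  helices <- NULL
  hx <- parsed$helix
  if (!is.null(hx) && length(hx$start) > 0) {
    helices <- tibble(
      chain = as.character(hx$chain),
      start = as.integer(hx$start),
      end = as.integer(hx$end)
    )
  }
  ops <- NULL
  bm <- parsed$remark$biomat
  if (!is.null(bm) && length(bm$mat) > 0) {
    mats <- unlist(bm$mat, recursive = FALSE)
    ops <- lapply(mats, function(m) list(R = m[, 1:3, drop = FALSE], t = m[, 4]))
    keep <- vapply(ops, function(op) is_rotation(op$R), logical(1))
    if (!all(keep)) warn("dropping non-orthonormal assembly operator(s)")
    ops <- ops[keep]
    if (length(ops) == 0) ops <- NULL
  }
  new_structure(atoms, helices = helices, assembly_ops = ops,
                source_id = sub("\\.(pdb|ent|cif|mmcif)$", "",
                                basename(path), ignore.case = TRUE))
}

#' Expand a biological assembly from stored operators
#'
#' Applies the requested assembly operators to every chain of the input and
#' returns the expanded structure. Image chains get deterministic identifiers
#' `<original id><operator index>` (e.g. chain `A` under operator 2 becomes
#' `A2`) so interface reports are reproducible. Helix annotations are carried
#' over to each image chain; the transform is rigid, so all intra-chain
#' distances are preserved.
#'
#' @param structure A `lobe_structure`.
#' @param op_indices Integer vector of operator indices, or `"all"`.
#' @return The expanded `lobe_structure` (identity operator only).
#' @export
build_assembly <- function(structure, op_indices = "all") {
  ops <- attr(structure, "assembly_ops")
  if (identical(op_indices, "all")) op_indices <- seq_along(ops)
  bad <- setdiff(op_indices, seq_along(ops))
  if (length(bad) > 0)
    abort(sprintf("operator(s) %s not available; stored operators: %s",
                  paste(bad, collapse = ", "),
                  paste(seq_along(ops), collapse = ", ")))
  atoms <- as_tibble(structure)
  helices <- attr(structure, "helices")
  pieces <- lapply(op_indices, function(i) {
    op <- ops[[i]]
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(op$R)
    out <- atoms
    out$x <- xyz[, 1] + op$t[1]
    out$y <- xyz[, 2] + op$t[2]
    out$z <- xyz[, 3] + op$t[3]
    out$chain <- paste0(atoms$chain, i)
    out
  })
  new_helices <- NULL
  if (!is.null(helices)) {
    new_helices <- bind_rows(lapply(op_indices, function(i)
      mutate(helices, chain = paste0(.data$chain, i))))
  }
  new_structure(bind_rows(pieces), helices = new_helices,
                assembly_ops = NULL, source_id = attr(structure, "source_id"))
}

#' Write a structure as PDB, optionally with per-residue scores
#'
#' `write_structure()` writes the atom table to a PDB file (coordinates
#' rounded to the 0.001-angstrom precision of the format).
#' `write_structure_with_scores()` additionally places a per-residue score
#' in the B-factor column of every atom of the residue, the standard trick
#' for painting conservation or any other residue-level quantity onto a
#' structure in molecular-graphics software. Scores are clamped to
#' `[0, 999.99]` (the field width of the PDB B-factor column); residues
#' without a score receive `sentinel`.
#'
#' @param structure A `lobe_structure`.
#' @param path Output file path.
#' @param scores Data frame with `chain`, `resno` and `score` columns
#'   (an optional `insert` column is honoured).
#' @param sentinel Value written for unscored residues (default 0).
#' @return Invisibly, the path written.
#' @export
write_structure <- function(structure, path) {
  at <- as_tibble(structure)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      resno = at$resno, resid = at$resname, chain = at$chain,
      insert = ifelse(nzchar(at$insert), at$insert, ""),
      elety = at$elety, o = at$occupancy, b = at$bfactor,
      elesy = at$element
    )
    TRUE
  }, error = function(e) abort(paste0("could not write ", path, ": ",
                                      conditionMessage(e))))
  invisible(path)
}

#' @rdname write_structure
#' @export
write_structure_with_scores <- function(structure, scores, path, sentinel = 0) {
  scores <- as_tibble(scores)
  stopifnot(all(c("chain", "resno", "score") %in% names(scores)))
  if (!"insert" %in% names(scores)) scores$insert <- ""
  at <- as_tibble(structure)
  key_at <- paste(at$chain, at$resno, at$insert, sep = "\r")
  key_sc <- paste(scores$chain, scores$resno, scores$insert, sep = "\r")
  missing_res <- setdiff(key_sc, key_at)
  if (length(missing_res) > 0)
    abort(sprintf("scores refer to %d residue(s) absent from the structure",
                  length(missing_res)))
  idx <- match(key_at, key_sc)
  b <- ifelse(is.na(idx), sentinel, scores$score[idx])
  b[is.na(b)] <- sentinel
  at$bfactor <- round(clamp(b, 0, 999.99), 2)
  write_structure(restore_structure(at, structure), path)
}

#' Drop hydrogen atoms from a structure
#'
#' @param structure A `lobe_structure`.
#' @return The structure without `element == "H"` (or deuterium) atoms.
#' @export
remove_hydrogens <- function(structure) {
  restore_structure(filter(as_tibble(structure),
                           !.data$element %in% c("H", "D")), structure)
}

#' Coordinate matrix of a structure
#'
#' @param structure A `lobe_structure` (or any atom table).
#' @return An N x 3 numeric matrix of coordinates in angstrom.
#' @export
coords_matrix <- function(structure) {
  m <- as.matrix(as_tibble(structure)[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Per-residue table of a structure
#'
#' @param structure A `lobe_structure`.
#' @return Tibble with one row per residue (`chain`, `resno`, `insert`,
#'   `resname`), in file order.
#' @export
residue_table <- function(structure) {
  distinct(as_tibble(structure), .data$chain, .data$resno, .data$insert,
           .data$resname)
}

#' One-letter sequence of a chain
#'
#' @param structure A `lobe_structure`.
#' @param chain Chain identifier; defaults to the first chain.
#' @return Single string; non-standard residues become `"X"`.
#' @export
chain_sequence <- function(structure, chain = NULL) {
  at <- as_tibble(structure)
  chain <- chain %||% at$chain[1]
  res <- filter(residue_table(structure), .data$chain == !!chain)
  if (nrow(res) == 0) abort(paste0("no residues in chain ", chain))
  paste(three_to_one(res$resname), collapse = "")
}

#' Chain identifiers of a structure
#'
#' @param structure A `lobe_structure`.
#' @return Character vector of chain ids in file order.
#' @export
structure_chains <- function(structure) unique(as_tibble(structure)$chain)

# Subset a structure to a chain id set (internal).
select_chains <- function(structure, chains) {
  restore_structure(filter(as_tibble(structure), .data$chain %in% chains),
                    structure)
}
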