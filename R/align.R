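#' Substitution matrices
#'
#' `default_substitution_matrix()` returns BLOSUM62 (from the Biostrings
#' collection). `read_substitution_matrix()` parses a matrix in NCBI text
#' format (`#` comments, a header row of residue symbols, one labelled row
#' per symbol).
#'
#' @param path Path to an NCBI-format matrix file.
#' @return A numeric matrix with residue symbols as dimnames.
#' @export
default_substitution_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' @rdname default_substitution_matrix
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("not a substitution matrix: too few rows")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(NA_real_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, "", 1), header))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (length(vals) != length(header) || anyNA(vals))
      abort(paste0("malformed matrix row for symbol ", rows[[i]][1]))
    m[i, ] <- vals
  }
  m
}

#' Global sequence alignment with affine gaps (Needleman-Wunsch)
#'
#' Computes the optimal global alignment of two protein sequences under an
#' affine gap model in which a gap of length L costs
#' `gap_open + L * gap_extend`. End gaps are penalized by default, so the
#' score is that of a true global alignment; with `end_gaps = FALSE`
#' terminal gaps are free (semi-global alignment). Percent identity follows
#' the EMBOSS convention: 100 x (identical columns) / (total alignment
#' columns); percent similarity counts columns whose substitution score is
#' positive.
#'
#' @param seq_a,seq_b Protein sequences (plain strings, non-empty).
#' @param matrix Substitution matrix (default BLOSUM62). Ambiguity codes are
#'   scored when the matrix carries rows for them.
#' @param gap_open,gap_extend Gap penalties (positive numbers; defaults 10
#'   and 0.5, the usual web-server defaults for global protein alignment).
#' @param end_gaps Penalize terminal gaps (default `TRUE`).
#' @return A `global_alignment` object: gapped strings `aligned_a`,
#'   `aligned_b`, `score`, `identity_pct`, `similarity_pct`, `length`,
#'   `n_identical`. `glance()` returns these as a one-row tibble.
#' @export
global_align <- function(seq_a, seq_b, matrix = NULL,
                         gap_open = 10, gap_extend = 0.5, end_gaps = TRUE) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  mat <- matrix %||% default_substitution_matrix()
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  unknown <- setdiff(unique(c(a, b)), rownames(mat))
  if (length(unknown) > 0)
    abort(paste0("symbol(s) missing from substitution matrix: ",
                 paste(unknown, collapse = ", ")))
  n <- length(a); m <- length(b)
  NEG <- -1e9
  sub <- mat[match(a, rownames(mat)), match(b, colnames(mat)), drop = FALSE]
  open1 <- gap_open + gap_extend

  # State matrices over matrix indices (I, J) = (i + 1, j + 1):
  #   M: a_i aligned to b_j;  X: gap in b (a_i consumed);  Y: gap in a.
  M <- base::matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  X[seq_len(n) + 1, 1] <- if (end_gaps) -(gap_open + gap_extend * seq_len(n)) else 0
  Y[1, seq_len(m) + 1] <- if (end_gaps) -(gap_open + gap_extend * seq_len(m)) else 0
  for (I in 2:(n + 1)) {
    prevM <- M[I - 1, ]; prevX <- X[I - 1, ]; prevY <- Y[I - 1, ]
    X[I, 2:(m + 1)] <- pmax(prevM[2:(m + 1)] - open1,
                            prevX[2:(m + 1)] - gap_extend,
                            prevY[2:(m + 1)] - open1)
    Mi <- M[I, ]; Yi <- Y[I, ]; Xi <- X[I, ]
    for (J in 2:(m + 1)) {
      Mi[J] <- sub[I - 1, J - 1] +
        max(prevM[J - 1], prevX[J - 1], prevY[J - 1])
      Yi[J] <- max(Mi[J - 1] - open1, Xi[J - 1] - open1,
                   Yi[J - 1] - gap_extend)
    }
    M[I, ] <- Mi; Y[I, ] <- Yi
  }

  tol <- 1e-9
  # Terminal cell and, for free end gaps, the implied tail of the alignment.
  tail_a <- character(0); tail_b <- character(0)
  if (end_gaps) {
    i <- n; j <- m
    ends <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
    best <- max(ends); state <- which.max(ends)
  } else {
    lastcol <- pmax(M[, m + 1], X[, m + 1], Y[, m + 1])
    lastrow <- pmax(M[n + 1, ], X[n + 1, ], Y[n + 1, ])
    if (max(lastcol) >= max(lastrow)) {
      I <- which.max(lastcol); i <- I - 1; j <- m
      if (i < n) { tail_a <- a[(i + 1):n]; tail_b <- rep("-", n - i) }
    } else {
      J <- which.max(lastrow); i <- n; j <- J - 1
      if (j < m) { tail_a <- rep("-", m - j); tail_b <- b[(j + 1):m] }
    }
    ends <- c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    best <- max(ends); state <- which.max(ends)
  }

  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    I <- i + 1; J <- j + 1
    if (state == 1) {
      ra <- c(a[i], ra); rb <- c(b[j], rb)
      target <- M[I, J] - sub[i, j]
      cand <- c(M[I - 1, J - 1], X[I - 1, J - 1], Y[I - 1, J - 1])
      state <- which(abs(cand - target) < tol)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ra <- c(a[i], ra); rb <- c("-", rb)
      cand <- c(M[I - 1, J] - open1, X[I - 1, J] - gap_extend,
                Y[I - 1, J] - open1)
      state <- which(abs(cand - X[I, J]) < tol)[1]
      if (is.na(state)) state <- 2L
      i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb)
      cand <- c(M[I, J - 1] - open1, X[I, J - 1] - open1,
                Y[I, J - 1] - gap_extend)
      state <- which(abs(cand - Y[I, J]) < tol)[1]
      if (is.na(state)) state <- 3L
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- 3L
    if (j == 0 && i > 0) state <- 2L
  }
  ca <- c(ra, tail_a); cb <- c(rb, tail_b)
  len <- length(ca)
  ident <- sum(ca == cb & ca != "-")
  both <- ca != "-" & cb != "-"
  simil <- sum(mat[cbind(match(ca[both], rownames(mat)),
                         match(cb[both], colnames(mat)))] > 0)
  structure(list(
    aligned_a = paste(ca, collapse = ""),
    aligned_b = paste(cb, collapse = ""),
    score = best,
    identity_pct = 100 * ident / len, similarity_pct = 100 * simil / len,
    length = len, n_identical = ident,
    gap_open = gap_open, gap_extend = gap_extend, end_gaps = end_gaps
  ), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf(
    "<global alignment: length %d, score %.1f, identity %.1f%%, similarity %.1f%%>\n",
    x$length, x$score, x$identity_pct, x$similarity_pct))
  block <- 60
  for (s in seq(1, x$length, by = block)) {
    e <- min(s + block - 1, x$length)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$aligned_b, s, e), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' @export
glance.global_alignment <- function(x, ...) {
  tibble(score = x$score, identity_pct = x$identity_pct,
         similarity_pct = x$similarity_pct, length = x$length,
         n_identical = x$n_identical)
}

#' Pair residues between two chains
#'
#' Establishes the residue correspondence needed before any inter-homolog
#' RMSD. `mode = "sequence"` globally aligns the one-letter sequences and
#' pairs residues in aligned non-gap columns; `mode = "seq_id"` pairs
#' residues with identical author numbers (and insertion codes).
#'
#' @param structure_a,structure_b `lobe_structure` objects.
#' @param chain_a,chain_b Chain ids (default: first chain of each).
#' @param mode `"sequence"` or `"seq_id"`.
#' @param ... Passed to [global_align()] in sequence mode.
#' @return Tibble with one row per residue pair: `resno_a`, `insert_a`,
#'   `resname_a`, `resno_b`, `insert_b`, `resname_b`.
#' @export
pair_residues <- function(structure_a, structure_b,
                          chain_a = NULL, chain_b = NULL,
                          mode = c("sequence", "seq_id"), ...) {
  mode <- match.arg(mode)
  chain_a <- chain_a %||% structure_chains(structure_a)[1]
  chain_b <- chain_b %||% structure_chains(structure_b)[1]
  ra <- filter(residue_table(structure_a), .data$chain == !!chain_a)
  rb <- filter(residue_table(structure_b), .data$chain == !!chain_b)
  if (nrow(ra) == 0 || nrow(rb) == 0) abort("both chains must be non-empty")
  if (mode == "sequence") {
    aln <- global_align(paste(three_to_one(ra$resname), collapse = ""),
                        paste(three_to_one(rb$resname), collapse = ""), ...)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
    keep <- ca != "-" & cb != "-"
    idx_a <- ia[keep]; idx_b <- ib[keep]
  } else {
    key_a <- paste(ra$resno, ra$insert)
    key_b <- paste(rb$resno, rb$insert)
    idx_a <- which(key_a %in% key_b)
    idx_b <- match(key_a[idx_a], key_b)
  }
  if (length(idx_a) == 0)
    abort("no residue pairs could be established between the chains")
  tibble(
    resno_a = ra$resno[idx_a], insert_a = ra$insert[idx_a],
    resname_a = ra$resname[idx_a],
    resno_b = rb$resno[idx_b], insert_b = rb$insert[idx_b],
    resname_b = rb$resname[idx_b]
  )
}
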