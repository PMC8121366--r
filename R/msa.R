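#' Multiple sequence alignment container
#'
#' An MSA is a tibble with columns `id` and `seq`, all sequences of equal
#' length over the alphabet of the 20 standard amino acids, the ambiguity
#' codes `X`/`B`/`Z` and the gap character `-`. Sequences are upper-cased
#' and `.` gaps are normalized to `-` on construction.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @return A `lobe_msa` tibble with attribute `width`.
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) > 0)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    abort("sequence identifiers must be unique")
  seqs <- gsub(".", "-", toupper(as.character(seqs)), fixed = TRUE)
  w <- nchar(seqs)
  if (length(unique(w)) != 1) {
    bad <- ids[which(w != w[1])[1]]
    abort(paste0("alignment is ragged: record '", bad, "' has width ",
                 nchar(seqs[ids == bad][1]), ", expected ", w[1]))
  }
  structure(tibble(id = ids, seq = seqs),
            width = w[1],
            class = c("lobe_msa", class(tibble())))
}

#' @export
print.lobe_msa <- function(x, ...) {
  cat(sprintf("<MSA: %d sequences x %d columns>\n", nrow(x), msa_width(x)))
  NextMethod()
}

#' Alignment width
#' @param x A `lobe_msa`.
#' @return Integer number of alignment columns.
#' @export
msa_width <- function(x) attr(x, "width") %||% unique(nchar(x$seq))

#' Read an aligned FASTA file
#'
#' All records must have identical aligned lengths; a ragged file is an
#' error naming the offending record. Characters are upper-cased and `.`
#' gaps normalized to `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A `lobe_msa`; see [msa()].
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0(
                    "could not parse FASTA ", path, ": ", conditionMessage(e))))
  if (length(set) == 0) abort(paste0("no sequences in ", path))
  ids <- sub("\\s.*$", "", names(set))
  msa(ids, as.character(set))
}

#' Write an MSA as aligned FASTA
#'
#' @param x A `lobe_msa`.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_msa <- function(x, path) {
  lines <- as.vector(rbind(paste0(">", x$id), x$seq))
  writeLines(lines, path)
  invisible(path)
}

# Character matrix (n_seq x width) of an MSA, rownames = ids.
msa_char_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seq, "", fixed = TRUE))
  rownames(m) <- x$id
  m
}
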