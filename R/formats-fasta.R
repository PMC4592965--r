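#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA is converted to DNA space (U to T),
#' the internal alphabet of the whole pipeline.  Identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1])
  }
  seqs <- chartr("U", "T", toupper(as.character(x)))
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param desc optional character vector of header descriptions.
#' @param rna write in RNA space (T converted to U), used for precursor
#'   outputs that represent RNA molecules.
#' @export
write_fasta <- function(seqs, path, desc = NULL, rna = FALSE) {
  if (length(seqs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  hdr <- paste0(">", names(seqs))
  if (!is.null(desc)) hdr <- paste(hdr, desc)
  body <- if (rna) chartr("T", "U", seqs) else unname(seqs)
  writeLines(as.vector(rbind(hdr, body)), path)
  invisible(path)
}

#' Write dot-bracket (DBN) records
#'
#' Each record is three lines: `>id`, the sequence, and its secondary
#' structure in dot-bracket notation.  The structure must have the same
#' length as the sequence and balanced parentheses.
#'
#' @param records data.frame with columns `id`, `sequence`, `structure`.
#' @param path output path.
#' @param rna write sequences in RNA space (default TRUE: DBN describes the
#'   folded RNA).
#' @export
write_dbn <- function(records, path, rna = TRUE) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  for (i in seq_len(nrow(records))) {
    s <- records$structure[i]
    if (nchar(s) != nchar(records$sequence[i])) {
      stop("DBN structure length differs from sequence for ",
           records$id[i])
    }
    ch <- strsplit(s, "")[[1]]
    if (!all(ch %in% c(".", "(", ")"))) {
      stop("invalid DBN characters for ", records$id[i])
    }
    depth <- cumsum((ch == "(") - (ch == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0) {
      stop("unbalanced DBN structure for ", records$id[i])
    }
  }
  body <- if (rna) chartr("T", "U", records$sequence) else records$sequence
  writeLines(as.vector(rbind(paste0(">", records$id), body,
                             records$structure)), path)
  invisible(path)
}
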