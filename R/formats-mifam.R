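#' Parse a miFam.dat-style family classification file
#'
#' The file is a sequence of stanzas, each opened by `AC` (family
#' accession) and `ID` (family name) lines, followed by one `MI` line per
#' member precursor (`MI   <accession>  <precursor name>`), and terminated
#' by `//`.  Each precursor may belong to at most one family; precursors
#' absent from every stanza are treated downstream as their own singleton
#' families.
#'
#' @param path path to the family file.
#' @return data.frame with columns `family_ac`, `family_id`, `mi_ac`,
#'   `precursor` (one row per member).
#' @export
parse_mifam <- function(path) {
  lines <- readLines(path)
  fam_ac <- fam_id <- NA_character_
  open <- FALSE
  rows <- list()
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    if (tag == "AC") {
      fam_ac <- trimws(substring(ln, 3))
      open <- TRUE
    } else if (tag == "ID") {
      fam_id <- trimws(substring(ln, 3))
      open <- TRUE
    } else if (tag == "MI") {
      fields <- strsplit(trimws(substring(ln, 3)), "\\s+")[[1]]
      if (length(fields) < 2) stop("malformed MI line: ", ln)
      rows[[length(rows) + 1]] <- data.frame(
        family_ac = fam_ac, family_id = fam_id,
        mi_ac = fields[1], precursor = fields[2],
        stringsAsFactors = FALSE)
      open <- TRUE
    } else if (trimws(ln) == "//") {
      fam_ac <- fam_id <- NA_character_
      open <- FALSE
    }
  }
  if (open) stop("malformed family file: last stanza lacks '//' terminator")
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(family_ac = character(0), family_id = character(0),
               mi_ac = character(0), precursor = character(0),
               stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$precursor)) {
    stop("precursor assigned to more than one family: ",
         out$precursor[duplicated(out$precursor)][1])
  }
  out
}

#' Family membership lookup for a hairpin id
#'
#' @param mifam data.frame from [parse_mifam()].
#' @param hairpin_id hairpin identifier (matched case-insensitively against
#'   the precursor name and accession columns).
#' @return family name, or `NA` when the precursor is in no family.
#' @export
family_of <- function(mifam, hairpin_id) {
  hit <- tolower(mifam$precursor) == tolower(hairpin_id) |
    tolower(mifam$mi_ac) == tolower(hairpin_id)
  if (any(hit)) mifam$family_id[which(hit)[1]] else NA_character_
}
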