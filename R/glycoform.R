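#' Parse intact glycopeptide (glycoform) identifiers
#'
#' An intact glycopeptide, or glycoform, is a peptide carrying a specific
#' glycan at a specific site. Its identifier is the underscore-delimited
#' composite
#' `GeneName_PeptideStartSite_PeptideSequence_GlycositeNumber_GlycositePosition_GlycanComposition`,
#' e.g. `HYOU1_869_NATLAEQAK_1_869_N2H9`: gene `HYOU1`, peptide starting at
#' protein position 869 with sequence `NATLAEQAK`, one glycosite on the
#' peptide, glycosylated at protein position 869, carrying glycan
#' composition `N2H9` (2 HexNAc, 9 Hex).
#'
#' Gene symbols may themselves contain underscores while peptide sequences
#' (amino-acid alphabet) and glycan compositions cannot, so tokens are
#' consumed from the right for the last four fields, then the start site,
#' and the gene is everything remaining on the left.
#'
#' Constraints checked: coordinates are positive integers; the glycosite
#' position lies within the peptide span
#' `[start, start + nchar(peptide) - 1]`; the glycosite count is >= 1; the
#' peptide is alphabetic; the glycan composition is a sequence of
#' letter+count tokens (any monosaccharide letter code, each count a
#' positive integer).
#'
#' @param ids Character vector of glycoform identifiers.
#' @return A data.frame with one row per identifier and columns `id`,
#'   `gene`, `peptide_start`, `peptide_sequence`, `glycosite_number`,
#'   `glycosite_position`, `glycan_composition`.
#' @examples
#' parse_glycoform("HYOU1_869_NATLAEQAK_1_869_N2H9")
#' @export
parse_glycoform <- function(ids) {
  ids <- as.character(ids)
  rows <- lapply(ids, .parse_one_glycoform)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.glycan_re <- "^([A-Za-z]+[1-9][0-9]*)+$"

.parse_one_glycoform <- function(id) {
  tok <- strsplit(id, "_", fixed = TRUE)[[1]]
  if (length(tok) < 6)
    stop("glycoform '", id, "': expected >=6 underscore-delimited tokens, got ",
         length(tok))
  n <- length(tok)
  glycan <- tok[n]
  pos_txt <- tok[n - 1]
  count_txt <- tok[n - 2]
  peptide <- tok[n - 3]
  start_txt <- tok[n - 4]
  gene <- paste(tok[seq_len(n - 5)], collapse = "_")
  as_int <- function(x, field) {
    if (!grepl("^[0-9]+$", x))
      stop("glycoform '", id, "': ", field, " '", x, "' is not a positive integer")
    as.integer(x)
  }
  start <- as_int(start_txt, "peptide start site")
  pos <- as_int(pos_txt, "glycosite position")
  count <- as_int(count_txt, "glycosite number")
  if (count < 1)
    stop("glycoform '", id, "': glycosite number must be >= 1")
  if (!grepl("^[A-Za-z]+$", peptide))
    stop("glycoform '", id, "': peptide sequence '", peptide,
         "' is not alphabetic")
  span_end <- start + nchar(peptide) - 1L
  if (pos < start || pos > span_end)
    stop("glycoform '", id, "': glycosite position ", pos,
         " outside peptide span [", start, ", ", span_end, "]")
  if (!grepl(.glycan_re, glycan))
    stop("glycoform '", id, "': malformed glycan composition '", glycan, "'")
  data.frame(id = id, gene = gene, peptide_start = start,
             peptide_sequence = peptide, glycosite_number = count,
             glycosite_position = pos, glycan_composition = glycan,
             stringsAsFactors = FALSE)
}

#' Format glycoform identifiers
#'
#' Inverse of [parse_glycoform()]: reassembles the underscore-delimited
#' identifier, so that `format_glycoform(parse_glycoform(x)) == x` for any
#' valid identifier.
#'
#' @param g data.frame with the parsed glycoform columns (as returned by
#'   [parse_glycoform()]).
#' @return Character vector of identifiers.
#' @export
format_glycoform <- function(g) {
  paste(g$gene, g$peptide_start, g$peptide_sequence, g$glycosite_number,
        g$glycosite_position, g$glycan_composition, sep = "_")
}

#' Test which identifiers parse as glycoforms
#'
#' @param ids Character vector.
#' @return Logical vector, `TRUE` where the identifier is a valid glycoform.
#' @export
is_glycoform <- function(ids) {
  vapply(as.character(ids), function(x)
    !inherits(try(.parse_one_glycoform(x), silent = TRUE), "try-error"),
    logical(1), USE.NAMES = FALSE)
}

#' Decompose a glycan composition string
#'
#' Splits a composition like `"N2H9F1"` into a named integer vector
#' (`c(N = 2, H = 9, F = 1)`). No fixed monosaccharide alphabet is
#' enforced: any letter code followed by a positive count is accepted.
#'
#' @param composition Single composition string.
#' @return Named integer vector of monosaccharide counts.
#' @export
glycan_composition_counts <- function(composition) {
  if (!grepl(.glycan_re, composition))
    stop("malformed glycan composition '", composition, "'")
  m <- gregexpr("[A-Za-z]+|[0-9]+", composition)[[1]]
  tokens <- regmatches(composition, list(m))[[1]]
  counts <- as.integer(tokens[c(FALSE, TRUE)])
  stats::setNames(counts, tokens[c(TRUE, FALSE)])
}
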