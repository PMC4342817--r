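# Alignment container, FASTA/Stockholm I/O and gap-column filtering.

#' Construct an Msa from aligned sequences
#'
#' Rows must be equal-width aligned amino-acid strings. '.' gap
#' characters are normalised to '-' and residues upper-cased on
#' construction.
#'
#' @param x Named character vector or \code{AAStringSet} of aligned rows.
#' @param sourceColumns Optional integer vector of original column
#'   indices (defaults to 1..width).
#' @return An \linkS4class{Msa}.
#' @examples
#' Msa(c(s1 = "AC-E", s2 = "ACDE"))
#' @export
Msa <- function(x, sourceColumns = NULL) {
  if (methods::is(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L)
    stop("alignment rows must be a non-empty character vector")
  if (is.null(names(x)))
    names(x) <- paste0("seq", seq_along(x))
  x <- toupper(gsub(".", "-", x, fixed = TRUE))
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("aligned rows differ in width")
  if (is.null(sourceColumns)) sourceColumns <- seq_len(w)
  methods::new("Msa", rows = Biostrings::AAStringSet(x),
               sourceColumns = as.integer(sourceColumns))
}

#' Read an aligned FASTA file into an Msa
#' @param path FASTA file with equal-width aligned rows.
#' @return An \linkS4class{Msa}.
#' @export
readAlignedFasta <- function(path) {
  Msa(Biostrings::readAAStringSet(path))
}

#' Write an Msa to aligned FASTA
#' @param msa An \linkS4class{Msa}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignedFasta <- function(msa, path) {
  Biostrings::writeXStringSet(msa@rows, path)
  invisible(path)
}

#' Read a Stockholm-format alignment into an Msa
#'
#' Minimal single-alignment Stockholm reader: sequence lines are
#' concatenated across interleaved blocks; markup (#=) and blank lines
#' are ignored.
#'
#' @param path Stockholm file.
#' @return An \linkS4class{Msa}.
#' @export
readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  seqs <- list()
  for (ln in lines[-1]) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || grepl("^\\s*$", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    nm <- parts[1]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]],
                         parts[2])
  }
  if (!length(seqs)) stop("Stockholm file contains no sequences: ", path)
  Msa(unlist(seqs))
}

#' Remove high-gap alignment columns
#'
#' Drops every column whose gap fraction is strictly greater than
#' \code{maxGapFraction}; columns exactly at the threshold are retained.
#' Column provenance is tracked in \code{sourceColumns}, so the operation
#' is idempotent.
#'
#' @param msa An \linkS4class{Msa}.
#' @param maxGapFraction Retention threshold (default 0.5).
#' @return A filtered \linkS4class{Msa}.
#' @examples
#' m <- Msa(c(a = "A-CD", b = "A-CD", c = "AECD", d = "A-C-"))
#' msaWidth(filterGapColumns(m))
#' @export
filterGapColumns <- function(msa, maxGapFraction = 0.5) {
  stopifnot(methods::is(msa, "Msa"))
  if (length(msa) == 0L) stop("empty alignment")
  gf <- gapFractions(msa)
  keep <- which(gf <= maxGapFraction)
  if (!length(keep)) stop("no column survives the gap filter")
  m <- .msaMatrix(msa)
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- names(msa@rows)
  Msa(rows, sourceColumns = msa@sourceColumns[keep])
}
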