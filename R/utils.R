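# Shared constants and numeric helpers.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Residues are indexed 1..20 in the order of \code{AA_ALPHABET20}.
#' @format Character vector of the 20 standard residues.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

# Ambiguity / nonstandard codes scored at background probability unless
# strict mode rejects them. 'U' (selenocysteine) deliberately maps to
# background, not to C.
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*")

#' Uniform background amino-acid distribution
#'
#' The default null model: each of the 20 residues at probability 1/20.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniformBackground <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
}

# Map residue characters to 1..20 (0 = ambiguous/background, -1 = illegal).
.aaIndex <- function(chars) {
  idx <- match(chars, AA_ALPHABET20)
  idx[is.na(idx) & chars %in% AA_AMBIGUOUS] <- 0L
  idx[is.na(idx)] <- -1L
  idx
}

.checkResidues <- function(seq, strict = FALSE, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) stop("empty ", what)
  idx <- .aaIndex(chars)
  if (any(idx < 0L))
    stop("illegal residue character(s) in ", what, ": ",
         paste(unique(chars[idx < 0L]), collapse = ", "))
  if (strict && any(idx == 0L))
    stop("ambiguous residue character(s) rejected in strict mode: ",
         paste(unique(chars[idx == 0L]), collapse = ", "))
  idx
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Draw one index from probability vector p (length-stable, no sample() quirks).
.rcat <- function(p) {
  u <- stats::runif(1)
  cs <- cumsum(p)
  findInterval(u, cs, left.open = TRUE) + 1L
}

.isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

.isFraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
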