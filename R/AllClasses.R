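#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importClassesFrom Biostrings AAStringSet
NULL

#' Gumbel (extreme-value) calibration parameters for a profile HMM
#'
#' Bit scores of background-composition random sequences against a profile
#' HMM are well described by a Gumbel distribution. \code{mu} is the
#' location (bits) and \code{lambda} the inverse scale (1/bits) of the
#' fitted distribution; E-values follow as
#' \eqn{E = N (1 - \exp(-\exp(-\lambda (s - \mu))))} for database size N.
#'
#' @slot mu Gumbel location, in bits.
#' @slot lambda Gumbel inverse scale, per bit; strictly positive.
#' @slot nCalibration Number of random sequences used in the fit (>= 100).
#' @slot seed Integer seed the calibration draw was made under.
#' @exportClass GumbelParams
setClass("GumbelParams",
  representation(mu = "numeric", lambda = "numeric",
                 nCalibration = "integer", seed = "integer"),
  prototype(mu = NA_real_, lambda = NA_real_,
            nCalibration = NA_integer_, seed = NA_integer_))

setValidity("GumbelParams", function(object) {
  msg <- character()
  if (length(object@mu) != 1L || !is.finite(object@mu))
    msg <- c(msg, "mu must be a single finite number")
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive number")
  if (length(object@nCalibration) != 1L || is.na(object@nCalibration) ||
      object@nCalibration < 100L)
    msg <- c(msg, "nCalibration must be >= 100")
  if (length(msg)) msg else TRUE
})

#' Profile hidden Markov model over the 20-letter amino-acid alphabet
#'
#' A linear match/insert/delete profile with local-alignment semantics:
#' flanking states N (before entry) and C (after exit) emit background
#' residues with a self-loop, entry is distributed over match states
#' (\code{transitions$entry}) and every match state carries an exit
#' probability to E. Scores are log-odds in bits against a background
#' null model that emits each residue independently from
#' \code{background}.
#'
#' @slot name Model identifier, usually a subfamily name.
#' @slot matchEmissions L x 20 matrix; row k is the emission distribution
#'   of match state k (columns in \code{AA_ALPHABET20} order).
#' @slot insertEmissions L x 20 matrix; row k is the emission distribution
#'   of the insert state between match k and k+1 (row L is unused padding
#'   but kept normalised).
#' @slot transitions List with elements \code{entry} (length L, B->Mk),
#'   \code{fromM} (L x 4, columns MM, MI, MD, ME), \code{fromI} (L x 2,
#'   columns IM, II), \code{fromD} (L x 3, columns DM, DD, DE),
#'   \code{loopN}, \code{loopC} (flank self-loop probabilities).
#' @slot background Length-20 null emission distribution.
#' @slot calibration A \linkS4class{GumbelParams} object, or NULL before
#'   calibration.
#' @slot metadata Free-form list (provenance, weighting scheme, ...).
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(name = "character", matchEmissions = "matrix",
                 insertEmissions = "matrix", transitions = "list",
                 background = "numeric", calibration = "ANY",
                 metadata = "list"),
  prototype(calibration = NULL, metadata = list()))

.checkProb <- function(x, what, tol = 1e-9) {
  msg <- character()
  if (any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol))
    msg <- c(msg, paste0(what, " has entries outside [0, 1]"))
  msg
}

.checkRowSums <- function(m, what, tol = 1e-9) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad))
    paste0(what, " rows not summing to 1: ",
           paste(which(bad), collapse = ", "))
  else character()
}

setValidity("ProfileHMM", function(object) {
  msg <- character()
  L <- nrow(object@matchEmissions)
  if (is.null(L) || L < 1L) return("at least one match state is required")
  if (ncol(object@matchEmissions) != 20L ||
      ncol(object@insertEmissions) != 20L)
    return("emission matrices must have 20 columns")
  if (nrow(object@insertEmissions) != L)
    return("insertEmissions must have one row per match state")
  tr <- object@transitions
  need <- c("entry", "fromM", "fromI", "fromD", "loopN", "loopC")
  if (!all(need %in% names(tr)))
    return(paste("transitions must contain:", paste(need, collapse = ", ")))
  msg <- c(msg,
    .checkProb(object@matchEmissions, "matchEmissions"),
    .checkProb(object@insertEmissions, "insertEmissions"),
    .checkRowSums(object@matchEmissions, "matchEmissions"),
    .checkRowSums(object@insertEmissions, "insertEmissions"),
    .checkProb(tr$entry, "entry"), .checkProb(tr$fromM, "fromM"),
    .checkProb(tr$fromI, "fromI"), .checkProb(tr$fromD, "fromD"))
  if (abs(sum(tr$entry) - 1) > 1e-9)
    msg <- c(msg, "entry does not sum to 1")
  if (length(tr$entry) != L) msg <- c(msg, "entry must have length L")
  if (!identical(dim(tr$fromM), c(L, 4L)) &&
      !identical(dim(tr$fromM), as.integer(c(L, 4))))
    msg <- c(msg, "fromM must be L x 4")
  else msg <- c(msg, .checkRowSums(tr$fromM, "fromM"))
  if (nrow(tr$fromI) != L || ncol(tr$fromI) != 2L)
    msg <- c(msg, "fromI must be L x 2")
  else msg <- c(msg, .checkRowSums(tr$fromI, "fromI"))
  if (nrow(tr$fromD) != L || ncol(tr$fromD) != 3L)
    msg <- c(msg, "fromD must be L x 3")
  else msg <- c(msg, .checkRowSums(tr$fromD, "fromD"))
  if (tr$fromM[L, 1] != 0 || tr$fromM[L, 3] != 0)
    msg <- c(msg, "final match state cannot transition to M or D")
  if (tr$fromD[L, 1] != 0 || tr$fromD[L, 2] != 0)
    msg <- c(msg, "final delete state must exit to E")
  if (!.isFraction(tr$loopN) || !.isFraction(tr$loopC))
    msg <- c(msg, "loopN/loopC must be probabilities")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be a length-20 distribution")
  if (!is.null(object@calibration) &&
      !methods::is(object@calibration, "GumbelParams"))
    msg <- c(msg, "calibration must be NULL or a GumbelParams")
  if (length(msg)) msg else TRUE
})

#' Multiple sequence alignment with column provenance
#'
#' Aligned amino-acid rows of equal width with '-' gap characters. When an
#' alignment is derived from another by column filtering,
#' \code{sourceColumns} records the original (1-based) indices of the
#' retained columns.
#'
#' @slot rows An \code{AAStringSet} of equal-width aligned rows.
#' @slot sourceColumns Strictly increasing integer vector, one entry per
#'   column, giving each column's index in the original alignment.
#' @exportClass Msa
setClass("Msa",
  representation(rows = "AAStringSet", sourceColumns = "integer"))

setValidity("Msa", function(object) {
  msg <- character()
  w <- unique(Biostrings::width(object@rows))
  if (length(object@rows) == 0L) msg <- c(msg, "alignment has no rows")
  if (length(w) > 1L) msg <- c(msg, "rows differ in width")
  if (length(w) == 1L && length(object@sourceColumns) != w)
    msg <- c(msg, "sourceColumns must have one entry per column")
  if (length(object@sourceColumns) > 1L &&
      any(diff(object@sourceColumns) <= 0L))
    msg <- c(msg, "sourceColumns must be strictly increasing")
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
    msg <- c(msg, "rows must carry unique names")
  if (length(msg)) msg else TRUE
})

#' Registry of trGTPase subfamilies, evolutionary timeline and minimal
#' repertoires
#'
#' Holds the 57-subfamily classification schema: one record per subfamily
#' (family/midfamily membership, domain of life, subcellular compartment,
#' synonyms, origin node on the timeline, domain architecture, and for
#' organellar subfamilies the bacterial equivalent used by dual notation),
#' together with ancestral trGTPase complements at the major timeline
#' nodes and the minimal per-domain subfamily repertoires.
#'
#' @slot records A \code{DataFrame} with one row per subfamily record.
#' @slot timeline Named list: timeline node id -> character vector of
#'   ancestral lineage names present at that node.
#' @slot minimal Named list: domain of life -> character vector of
#'   subfamily names forming the minimal repertoire.
#' @slot metadata Free-form list (format version, reconciliation notes,
#'   genome counts).
#' @exportClass TrgRegistry
setClass("TrgRegistry",
  representation(records = "DataFrame", timeline = "list",
                 minimal = "list", metadata = "list"))

REGISTRY_DOMAINS <- c("bacteria", "archaea", "eukaryote")
REGISTRY_COMPARTMENTS <- c("cytoplasmic", "mitochondrial", "plastid",
                           "unknown-organellar")
REGISTRY_FAMILIES <- c("EF1S", "EF2", "IF2")
REGISTRY_MIDFAMILIES <- c("EF1", "SelB")
REGISTRY_NODES <- c("LUCA", "bLCA", "a+eLCA", "aLCA", "eLCA",
                    "post-eLCA-lineage", "post-bLCA-lineage")
ARCHITECTURE_TOKENS <- c("G", "G'", "G''", "II", "III", "IV", "C",
                         "LepA_C", "IF2_N", "IF-2", "RF3-CTD", "NYN",
                         "N-ext")

setValidity("TrgRegistry", function(object) {
  msg <- .validateRegistryRecords(object@records)
  msg <- c(msg, .validateRegistryExtras(object))
  if (length(msg)) msg else TRUE
})
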