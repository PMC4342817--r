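# Generics and simple accessors.

#' Number of match states of a profile HMM
#' @param x A \linkS4class{ProfileHMM}.
#' @return Integer.
#' @export
setGeneric("modelLength", function(x) standardGeneric("modelLength"))

#' @rdname modelLength
#' @export
setMethod("modelLength", "ProfileHMM",
          function(x) nrow(x@matchEmissions))

#' Calibration parameters of a profile HMM
#' @param x A \linkS4class{ProfileHMM}.
#' @return A \linkS4class{GumbelParams} or NULL.
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname calibration
#' @export
setMethod("calibration", "ProfileHMM", function(x) x@calibration)

#' Is a profile HMM calibrated?
#' @param x A \linkS4class{ProfileHMM}.
#' @return Logical.
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' @rdname isCalibrated
#' @export
setMethod("isCalibrated", "ProfileHMM",
          function(x) !is.null(x@calibration))

#' Model name accessor
#' @param x A \linkS4class{ProfileHMM}.
#' @return Character scalar.
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname modelName
#' @export
setMethod("modelName", "ProfileHMM", function(x) x@name)

#' Consensus sequence of a profile HMM
#'
#' The residue of maximal emission probability at each match state
#' (ties broken by alphabet order).
#' @param x A \linkS4class{ProfileHMM}.
#' @return Character scalar of length \code{modelLength(x)}.
#' @export
setGeneric("consensusSequence",
           function(x) standardGeneric("consensusSequence"))

#' @rdname consensusSequence
#' @export
setMethod("consensusSequence", "ProfileHMM", function(x) {
  paste(AA_ALPHABET20[apply(x@matchEmissions, 1, which.max)],
        collapse = "")
})

#' Alignment rows of an Msa
#' @param x An \linkS4class{Msa}.
#' @return An \code{AAStringSet}.
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname msaRows
#' @export
setMethod("msaRows", "Msa", function(x) x@rows)

#' Per-column gap fractions of an alignment
#' @param x An \linkS4class{Msa}.
#' @return Numeric vector in [0, 1], one entry per column.
#' @export
setGeneric("gapFractions", function(x) standardGeneric("gapFractions"))

#' @rdname gapFractions
#' @export
setMethod("gapFractions", "Msa", function(x) {
  m <- .msaMatrix(x)
  colMeans(m == "-")
})

#' Original column indices of a (possibly filtered) alignment
#' @param x An \linkS4class{Msa}.
#' @return Integer vector.
#' @export
setGeneric("sourceColumns", function(x) standardGeneric("sourceColumns"))

#' @rdname sourceColumns
#' @export
setMethod("sourceColumns", "Msa", function(x) x@sourceColumns)

#' @describeIn Msa number of rows
#' @param x An \linkS4class{Msa}.
#' @export
setMethod("length", "Msa", function(x) length(x@rows))

#' Alignment width (number of columns)
#' @param x An \linkS4class{Msa}.
#' @return Integer.
#' @export
setGeneric("msaWidth", function(x) standardGeneric("msaWidth"))

#' @rdname msaWidth
#' @export
setMethod("msaWidth", "Msa", function(x) {
  if (length(x@rows) == 0L) 0L else Biostrings::width(x@rows)[1]
})

#' Number of subfamily records in a registry
#' @param x A \linkS4class{TrgRegistry}.
#' @return Integer.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname nRecords
#' @export
setMethod("nRecords", "TrgRegistry", function(x) nrow(x@records))

#' Canonical subfamily names in a registry
#' @param x A \linkS4class{TrgRegistry}.
#' @return Character vector.
#' @export
setGeneric("subfamilyNames", function(x) standardGeneric("subfamilyNames"))

#' @rdname subfamilyNames
#' @export
setMethod("subfamilyNames", "TrgRegistry", function(x) x@records$name)

#' Subfamily record table of a registry
#' @param x A \linkS4class{TrgRegistry}.
#' @return A \code{DataFrame}, one row per record.
#' @export
setGeneric("registryRecords",
           function(x) standardGeneric("registryRecords"))

#' @rdname registryRecords
#' @export
setMethod("registryRecords", "TrgRegistry", function(x) x@records)

setMethod("show", "GumbelParams", function(object) {
  cat("GumbelParams: mu =", format(object@mu, digits = 4),
      "bits, lambda =", format(object@lambda, digits = 4),
      "/bit (n =", object@nCalibration, ", seed =", object@seed, ")\n")
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM '", object@name, "': ", modelLength(object),
      " match states, ",
      if (isCalibrated(object)) "calibrated" else "uncalibrated",
      "\n", sep = "")
  cat("  consensus: ",
      substr(consensusSequence(object), 1, 60),
      if (modelLength(object) > 60) "..." else "", "\n", sep = "")
})

setMethod("show", "Msa", function(object) {
  cat("Msa: ", length(object@rows), " rows x ", msaWidth(object),
      " columns\n", sep = "")
})

setMethod("show", "TrgRegistry", function(object) {
  cat("TrgRegistry: ", nrow(object@records), " subfamily records, ",
      length(object@timeline), " timeline nodes, ",
      length(object@minimal), " minimal compositions\n", sep = "")
})
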