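# Candidate gathering and sequence hygiene: homolog gathering, G-domain
# checks, analysis-region extraction, deduplication, fusion flagging and
# active-site surveys.

#' Read a proteome FASTA file
#' @param path Protein FASTA.
#' @return An \code{AAStringSet}; names are sequence ids.
#' @export
readProteome <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence ids in proteome: ", path)
  x
}

#' Read a taxon metadata sidecar (TSV)
#'
#' Expected columns: taxon_id, name, domain_of_life, lineage
#' (semicolon-separated ranks).
#'
#' @param path TSV file.
#' @return data.frame with one row per taxon; lineage as a list column.
#' @export
readTaxonInfo <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "name", "domain_of_life", "lineage")
  if (!all(need %in% colnames(df)))
    stop("taxon sidecar must have columns: ", paste(need, collapse = ", "))
  bad <- !df$domain_of_life %in% REGISTRY_DOMAINS
  if (any(bad))
    stop("unknown domain_of_life for taxon/taxa: ",
         paste(df$taxon_id[bad], collapse = ", "))
  df$lineage <- strsplit(df$lineage, ";")
  if (any(lengths(df$lineage) == 0L)) stop("empty lineage in sidecar")
  df
}

#' Gather candidate homologs from a proteome
#'
#' Scores every sequence against every (calibrated) query model with the
#' forward algorithm and keeps sequences whose best E-value is at or
#' below \code{eMax}. Lowering \code{eMax} never adds members.
#'
#' @param proteome \code{AAStringSet}.
#' @param queryModels List of calibrated \linkS4class{ProfileHMM}s (a
#'   single model is accepted).
#' @param eMax Gathering E-value threshold (default 1e-3).
#' @param dbSize Database size used for E-values; defaults to the number
#'   of sequences scanned.
#' @return The gathered subset of \code{proteome}, with a
#'   \code{bestEvalue} attribute (named numeric, one entry per gathered
#'   sequence).
#' @export
gatherCandidates <- function(proteome, queryModels, eMax = 1e-3,
                             dbSize = length(proteome)) {
  if (methods::is(queryModels, "ProfileHMM"))
    queryModels <- list(queryModels)
  if (!length(queryModels)) stop("no query models supplied")
  if (!length(proteome)) stop("empty proteome")
  ok <- vapply(queryModels, isCalibrated, logical(1))
  if (any(!ok))
    stop("uncalibrated query model(s): ",
         paste(vapply(queryModels[!ok], modelName, character(1)),
               collapse = ", "))
  best <- rep(Inf, length(proteome))
  seqs <- as.character(proteome)
  for (mod in queryModels) {
    ev <- vapply(seqs, function(s)
      evalueOf(forwardScore(mod, s), mod, dbSize), numeric(1),
      USE.NAMES = FALSE)
    best <- pmin(best, ev)
  }
  keep <- which(best <= eMax)
  out <- proteome[keep]
  attr(out, "bestEvalue") <- stats::setNames(best[keep],
                                             names(proteome)[keep])
  out
}

#' Test whether a sequence retains the G-domain model
#'
#' @param seq Amino-acid string.
#' @param gModel Calibrated G-domain \linkS4class{ProfileHMM}.
#' @param eCut Retention E-value cutoff (default 1e-3).
#' @param dbSize Database size for the E-value (default 1: the E-value
#'   equals the per-sequence P-value).
#' @return List with \code{hasGDomain} (logical), \code{evalue}, and
#'   \code{envelope} (0-based half-open match envelope, NA when no hit).
#' @export
checkGDomain <- function(seq, gModel, eCut = 1e-3, dbSize = 1) {
  stopifnot(methods::is(gModel, "ProfileHMM"))
  if (!isCalibrated(gModel)) stop("G-domain model is not calibrated")
  if (!nzchar(seq))
    return(list(hasGDomain = FALSE, evalue = Inf,
                envelope = c(NA_integer_, NA_integer_)))
  ev <- evalueOf(forwardScore(gModel, seq), gModel, dbSize)
  if (is.finite(ev) && ev <= eCut) {
    vit <- viterbiScore(gModel, seq)
    list(hasGDomain = TRUE, evalue = ev, envelope = vit$envelope)
  } else {
    list(hasGDomain = FALSE, evalue = ev,
         envelope = c(NA_integer_, NA_integer_))
  }
}

#' Extract the G-domain + domain II analysis region
#'
#' The alignable analysis region starts at the G-domain's N-terminal
#' boundary. When a domain II envelope is predicted it ends at domain
#' II's C-terminal boundary; otherwise it extends 100 residues (the
#' average domain II length plus margin) past the G-domain's C-terminal
#' boundary, truncated at the sequence end.
#'
#' @param seq Amino-acid string (or its length).
#' @param gEnvelope 0-based half-open G-domain interval.
#' @param d2Envelope Optional 0-based half-open domain II interval.
#' @param extension Extension in residues when no domain II envelope is
#'   available (default 100).
#' @return 0-based half-open interval \code{c(start, end)}.
#' @examples
#' extractRegion(strrep("A", 400), c(10, 190))
#' @export
extractRegion <- function(seq, gEnvelope, d2Envelope = NULL,
                          extension = 100) {
  n <- if (is.character(seq)) nchar(seq) else as.integer(seq)
  g <- as.integer(gEnvelope)
  if (length(g) != 2L || g[1] < 0L || g[2] > n || g[1] >= g[2])
    stop("G-domain envelope outside sequence bounds")
  if (!is.null(d2Envelope) && !any(is.na(d2Envelope))) {
    d2 <- as.integer(d2Envelope)
    if (d2[2] > n || d2[1] < 0L || d2[1] >= d2[2])
      stop("domain II envelope outside sequence bounds")
    c(g[1], d2[2])
  } else {
    c(g[1], min(g[2] + as.integer(extension), n))
  }
}

#' Remove exact-duplicate sequences
#'
#' Byte-identical sequences are collapsed to the first occurrence in
#' input order; near-identical sequences are retained.
#'
#' @param seqs \code{AAStringSet} (or named character vector).
#' @return Deduplicated \code{AAStringSet}.
#' @export
dedupSequences <- function(seqs) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  seqs[!duplicated(as.character(seqs))]
}

#' Flag probable fusion proteins
#'
#' An automated surrogate for manual fusion curation: a sequence is
#' flagged when its analysis region covers less than
#' \code{coverageFraction} of the total length while the total length
#' exceeds \code{lengthMultiple} times the model consensus length —
#' i.e. there is a large scored core inside a much larger protein.
#'
#' @param seq Amino-acid string (or its length).
#' @param analysisRegion 0-based half-open interval.
#' @param consensusLength Match-state count of the classifying model.
#' @param coverageFraction Maximum covered fraction before flagging
#'   (default 0.5).
#' @param lengthMultiple Minimum length multiple before flagging
#'   (default 1.5).
#' @return Logical.
#' @export
flagFusion <- function(seq, analysisRegion, consensusLength,
                       coverageFraction = 0.5, lengthMultiple = 1.5) {
  n <- if (is.character(seq)) nchar(seq) else as.integer(seq)
  cov <- (analysisRegion[2] - analysisRegion[1]) / n
  (cov < coverageFraction) && (n > lengthMultiple * consensusLength)
}

#' Survey residues at annotated alignment sites
#'
#' Reports, for every sequence, the residue (or gap) at each named
#' alignment column — e.g. the P-loop Asp and Switch I Gly positions that
#' coordinate the monovalent cation in most trGTPases — together with
#' per-site residue counts.
#'
#' @param msa An \linkS4class{Msa}.
#' @param siteMap Named integer vector: site name -> alignment column
#'   (1-based, in the current alignment).
#' @return List with \code{perSequence} (data.frame, rows = sequences,
#'   columns = sites) and \code{summary} (list of per-site residue count
#'   tables).
#' @export
siteSurvey <- function(msa, siteMap) {
  stopifnot(methods::is(msa, "Msa"))
  if (!length(siteMap))
    return(list(perSequence = data.frame(row.names =
                                           names(msaRows(msa))),
                summary = list()))
  if (is.null(names(siteMap)) || any(!nzchar(names(siteMap))))
    stop("siteMap must be a named vector")
  w <- msaWidth(msa)
  if (any(siteMap < 1L | siteMap > w))
    stop("site column index out of range (alignment width ", w, ")")
  m <- .msaMatrix(msa)
  res <- as.data.frame(m[, siteMap, drop = FALSE],
                       stringsAsFactors = FALSE)
  colnames(res) <- names(siteMap)
  rownames(res) <- names(msaRows(msa))
  list(perSequence = res,
       summary = lapply(res, function(col) table(col)))
}

#' Write a region-annotation report (TSV, 1-based inclusive coordinates)
#'
#' @param annotations data.frame with columns sequence_id, g_start,
#'   g_end, d2_start, d2_end, region_start, region_end in 0-based
#'   half-open coordinates.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
writeRegionReport <- function(annotations, path) {
  out <- annotations
  for (cs in c("g_start", "d2_start", "region_start"))
    if (cs %in% colnames(out)) out[[cs]] <- out[[cs]] + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
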