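# Competitive subfamily classification: proteome scanning, E-value
# assignment with taxonomy-aware dual notation, iterative model
# refinement, and reporting.

#' Pipeline configuration
#'
#' Central thresholds of the classification pipeline. The defaults are
#' the operating points of the published procedure: candidate gathering
#' at E <= 1e-3 and superfamily membership at E <= 1e-20.
#'
#' @param gatherEMax Gathering E-value limit (default 1e-3).
#' @param memberEMax Superfamily-membership E-value cutoff (default
#'   1e-20); must be below \code{gatherEMax}.
#' @param gapFraction Gap-column filter threshold (default 0.5).
#' @param regionExtension Analysis-region extension past the G domain
#'   when no domain II envelope is predicted, in residues (default 100).
#' @param calibrationN Random sequences per model calibration (default
#'   200).
#' @param maxRounds Maximum scan/rebuild rounds (default 10).
#' @param seed Master integer seed; per-model calibration seeds are
#'   derived from it.
#' @param minPurity,minSize Clade-extraction thresholds.
#' @param dbSizePolicy How the E-value database size is chosen;
#'   "scanned" (the number of sequences in the current scan) is the only
#'   policy implemented.
#' @return A validated configuration list of class "TrgConfig".
#' @export
pipelineConfig <- function(gatherEMax = 1e-3, memberEMax = 1e-20,
                           gapFraction = 0.5, regionExtension = 100,
                           calibrationN = 200L, maxRounds = 10L,
                           seed = 1L, minPurity = 0.9, minSize = 3L,
                           dbSizePolicy = "scanned") {
  if (!(memberEMax > 0 && memberEMax < gatherEMax))
    stop("must have 0 < memberEMax < gatherEMax")
  if (!.isCount(maxRounds, 1L)) stop("maxRounds must be >= 1")
  if (!.isCount(calibrationN, 100L))
    stop("calibrationN must be >= 100")
  if (!.isFraction(gapFraction)) stop("gapFraction must be in [0, 1]")
  if (!identical(dbSizePolicy, "scanned"))
    stop("unknown dbSizePolicy: ", dbSizePolicy)
  structure(list(gatherEMax = gatherEMax, memberEMax = memberEMax,
                 gapFraction = gapFraction,
                 regionExtension = regionExtension,
                 calibrationN = as.integer(calibrationN),
                 maxRounds = as.integer(maxRounds),
                 seed = as.integer(seed), minPurity = minPurity,
                 minSize = as.integer(minSize),
                 dbSizePolicy = dbSizePolicy),
            class = "TrgConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are \code{pipelineConfig} arguments.
#' @return A "TrgConfig" list.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

.checkModels <- function(models) {
  if (!length(models)) stop("empty model collection")
  if (is.null(names(models)))
    names(models) <- vapply(models, modelName, character(1))
  ok <- vapply(models, isCalibrated, logical(1))
  if (any(!ok))
    stop("uncalibrated model(s): ",
         paste(names(models)[!ok], collapse = ", "))
  models
}

#' Scan proteomes against a model collection
#'
#' Scores every sequence of every proteome against every calibrated
#' model (forward algorithm) and returns the hits with E-value at or
#' below the gathering threshold, one row per (sequence, model) pair.
#' The E-value database size is the total number of sequences scanned.
#'
#' @param proteomes Named list (taxon_id -> \code{AAStringSet}); a
#'   single \code{AAStringSet} is treated as one unnamed taxon.
#' @param models Named list of calibrated \linkS4class{ProfileHMM}s.
#' @param config A "TrgConfig".
#' @return data.frame with columns taxon_id, sequence_id, model_name,
#'   bits, evalue, env_start, env_end (0-based half-open envelopes).
#' @export
scanProteomes <- function(proteomes, models, config = pipelineConfig()) {
  if (methods::is(proteomes, "AAStringSet"))
    proteomes <- list(proteome = proteomes)
  models <- .checkModels(models)
  dbSize <- sum(vapply(proteomes, length, integer(1)))
  out <- list()
  for (tx in names(proteomes)) {
    seqs <- as.character(proteomes[[tx]])
    for (mn in names(models)) {
      mod <- models[[mn]]
      for (sid in names(seqs)) {
        bits <- forwardScore(mod, seqs[[sid]])
        ev <- evalueOf(bits, mod, dbSize)
        if (is.finite(ev) && ev <= config$gatherEMax) {
          vit <- viterbiScore(mod, seqs[[sid]])
          out[[length(out) + 1L]] <- data.frame(
            taxon_id = tx, sequence_id = sid, model_name = mn,
            bits = bits, evalue = ev,
            env_start = vit$envelope[1], env_end = vit$envelope[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(taxon_id = character(), sequence_id = character(),
                      model_name = character(), bits = numeric(),
                      evalue = numeric(), env_start = integer(),
                      env_end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assign one sequence to a subfamily from its hits
#'
#' Classification is first by E-value: the model of minimum E wins when
#' that E is at or below the superfamily cutoff; a best E above the
#' cutoff but within the gathering limit yields status
#' "superfamily-nonmember"; no qualifying hit yields
#' "candidate-unassigned". Ties on E are broken by higher bit score,
#' then lexicographic model name, and flagged "ambiguous-tie".
#' Taxonomy correction never reassigns: when a bacterial-taxon sequence
#' is won by an organellar subfamily whose registry bacterial
#' equivalent also hits, the result carries the equivalent as a dual
#' label, rendered "organellar(bacterial)".
#'
#' @param hits data.frame of hits for a single sequence (rows of
#'   \code{scanProteomes} output; may have zero rows).
#' @param taxon One-row data.frame or list with at least
#'   \code{domain_of_life} (and \code{taxon_id}).
#' @param registry A \linkS4class{TrgRegistry}.
#' @param config A "TrgConfig".
#' @return One-row data.frame: sequence_id, taxon_id, status,
#'   primary_label, bacterial_equivalent_label, report_label,
#'   best_evalue, best_bits, runner_up_label, runner_up_evalue, flags.
#' @export
assignSequence <- function(hits, taxon, registry,
                           config = pipelineConfig()) {
  if (nrow(hits) > 0 && length(unique(hits$sequence_id)) != 1L)
    stop("hit set references multiple sequences")
  sid <- if (nrow(hits)) hits$sequence_id[1] else NA_character_
  tid <- if (!is.null(taxon$taxon_id)) taxon$taxon_id
         else if (nrow(hits)) hits$taxon_id[1] else NA_character_
  empty <- data.frame(
    sequence_id = sid, taxon_id = tid, status = "candidate-unassigned",
    primary_label = NA_character_,
    bacterial_equivalent_label = NA_character_,
    report_label = NA_character_, best_evalue = NA_real_,
    best_bits = NA_real_, runner_up_label = NA_character_,
    runner_up_evalue = NA_real_, flags = "", stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  ord <- order(hits$evalue, -hits$bits, hits$model_name)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[1, ]
  flags <- character(0)
  if (nrow(hits) > 1 && hits$evalue[2] == best$evalue &&
      hits$bits[2] == best$bits)
    flags <- c(flags, "ambiguous-tie")
  res <- empty
  res$best_evalue <- best$evalue
  res$best_bits <- best$bits
  if (nrow(hits) > 1) {
    res$runner_up_label <- hits$model_name[2]
    res$runner_up_evalue <- hits$evalue[2]
  }
  if (best$evalue <= config$memberEMax) {
    res$status <- "classified"
    res$primary_label <- best$model_name
    rec <- registryRecords(registry)
    ri <- match(best$model_name, rec$name)
    if (is.na(ri))
      stop("winning model '", best$model_name,
           "' is absent from the registry")
    beq <- rec$bacterial_equivalent[ri]
    if (identical(taxon$domain_of_life, "bacteria") &&
        isTRUE(rec$organellar[ri]) && !is.na(beq) &&
        beq %in% hits$model_name) {
      res$bacterial_equivalent_label <- beq
      res$report_label <- paste0(best$model_name, "(", beq, ")")
    } else {
      res$report_label <- best$model_name
    }
  } else if (best$evalue <= config$gatherEMax) {
    res$status <- "superfamily-nonmember"
  }
  res$flags <- paste(flags, collapse = ";")
  res
}

#' Scan and assign every sequence of a proteome collection
#'
#' @param proteomes Named list (taxon_id -> \code{AAStringSet}).
#' @param models Named list of calibrated models.
#' @param taxa data.frame from \code{readTaxonInfo} (or with columns
#'   taxon_id and domain_of_life).
#' @param registry A \linkS4class{TrgRegistry}.
#' @param config A "TrgConfig".
#' @param hits Optional precomputed \code{scanProteomes} output.
#' @return data.frame of per-sequence classification results (one row
#'   per sequence in the input, including unhit sequences).
#' @export
classifyProteomes <- function(proteomes, models, taxa, registry,
                              config = pipelineConfig(), hits = NULL) {
  if (methods::is(proteomes, "AAStringSet"))
    proteomes <- list(proteome = proteomes)
  if (!length(proteomes)) stop("empty proteome list")
  if (is.null(hits)) hits <- scanProteomes(proteomes, models, config)
  out <- list()
  for (tx in names(proteomes)) {
    trow <- taxa[taxa$taxon_id == tx, , drop = FALSE]
    if (!nrow(trow))
      stop("no taxon metadata for proteome '", tx, "'")
    for (sid in names(proteomes[[tx]])) {
      h <- hits[hits$taxon_id == tx & hits$sequence_id == sid, ,
                drop = FALSE]
      res <- assignSequence(h, as.list(trow[1, ]), registry, config)
      res$sequence_id <- sid
      res$taxon_id <- tx
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

# Profile-align classified member regions to their model's match
# columns: one aligned row of width modelLength(model) per member.
.profileAlignMembers <- function(model, seqs) {
  L <- modelLength(model)
  rows <- vapply(names(seqs), function(sid) {
    vit <- viterbiScore(model, seqs[[sid]])
    aln <- rep("-", L)
    chars <- strsplit(seqs[[sid]], "")[[1]]
    mpos <- vit$stateOf > 0
    aln[vit$stateOf[mpos]] <- chars[mpos]
    paste(aln, collapse = "")
  }, character(1))
  Msa(rows)
}

#' Rebuild the model collection from current classifications
#'
#' For every subfamily with at least one classified member: member
#' analysis regions are re-extracted from the winning-model envelope,
#' deduplicated, fusion-flagged members excluded, the remainder
#' profile-aligned to the current model's match columns, and the model
#' rebuilt and recalibrated. Subfamilies with no classified member keep
#' their previous model (with a warning); a subfamily whose members are
#' all fusion-flagged is an error.
#'
#' @param classifications Output of \code{classifyProteomes}.
#' @param proteomes Named list (taxon_id -> \code{AAStringSet}).
#' @param models Current named model collection.
#' @param config A "TrgConfig".
#' @param round Round number (enters derived calibration seeds).
#' @return Named list of calibrated models (same names as input).
#' @export
rebuildModels <- function(classifications, proteomes, models,
                          config = pipelineConfig(), round = 1L) {
  models <- .checkModels(models)
  cls <- classifications[classifications$status == "classified", ,
                         drop = FALSE]
  flat <- do.call(c, unname(lapply(proteomes, as.character)))
  out <- models
  for (mi in seq_along(models)) {
    mn <- names(models)[mi]
    members <- cls[cls$primary_label == mn, , drop = FALSE]
    if (!nrow(members)) {
      warning("subfamily '", mn,
              "' has no classified member; previous model kept")
      next
    }
    model <- models[[mn]]
    seqs <- flat[members$sequence_id]
    regions <- character(0)
    keptIds <- character(0)
    for (i in seq_len(nrow(members))) {
      s <- seqs[[i]]
      vit <- viterbiScore(model, s)
      if (any(is.na(vit$envelope))) next
      region <- vit$envelope
      if (flagFusion(s, region, modelLength(model))) next
      regions <- c(regions, substr(s, region[1] + 1L, region[2]))
      keptIds <- c(keptIds, members$sequence_id[i])
    }
    if (!length(regions))
      stop("all members of subfamily '", mn,
           "' are fusion-flagged; cannot rebuild")
    names(regions) <- keptIds
    kept <- as.character(dedupSequences(regions))
    names(kept) <- keptIds[!duplicated(regions)]
    msa <- .profileAlignMembers(model, as.list(kept))
    newModel <- buildProfile(msa, matchGapThreshold = config$gapFraction,
                             name = mn,
                             background = model@background)
    out[[mn]] <- calibrate(newModel, nRandom = config$calibrationN,
                           seed = config$seed + 1009L * round + mi)
  }
  out
}

#' Run the iterative classification pipeline
#'
#' Builds and calibrates subfamily models from seed alignments, then
#' alternates proteome scanning/assignment with model rebuilding until
#' the per-sequence assignment map is unchanged between consecutive
#' rounds or \code{maxRounds} is reached (with a warning).
#'
#' @param proteomes Named list (taxon_id -> \code{AAStringSet}).
#' @param seedAlignments Named list (subfamily -> \linkS4class{Msa}).
#' @param taxa Taxon metadata data.frame.
#' @param registry A \linkS4class{TrgRegistry}.
#' @param config A "TrgConfig".
#' @return List with \code{models}, \code{classifications} and
#'   \code{roundLog} (data.frame: round, nClassified, nChanged).
#' @export
iterateClassify <- function(proteomes, seedAlignments, taxa, registry,
                            config = pipelineConfig()) {
  if (!length(proteomes)) stop("empty proteome list")
  if (!length(seedAlignments)) stop("no seed alignments")
  models <- lapply(names(seedAlignments), function(mn) {
    msa <- filterGapColumns(seedAlignments[[mn]],
                            maxGapFraction = config$gapFraction)
    calibrate(buildProfile(msa, matchGapThreshold = config$gapFraction,
                           name = mn),
              nRandom = config$calibrationN,
              seed = config$seed +
                match(mn, names(seedAlignments)))
  })
  names(models) <- names(seedAlignments)
  prevMap <- NULL
  roundLog <- list()
  cls <- NULL
  for (round in seq_len(config$maxRounds)) {
    cls <- classifyProteomes(proteomes, models, taxa, registry, config)
    map <- stats::setNames(cls$primary_label,
                           paste(cls$taxon_id, cls$sequence_id))
    changed <- if (is.null(prevMap)) sum(!is.na(map))
               else sum(!mapequal(map, prevMap[names(map)]))
    roundLog[[round]] <- data.frame(
      round = round, nClassified = sum(cls$status == "classified"),
      nChanged = changed)
    if (!is.null(prevMap) && changed == 0L) break
    prevMap <- map
    if (round < config$maxRounds)
      models <- rebuildModels(cls, proteomes, models, config,
                              round = round)
    else
      warning("assignment map still changing at maxRounds = ",
              config$maxRounds)
  }
  list(models = models, classifications = cls,
       roundLog = do.call(rbind, roundLog))
}

# Elementwise label-map equality treating NA == NA as equal.
mapequal <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

#' Presence/absence and per-sequence classification report
#'
#' @param classifications Output of \code{classifyProteomes}.
#' @param registry A \linkS4class{TrgRegistry}.
#' @return List with \code{presence} (data.frame: one row per taxon,
#'   one count column per registry subfamily) and \code{perSequence}
#'   (data.frame with dual-notation report labels).
#' @export
classificationReport <- function(classifications, registry) {
  subfams <- subfamilyNames(registry)
  taxa <- unique(classifications$taxon_id)
  pres <- matrix(0L, nrow = length(taxa), ncol = length(subfams),
                 dimnames = list(taxa, subfams))
  cls <- classifications[classifications$status == "classified", ,
                         drop = FALSE]
  if (nrow(cls)) {
    tab <- table(cls$taxon_id, cls$primary_label)
    pres[rownames(tab), colnames(tab)] <-
      pres[rownames(tab), colnames(tab)] + as.matrix(tab)
  }
  presence <- data.frame(taxon_id = taxa, as.data.frame(pres),
                         check.names = FALSE, row.names = NULL)
  perSequence <- classifications[, c("sequence_id", "taxon_id",
                                     "status", "report_label",
                                     "best_evalue", "runner_up_label",
                                     "runner_up_evalue", "flags")]
  list(presence = presence, perSequence = perSequence)
}
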