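# Profile-HMM engine: build from alignment, score, calibrate, sample.

#' @useDynLib trgpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Default structural transition parameters of the local-alignment shell.
# loopN/loopC: flank self-loops; pExit: early exit from internal match
# states (the final match state always exits).
.PHMM_LOOP <- 0.99
.PHMM_PEXIT <- 0.01

.defaultTransitions <- function(L, coreM = NULL, coreI = NULL,
                                coreD = NULL, pExit = .PHMM_PEXIT,
                                loop = .PHMM_LOOP) {
  if (is.null(coreM))
    coreM <- matrix(rep(c(0.9, 0.05, 0.05), each = L), nrow = L)
  if (is.null(coreI))
    coreI <- matrix(rep(c(0.8, 0.2), each = L), nrow = L)
  if (is.null(coreD))
    coreD <- matrix(rep(c(0.8, 0.2), each = L), nrow = L)
  coreM <- coreM / rowSums(coreM)
  coreI <- coreI / rowSums(coreI)
  coreD <- coreD / rowSums(coreD)
  fromM <- cbind(coreM * (1 - pExit), pExit)
  fromM[L, ] <- c(0, 0, 0, 1)
  if (L > 1) {
    # A match state one short of the end cannot open an insert run that
    # has nowhere to rejoin; nor can the last two delete chains continue.
    fromI <- cbind(coreI[, 1] + 0, coreI[, 2])
    fromI[L, ] <- c(1, 0)
    fromD <- cbind(coreD[, 1] * (1 - pExit), coreD[, 2] * (1 - pExit),
                   pExit)
    fromD[L, ] <- c(0, 0, 1)
  } else {
    fromI <- matrix(c(1, 0), nrow = 1)
    fromD <- matrix(c(0, 0, 1), nrow = 1)
  }
  colnames(fromM) <- c("MM", "MI", "MD", "ME")
  colnames(fromI) <- c("IM", "II")
  colnames(fromD) <- c("DM", "DD", "DE")
  list(entry = rep(1 / L, L), fromM = fromM, fromI = fromI,
       fromD = fromD, loopN = loop, loopC = loop)
}

#' Construct a ProfileHMM from explicit parameters
#'
#' Low-level constructor; most users build models from alignments with
#' \code{\link{buildProfile}}. Missing transition components fall back to
#' the package defaults (uniform entry over match states, small constant
#' early-exit probability, 0.99 flank self-loops).
#'
#' @param matchEmissions L x 20 matrix of match emission probabilities
#'   (rows normalised; columns in \code{AA_ALPHABET20} order).
#' @param name Model identifier.
#' @param insertEmissions Optional L x 20 insert emission matrix; default
#'   is the background at every state.
#' @param transitions Optional transition list (see
#'   \linkS4class{ProfileHMM}).
#' @param background Length-20 null distribution.
#' @param metadata Free-form list.
#' @return A validated \linkS4class{ProfileHMM}.
#' @export
newProfileHMM <- function(matchEmissions, name = "profile",
                          insertEmissions = NULL, transitions = NULL,
                          background = uniformBackground(),
                          metadata = list()) {
  matchEmissions <- as.matrix(matchEmissions)
  L <- nrow(matchEmissions)
  if (is.null(insertEmissions))
    insertEmissions <- matrix(rep(background, each = L), nrow = L)
  if (is.null(transitions)) transitions <- .defaultTransitions(L)
  colnames(matchEmissions) <- AA_ALPHABET20
  colnames(insertEmissions) <- AA_ALPHABET20
  methods::new("ProfileHMM", name = name,
               matchEmissions = matchEmissions,
               insertEmissions = insertEmissions,
               transitions = transitions,
               background = unname(background), calibration = NULL,
               metadata = metadata)
}

# Henikoff position-based sequence weights for a character matrix with
# '-' gaps; returns weights normalised to sum to the number of rows.
.henikoffWeights <- function(m) {
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- col != "-"
    if (!any(obs)) next
    tab <- table(col[obs])
    r <- length(tab)
    contrib <- numeric(n)
    contrib[obs] <- 1 / (r * as.numeric(tab[col[obs]]))
    w <- w + contrib
  }
  if (sum(w) == 0) w <- rep(1, n)
  w * n / sum(w)
}

.msaMatrix <- function(msa) {
  rows <- as.character(msa@rows)
  do.call(rbind, strsplit(rows, ""))
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns with gap fraction at or below \code{matchGapThreshold} become
#' match states; residues falling in the remaining columns are treated as
#' insertions. Match emissions are Henikoff-weighted residue counts mixed
#' with \code{pseudocountWeight} total pseudocounts distributed as the
#' background; insert states emit the background. Core transition
#' probabilities are estimated from the weighted gap structure of the
#' alignment with Laplace-style pseudocounts, then wrapped in the
#' local-alignment shell (uniform entry, constant early-exit, background
#' flanks).
#'
#' @param msa An \linkS4class{Msa}.
#' @param matchGapThreshold Columns with gap fraction strictly greater
#'   than this become insert columns (default 0.5).
#' @param pseudocountWeight Total pseudocount mass added to each match
#'   emission distribution (default 1).
#' @param name Model identifier.
#' @param background Length-20 null distribution.
#' @return An uncalibrated \linkS4class{ProfileHMM}.
#' @examples
#' msa <- Msa(c(a = "ACDE", b = "ACDE", c = "ACDE"))
#' buildProfile(msa, name = "toy")
#' @export
buildProfile <- function(msa, matchGapThreshold = 0.5,
                         pseudocountWeight = 1,
                         name = "profile",
                         background = uniformBackground()) {
  stopifnot(methods::is(msa, "Msa"))
  if (length(msa) == 0L) stop("empty alignment")
  m <- toupper(.msaMatrix(msa))
  m[m == "."] <- "-"
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  if (pseudocountWeight <= 0) stop("pseudocountWeight must be positive")
  gapFrac <- colMeans(m == "-")
  if (all(gapFrac == 1)) stop("alignment consists only of gap characters")
  matchCols <- which(gapFrac <= matchGapThreshold)
  L <- length(matchCols)
  if (L == 0L) stop("no alignment column qualifies as a match state")
  w <- .henikoffWeights(m)
  bg <- unname(background)
  em <- matrix(0, nrow = L, ncol = 20)
  for (ki in seq_len(L)) {
    col <- m[, matchCols[ki]]
    idx <- .aaIndex(col)
    keep <- idx > 0L
    cnt <- numeric(20)
    if (any(keep))
      cnt <- vapply(1:20, function(a) sum(w[keep][idx[keep] == a]),
                    numeric(1))
    em[ki, ] <- cnt + pseudocountWeight * bg
    em[ki, ] <- em[ki, ] / sum(em[ki, ])
  }
  # Core transition counts from the implied state path of each row.
  cM <- matrix(rep(c(0.90, 0.05, 0.05), each = L), nrow = L)  # priors
  cI <- matrix(rep(c(0.80, 0.20), each = L), nrow = L)
  cD <- matrix(rep(c(0.80, 0.20), each = L), nrow = L)
  isMatch <- seq_len(ncol(m)) %in% matchCols
  colRank <- cumsum(isMatch)  # match index of each column
  for (s in seq_len(nrow(m))) {
    prev <- NULL  # c(type, k): type 1=M, 2=I, 3=D
    for (j in seq_len(ncol(m))) {
      res <- m[s, j] != "-"
      if (isMatch[j]) cur <- c(if (res) 1L else 3L, colRank[j])
      else if (res) cur <- c(2L, colRank[j])  # insert after match k
      else next
      if (!is.null(prev)) {
        k <- prev[2]
        if (prev[1] == 1L && k >= 1L && k <= L) {
          slot <- c(`1` = 1, `2` = 2, `3` = 3)[as.character(cur[1])]
          cM[k, slot] <- cM[k, slot] + w[s]
        } else if (prev[1] == 2L && k >= 1L && k <= L) {
          cI[k, if (cur[1] == 2L) 2 else 1] <-
            cI[k, if (cur[1] == 2L) 2 else 1] + w[s]
        } else if (prev[1] == 3L && k >= 1L && k <= L) {
          cD[k, if (cur[1] == 3L) 2 else 1] <-
            cD[k, if (cur[1] == 3L) 2 else 1] + w[s]
        }
      }
      prev <- cur
    }
  }
  tr <- .defaultTransitions(L, coreM = cM, coreI = cI, coreD = cD)
  hmm <- newProfileHMM(em, name = name, transitions = tr,
                       background = bg,
                       metadata = list(
                         nSequences = nrow(m),
                         matchGapThreshold = matchGapThreshold,
                         pseudocountWeight = pseudocountWeight,
                         sequenceWeighting = "henikoff-position-based",
                         matchColumns = sourceColumns(msa)[matchCols]))
  methods::validObject(hmm)
  hmm
}

.hmmSeqIndex <- function(seq, strict = FALSE) {
  .checkResidues(seq, strict = strict)
}

#' Viterbi score and alignment of a sequence against a profile HMM
#'
#' Returns the log-odds score (bits, base 2, against the background null)
#' of the single best state path, together with the path and the match
#' envelope.
#'
#' @param hmm A \linkS4class{ProfileHMM}.
#' @param seq Amino-acid string.
#' @param strict Reject ambiguous residue codes instead of scoring them
#'   at background odds.
#' @return List with \code{bits}, \code{stateOf} (per residue: 0 = flank,
#'   k = match state k, -k = insert state k), and \code{envelope}, the
#'   0-based half-open interval of residues emitted by the core model.
#' @export
viterbiScore <- function(hmm, seq, strict = FALSE) {
  stopifnot(methods::is(hmm, "ProfileHMM"))
  idx <- .hmmSeqIndex(seq, strict)
  tr <- hmm@transitions
  res <- .phmm_viterbi(hmm@matchEmissions, hmm@insertEmissions,
                       tr$entry, tr$fromM, tr$fromI, tr$fromD,
                       tr$loopN, tr$loopC, hmm@background,
                       as.integer(idx))
  env <- if (is.na(res$envStart)) c(NA_integer_, NA_integer_)
         else c(res$envStart - 1L, res$envEnd)
  list(bits = res$bits, stateOf = res$stateOf, envelope = env)
}

#' Forward score of a sequence against a profile HMM
#'
#' Log-odds (bits) of the sum over all state paths; always at least the
#' Viterbi score.
#'
#' @inheritParams viterbiScore
#' @return Numeric bit score.
#' @export
forwardScore <- function(hmm, seq, strict = FALSE) {
  stopifnot(methods::is(hmm, "ProfileHMM"))
  idx <- .hmmSeqIndex(seq, strict)
  tr <- hmm@transitions
  .phmm_forward(hmm@matchEmissions, hmm@insertEmissions,
                tr$entry, tr$fromM, tr$fromI, tr$fromD,
                tr$loopN, tr$loopC, hmm@background, as.integer(idx))
}

#' Default calibration length sampler
#'
#' Draws sequence lengths uniformly between 200 and 500 residues,
#' spanning typical single-domain to two-domain protein lengths.
#' @param n Number of lengths to draw.
#' @return Integer vector.
#' @export
defaultLengthSampler <- function(n) sample(200:500, n, replace = TRUE)

#' Calibrate a profile HMM for E-value computation
#'
#' Scores \code{nRandom} i.i.d. background-composition random sequences
#' (lengths from \code{lengthSampler}) with the forward algorithm and
#' fits a Gumbel distribution to the resulting bit scores by maximum
#' likelihood. The fitted parameters, sample size and seed are stored in
#' the model's \code{calibration} slot.
#'
#' @param hmm A \linkS4class{ProfileHMM}.
#' @param nRandom Number of random sequences (>= 100).
#' @param lengthSampler Function n -> integer lengths.
#' @param seed Integer seed; the calibration is reproducible under it.
#' @return The calibrated \linkS4class{ProfileHMM}.
#' @export
calibrate <- function(hmm, nRandom = 200L,
                      lengthSampler = defaultLengthSampler,
                      seed = 1L) {
  stopifnot(methods::is(hmm, "ProfileHMM"))
  if (!.isCount(nRandom, 100L))
    stop("nRandom must be an integer >= 100")
  scores <- withSeed(seed, {
    lens <- lengthSampler(nRandom)
    vapply(lens, function(len) {
      s <- paste(AA_ALPHABET20[.rcatN(hmm@background, len)],
                 collapse = "")
      forwardScore(hmm, s)
    }, numeric(1))
  })
  fit <- gumbelFit(scores)
  hmm@calibration <- methods::new("GumbelParams", mu = fit$mu,
                                  lambda = fit$lambda,
                                  nCalibration = as.integer(nRandom),
                                  seed = as.integer(seed))
  hmm
}

# Vectorised categorical draw of n indices from probability vector p.
.rcatN <- function(p, n) {
  findInterval(stats::runif(n), cumsum(p), left.open = TRUE) + 1L
}

#' E-value of a bit score under a calibrated model
#'
#' \eqn{E = N \cdot P(S \ge s)} under the fitted Gumbel null: the
#' expected number of random sequences in a database of size N scoring at
#' least \code{score}. Strictly decreasing in the score and linear in the
#' database size.
#'
#' @param score Bit score(s).
#' @param hmm A calibrated \linkS4class{ProfileHMM}.
#' @param dbSize Database size (number of sequences searched).
#' @return Numeric E-value(s).
#' @export
evalueOf <- function(score, hmm, dbSize) {
  stopifnot(methods::is(hmm, "ProfileHMM"))
  if (!isCalibrated(hmm))
    stop("model '", hmm@name, "' is not calibrated")
  if (!is.numeric(dbSize) || dbSize < 0)
    stop("dbSize must be a non-negative number")
  cal <- hmm@calibration
  dbSize * .pgumbelUpper(score, cal@mu, cal@lambda)
}

#' Sample a sequence from the generative core of a profile HMM
#'
#' Draws a state path through the match/insert/delete core (entering at
#' the first match state, exiting after the last) and emits residues
#' along it. Early-exit and flank states are scoring devices and are not
#' sampled; a model with deterministic emissions and no insert/delete
#' probability therefore yields exactly its consensus.
#'
#' @param hmm A \linkS4class{ProfileHMM}.
#' @param seed Optional integer seed for a reproducible draw.
#' @return List with \code{sequence} (character), \code{stateOf}
#'   (per-residue: k = match k, -k = insert k) and \code{aligned}, the
#'   sampled sequence projected onto the L match columns ('-' at deleted
#'   positions, inserts dropped).
#' @export
sampleSequence <- function(hmm, seed = NULL) {
  stopifnot(methods::is(hmm, "ProfileHMM"))
  tr <- hmm@transitions
  L <- modelLength(hmm)
  withSeed(seed, {
    res <- character(0)
    states <- integer(0)
    alignedRes <- rep("-", L)
    type <- "M"  # enter at match state 1
    k <- 1L
    repeat {
      if (type == "M") {
        a <- .rcat(hmm@matchEmissions[k, ])
        res <- c(res, AA_ALPHABET20[a])
        states <- c(states, k)
        alignedRes[k] <- AA_ALPHABET20[a]
        if (k == L) break
        core <- tr$fromM[k, 1:3]
        core <- core / sum(core)
        nxt <- .rcat(core)
        if (nxt == 1L) { type <- "M"; k <- k + 1L }
        else if (nxt == 2L) type <- "I"
        else { type <- "D"; k <- k + 1L }
      } else if (type == "I") {
        a <- .rcat(hmm@insertEmissions[k, ])
        res <- c(res, AA_ALPHABET20[a])
        states <- c(states, -k)
        core <- tr$fromI[k, ]
        if (.rcat(core / sum(core)) == 1L) { type <- "M"; k <- k + 1L }
      } else {  # D
        if (k == L) break
        core <- tr$fromD[k, 1:2]
        core <- core / sum(core)
        if (.rcat(core) == 1L) { type <- "M"; k <- k + 1L }
        else { type <- "D"; k <- k + 1L }
      }
    }
    list(sequence = paste(res, collapse = ""), stateOf = states,
         aligned = paste(alignedRes, collapse = ""))
  })
}
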