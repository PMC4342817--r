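# Shared test helpers: brute-force path-enumeration oracle for profile-HMM
# scores, and small random model/alignment generators.

# Enumerate every state path of the profile architecture for a sequence
# and return the total and maximum path odds (base-2 logs). Independent
# of the package's dynamic-programming implementation.
oracleScores <- function(hmm, seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], trgpipe::AA_ALPHABET20)
  stopifnot(!anyNA(idx))
  tr <- hmm@transitions
  L <- trgpipe::modelLength(hmm)
  bg <- hmm@background
  emM <- hmm@matchEmissions
  emI <- hmm@insertEmissions
  n <- length(idx)
  total <- 0
  best <- 0
  rec <- function(state, k, i, acc) {
    if (acc == 0) return()
    if (state == "N") {
      if (i < n) rec("N", 0L, i + 1L, acc * tr$loopN)
      rec("B", 0L, i, acc * (1 - tr$loopN))
    } else if (state == "B") {
      for (k2 in seq_len(L)) rec("M", k2, i, acc * tr$entry[k2])
    } else if (state == "M") {
      if (i >= n) return()
      a2 <- acc * emM[k, idx[i + 1L]] / bg[idx[i + 1L]]
      i2 <- i + 1L
      if (k < L) {
        rec("M", k + 1L, i2, a2 * tr$fromM[k, 1])
        rec("I", k, i2, a2 * tr$fromM[k, 2])
        rec("D", k + 1L, i2, a2 * tr$fromM[k, 3])
      }
      rec("E", 0L, i2, a2 * tr$fromM[k, 4])
    } else if (state == "I") {
      if (i >= n) return()
      a2 <- acc * emI[k, idx[i + 1L]] / bg[idx[i + 1L]]
      i2 <- i + 1L
      rec("M", k + 1L, i2, a2 * tr$fromI[k, 1])
      rec("I", k, i2, a2 * tr$fromI[k, 2])
    } else if (state == "D") {
      if (k < L) {
        rec("M", k + 1L, i, acc * tr$fromD[k, 1])
        rec("D", k + 1L, i, acc * tr$fromD[k, 2])
      }
      rec("E", 0L, i, acc * tr$fromD[k, 3])
    } else if (state == "E") {
      rec("C", 0L, i, acc)
    } else {  # C
      if (i < n) rec("C", 0L, i + 1L, acc * tr$loopC)
      else {
        p <- acc * (1 - tr$loopC)
        total <<- total + p
        if (p > best) best <<- p
      }
    }
  }
  rec("N", 0L, 0L, 1)
  list(forward = unname(log2(total)), viterbi = unname(log2(best)))
}

# Random valid profile over a restricted alphabet (emission mass on the
# first nLetters residues), with random transitions respecting the
# structural zeros of the architecture.
makeRandomProfile <- function(L, nLetters = 4L, seed = 1L) {
  set.seed(seed)
  rdirich <- function(n) { x <- stats::rgamma(n, 1); x / sum(x) }
  em <- t(vapply(seq_len(L), function(k) {
    v <- numeric(20); v[seq_len(nLetters)] <- rdirich(nLetters); v
  }, numeric(20)))
  ins <- t(vapply(seq_len(L), function(k) {
    v <- numeric(20); v[seq_len(nLetters)] <- rdirich(nLetters); v
  }, numeric(20)))
  fromM <- t(vapply(seq_len(L), function(k) rdirich(4), numeric(4)))
  fromM[L, ] <- c(0, 0, 0, 1)
  fromI <- t(vapply(seq_len(L), function(k) rdirich(2), numeric(2)))
  if (L >= 1) fromI[L, ] <- c(1, 0)
  fromD <- t(vapply(seq_len(L), function(k) rdirich(3), numeric(3)))
  fromD[L, ] <- c(0, 0, 1)
  tr <- list(entry = rdirich(L), fromM = fromM, fromI = fromI,
             fromD = fromD, loopN = stats::runif(1, 0.3, 0.95),
             loopC = stats::runif(1, 0.3, 0.95))
  trgpipe::newProfileHMM(em, name = paste0("rand", L, "_", seed),
                         insertEmissions = ins, transitions = tr)
}

# All sequences of the given lengths over the first nLetters residues.
allSequences <- function(maxLen, nLetters = 4L) {
  letters20 <- trgpipe::AA_ALPHABET20[seq_len(nLetters)]
  unlist(lapply(seq_len(maxLen), function(len) {
    grid <- do.call(expand.grid, rep(list(letters20), len))
    apply(grid, 1, paste, collapse = "")
  }))
}

# Quick random alignment fixture.
makeRandomMsa <- function(nSeq, width, seed = 1L, gapProb = 0.1) {
  set.seed(seed)
  rows <- vapply(seq_len(nSeq), function(i) {
    chars <- sample(trgpipe::AA_ALPHABET20, width, replace = TRUE)
    gap <- stats::runif(width) < gapProb
    chars[gap] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- paste0("r", seq_len(nSeq))
  trgpipe::Msa(rows)
}
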