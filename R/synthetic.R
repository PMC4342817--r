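# Seeded synthetic proteomes with hierarchical subfamily structure,
# organellar/bacterial near-pairs and decoy classes, so every pipeline
# stage runs and is checkable without any external data.

#' Specification for a synthetic labelled dataset
#'
#' Generator profiles are evolved down a family -> subfamily relatedness
#' tree, so within-subfamily similarity exceeds between-subfamily
#' similarity within a family, which exceeds between-family similarity.
#' Organellar pairs evolve the organellar profile from its bacterial
#' partner at a small divergence, emulating chloroplast factors that
#' remain nearly inseparable from their bacterial counterparts. Decoy
#' classes: composition-preserving shuffles of members (hardest
#' negatives), uniform-random sequences, and G-domain-only sequences
#' representing GTPases outside the superfamily (diverged from the
#' superfamily root, with no domain II region).
#'
#' The default is the packaged benchmark: 8 subfamilies in 3 families,
#' 20 members per subfamily, 3 divergence levels across taxa, 150
#' decoys, seed 20150214.
#'
#' @param seed Master integer seed.
#' @param families Named list: family -> character vector of subfamily
#'   names (registry names, so classifications resolve).
#' @param organellarPairs List of c(organellar, bacterial) name pairs;
#'   both must appear in \code{families}.
#' @param divergenceLevels Named, strictly increasing per-site
#'   substitution probabilities of the taxa.
#' @param membersPerSubfamily Total members per subfamily, split across
#'   the taxa listing that subfamily.
#' @param decoys Named counts: shuffled, random, gdomain_only.
#' @param taxa List of taxon descriptors: list(taxon_id, domain_of_life,
#'   level, subfamilies).
#' @param gLength,d2Length Match-state counts of the G-domain and domain
#'   II blocks of every generator profile (analysis region = both).
#' @param flankRange Random-flank length range (uniform draw per side).
#' @param consensusProb Emission probability of the consensus residue at
#'   each match state.
#' @param familyDivergence,subfamilyDivergence,pairDivergence Per-site
#'   consensus redraw probabilities on the root->family,
#'   family->subfamily and bacterial->organellar edges.
#' @param decoyGDivergence Per-site consensus redraw probability applied
#'   to the superfamily root before drawing each G-domain-only decoy, so
#'   that these decoys emulate G-domain GTPases outside the superfamily
#'   (roughly 30 percent identity to any subfamily) rather than
#'   superfamily fragments.
#' @return A validated spec list of class "TrgSyntheticSpec".
#' @export
syntheticDatasetSpec <- function(
    seed = 20150214L,
    families = list(
      EF2 = c("EF-G", "LepA", "RF3"),
      EF1S = c("EF-Tu", "cEFTu", "SelB"),
      IF2 = c("IF2", "mIF2")),
    organellarPairs = list(c("cEFTu", "EF-Tu")),
    divergenceLevels = c(d1 = 0.05, d2 = 0.15, d3 = 0.30),
    membersPerSubfamily = 20L,
    decoys = c(shuffled = 50L, random = 50L, gdomain_only = 50L),
    taxa = NULL,
    gLength = 140L, d2Length = 90L,
    flankRange = c(20L, 60L),
    consensusProb = 0.9,
    familyDivergence = 0.45,
    subfamilyDivergence = 0.25,
    pairDivergence = 0.08,
    decoyGDivergence = 0.35) {
  if (is.null(taxa)) {
    bacterial <- c("EF-G", "LepA", "RF3", "EF-Tu", "SelB", "IF2")
    taxa <- list(
      list(taxon_id = "synb_d1", domain_of_life = "bacteria",
           level = "d1", subfamilies = c(bacterial, "cEFTu")),
      list(taxon_id = "syne_d1", domain_of_life = "eukaryote",
           level = "d1", subfamilies = c("cEFTu", "mIF2")),
      list(taxon_id = "synb_d2", domain_of_life = "bacteria",
           level = "d2", subfamilies = bacterial),
      list(taxon_id = "synb_d3", domain_of_life = "bacteria",
           level = "d3", subfamilies = bacterial))
  }
  allSub <- unlist(families, use.names = FALSE)
  if (anyDuplicated(allSub)) stop("duplicate subfamily in families")
  if (is.unsorted(divergenceLevels, strictly = TRUE))
    stop("divergence levels must be strictly increasing")
  if (any(divergenceLevels < 0 | divergenceLevels > 1))
    stop("divergence levels must be probabilities")
  if (any(decoys < 0)) stop("decoy counts must be non-negative")
  for (p in organellarPairs)
    if (!all(p %in% allSub))
      stop("organellar pair references unknown profile(s): ",
           paste(p, collapse = ", "))
  for (tx in taxa) {
    if (!tx$domain_of_life %in% REGISTRY_DOMAINS)
      stop("unknown domain for taxon ", tx$taxon_id)
    if (!all(tx$subfamilies %in% allSub))
      stop("taxon ", tx$taxon_id, " lists unknown subfamilies")
    if (!tx$level %in% names(divergenceLevels))
      stop("taxon ", tx$taxon_id, " has unknown divergence level")
  }
  structure(list(seed = as.integer(seed), families = families,
                 organellarPairs = organellarPairs,
                 divergenceLevels = divergenceLevels,
                 membersPerSubfamily = as.integer(membersPerSubfamily),
                 decoys = decoys, taxa = taxa,
                 gLength = as.integer(gLength),
                 d2Length = as.integer(d2Length),
                 flankRange = as.integer(flankRange),
                 consensusProb = consensusProb,
                 familyDivergence = familyDivergence,
                 subfamilyDivergence = subfamilyDivergence,
                 pairDivergence = pairDivergence,
                 decoyGDivergence = decoyGDivergence),
            class = "TrgSyntheticSpec")
}

# Redraw each consensus position with probability rate (new residue
# drawn uniformly from the other 19).
.evolveConsensus <- function(cons, rate) {
  hit <- stats::runif(length(cons)) < rate
  if (any(hit)) {
    repl <- vapply(cons[hit], function(a)
      sample(setdiff(1:20, a), 1L), integer(1))
    cons[hit] <- repl
  }
  cons
}

.profileFromConsensus <- function(cons, name, consensusProb = 0.9) {
  L <- length(cons)
  em <- matrix((1 - consensusProb) / 19, nrow = L, ncol = 20)
  em[cbind(seq_len(L), cons)] <- consensusProb
  newProfileHMM(em, name = name,
                metadata = list(generator = "synthetic-consensus"))
}

.randomSeq <- function(len) {
  paste(AA_ALPHABET20[sample.int(20, len, replace = TRUE)],
        collapse = "")
}

.shuffleSeq <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  paste(chars[sample.int(length(chars))], collapse = "")
}

# Per-site substitution at probability d (substituted residue uniform
# over the other 19).
.mutateSeq <- function(seq, d) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < d)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA_ALPHABET20, a), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Build the generator profile collection for a synthetic spec
#'
#' A root consensus is drawn and evolved down the family -> subfamily
#' tree; organellar pair members are evolved from their bacterial
#' partner at the (small) pair divergence instead of from the family
#' ancestor. The returned record verifies the intended similarity
#' ordering empirically on sampled sequence pairs.
#'
#' @param spec A "TrgSyntheticSpec".
#' @return List with \code{profiles} (named list of
#'   \linkS4class{ProfileHMM}, one per subfamily), \code{gProfile} (the
#'   root G-domain-only profile), \code{record} (data.frame of empirical
#'   mean p-distances: within-subfamily, between-subfamily within
#'   family, between-family) and \code{consensus} (named list of
#'   consensus index vectors).
#' @export
makeGeneratorProfiles <- function(spec) {
  stopifnot(inherits(spec, "TrgSyntheticSpec"))
  withSeed(spec$seed, {
    L <- spec$gLength + spec$d2Length
    root <- sample.int(20, L, replace = TRUE)
    famCons <- lapply(spec$families, function(subs)
      .evolveConsensus(root, spec$familyDivergence))
    cons <- list()
    pairMap <- stats::setNames(
      vapply(spec$organellarPairs, `[`, character(1), 1),
      vapply(spec$organellarPairs, `[`, character(1), 2))
    organellar <- unname(vapply(spec$organellarPairs, `[`,
                                character(1), 1))
    for (fam in names(spec$families)) {
      for (sub in spec$families[[fam]]) {
        if (sub %in% organellar) next  # derived from partner below
        cons[[sub]] <- .evolveConsensus(famCons[[fam]],
                                        spec$subfamilyDivergence)
      }
    }
    for (p in spec$organellarPairs)
      cons[[p[1]]] <- .evolveConsensus(cons[[p[2]]],
                                       spec$pairDivergence)
    profiles <- lapply(names(cons), function(nm)
      .profileFromConsensus(cons[[nm]], nm, spec$consensusProb))
    names(profiles) <- names(cons)
    gConsensus <- root[seq_len(spec$gLength)]
    gProfile <- .profileFromConsensus(gConsensus, "G-domain",
                                      spec$consensusProb)
    # Empirical similarity ordering on sampled pairs.
    subFam <- stats::setNames(
      rep(names(spec$families), lengths(spec$families)),
      unlist(spec$families, use.names = FALSE))
    pairDist <- function(a, b) {
      sa <- strsplit(sampleSequence(profiles[[a]])$aligned, "")[[1]]
      sb <- strsplit(sampleSequence(profiles[[b]])$aligned, "")[[1]]
      ok <- sa != "-" & sb != "-"
      mean(sa[ok] != sb[ok])
    }
    subs <- names(profiles)
    nPair <- 30L
    within <- mean(vapply(seq_len(nPair), function(i) {
      s <- sample(subs, 1L); pairDist(s, s)
    }, numeric(1)))
    multiFams <- names(spec$families)[lengths(spec$families) >= 2L]
    sameFam <- if (!length(multiFams)) NA_real_ else
      mean(vapply(seq_len(nPair), function(i) {
        fam <- if (length(multiFams) == 1L) multiFams
               else sample(multiFams, 1L)
        p <- sample(spec$families[[fam]], 2L)
        pairDist(p[1], p[2])
      }, numeric(1)))
    diffFam <- if (length(spec$families) < 2L) NA_real_ else
      mean(vapply(seq_len(nPair), function(i) {
        fams <- sample(names(spec$families), 2L)
        pairDist(sample(spec$families[[fams[1]]], 1L)[1],
                 sample(spec$families[[fams[2]]], 1L)[1])
      }, numeric(1)))
    record <- data.frame(comparison = c("within-subfamily",
                                        "between-subfamily-within-family",
                                        "between-family"),
                         mean_p_distance = c(within, sameFam, diffFam))
    list(profiles = profiles, gProfile = gProfile,
         gConsensus = gConsensus, record = record,
         consensus = cons, subfamilyFamily = subFam)
  })
}

.memberQuota <- function(total, nTaxa) {
  base <- total %/% nTaxa
  extra <- total %% nTaxa
  rep(base, nTaxa) + c(rep(1L, extra), rep(0L, nTaxa - extra))
}

#' Generate labelled synthetic proteomes, truth table and seed
#' alignments
#'
#' Members are sampled from their subfamily generator profile, mutated
#' at their taxon's per-site divergence, and embedded in random flanks;
#' decoys are added round-robin across taxa. Seed alignments (6 rows per
#' subfamily, emitted from the sampling paths, no aligner involved) are
#' returned alongside. Byte-identical output under identical spec+seed.
#'
#' @param spec A "TrgSyntheticSpec".
#' @param profiles Output of \code{makeGeneratorProfiles(spec)}.
#' @return List with \code{proteomes} (named list of
#'   \code{AAStringSet}), \code{truth} (data.frame: sequence_id,
#'   taxon_id, class, subfamily, divergence), \code{seedAlignments}
#'   (named list of \linkS4class{Msa}) and \code{taxa} (data.frame).
#' @export
generateProteomes <- function(spec, profiles) {
  stopifnot(inherits(spec, "TrgSyntheticSpec"))
  withSeed(spec$seed + 1L, {
    nSeed <- 6L
    seedAlignments <- lapply(profiles$profiles, function(p) {
      rows <- vapply(seq_len(nSeed), function(i)
        sampleSequence(p)$aligned, character(1))
      names(rows) <- paste0("seed_", modelName(p), "_", seq_len(nSeed))
      Msa(rows)
    })
    allSub <- unlist(spec$families, use.names = FALSE)
    taxIds <- vapply(spec$taxa, `[[`, character(1), "taxon_id")
    seqs <- stats::setNames(vector("list", length(taxIds)), taxIds)
    truth <- list()
    counter <- 0L
    addSeq <- function(tx, s, class, subfamily, div) {
      counter <<- counter + 1L
      sid <- sprintf("s%04d_%s", counter,
                     if (is.na(subfamily)) class else subfamily)
      sid <- gsub("[^A-Za-z0-9_.-]", ".", sid)
      seqs[[tx]][[sid]] <<- s
      truth[[length(truth) + 1L]] <<- data.frame(
        sequence_id = sid, taxon_id = tx, class = class,
        subfamily = subfamily, divergence = div,
        stringsAsFactors = FALSE)
    }
    memberSeqs <- character(0)
    for (sub in allSub) {
      listing <- which(vapply(spec$taxa, function(tx)
        sub %in% tx$subfamilies, logical(1)))
      quota <- .memberQuota(spec$membersPerSubfamily, length(listing))
      for (li in seq_along(listing)) {
        tx <- spec$taxa[[listing[li]]]
        d <- spec$divergenceLevels[[tx$level]]
        for (m in seq_len(quota[li])) {
          core <- sampleSequence(profiles$profiles[[sub]])$sequence
          core <- .mutateSeq(core, d)
          fl <- sample(spec$flankRange[1]:spec$flankRange[2], 2L,
                       replace = TRUE)
          s <- paste0(.randomSeq(fl[1]), core, .randomSeq(fl[2]))
          addSeq(tx$taxon_id, s, "member", sub, d)
          memberSeqs <- c(memberSeqs, s)
        }
      }
    }
    rr <- 0L
    nextTaxon <- function() {
      rr <<- rr + 1L
      taxIds[((rr - 1L) %% length(taxIds)) + 1L]
    }
    for (i in seq_len(spec$decoys[["shuffled"]])) {
      src <- if (length(memberSeqs))
        memberSeqs[sample.int(length(memberSeqs), 1L)]
      else .randomSeq(300L)
      addSeq(nextTaxon(), .shuffleSeq(src), "decoy-shuffled",
             NA_character_, NA_real_)
    }
    for (i in seq_len(spec$decoys[["random"]])) {
      len <- sample(200:400, 1L)
      addSeq(nextTaxon(), .randomSeq(len), "decoy-random",
             NA_character_, NA_real_)
    }
    for (i in seq_len(spec$decoys[["gdomain_only"]])) {
      # an out-of-superfamily GTPase: G-domain-like, no domain II, and
      # well diverged from every subfamily profile
      outCons <- .evolveConsensus(profiles$gConsensus,
                                  spec$decoyGDivergence)
      outProf <- .profileFromConsensus(outCons, "decoyG",
                                       spec$consensusProb)
      core <- sampleSequence(outProf)$sequence
      fl <- sample(spec$flankRange[1]:spec$flankRange[2], 2L,
                   replace = TRUE)
      addSeq(nextTaxon(), paste0(.randomSeq(fl[1]), core,
                                 .randomSeq(fl[2])),
             "decoy-gonly", NA_character_, NA_real_)
    }
    proteomes <- lapply(seqs, function(x)
      Biostrings::AAStringSet(unlist(x)))
    taxa <- data.frame(
      taxon_id = taxIds,
      name = taxIds,
      domain_of_life = vapply(spec$taxa, `[[`, character(1),
                              "domain_of_life"),
      stringsAsFactors = FALSE)
    taxa$lineage <- lapply(taxa$domain_of_life, function(d)
      c(d, "synthetic"))
    list(proteomes = proteomes, truth = do.call(rbind, truth),
         seedAlignments = seedAlignments, taxa = taxa)
  })
}

#' Minimal-repertoire synthetic proteome for a domain of life
#'
#' One sampled member per subfamily of the registry's minimal
#' composition for the domain, plus 50 composition-preserving shuffled
#' decoys, with matching seed alignments — the fixture used to check
#' end-to-end recovery of the minimal repertoires.
#'
#' @param registry A \linkS4class{TrgRegistry}.
#' @param domain_of_life One of bacteria, archaea, eukaryote.
#' @param seed Integer seed.
#' @return As \code{generateProteomes}: list(proteomes, truth,
#'   seedAlignments, taxa).
#' @export
minimalCompositionFixture <- function(registry, domain_of_life,
                                      seed = 20150214L) {
  minimal <- minimalComposition(registry, domain_of_life)  # errors if unknown
  rec <- registryRecords(registry)
  fams <- rec$family[match(minimal, rec$name)]
  families <- split(minimal, fams)
  spec <- syntheticDatasetSpec(
    seed = seed, families = families, organellarPairs = list(),
    membersPerSubfamily = 1L,
    decoys = c(shuffled = 50L, random = 0L, gdomain_only = 0L),
    taxa = list(list(taxon_id = paste0("minimal_", domain_of_life),
                     domain_of_life = domain_of_life, level = "d1",
                     subfamilies = unname(minimal))))
  profiles <- makeGeneratorProfiles(spec)
  generateProteomes(spec, profiles)
}
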