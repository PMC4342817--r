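# Candidate gathering, G-domain checks, region extraction, gap filtering,
# dedup, fusion flagging and active-site surveys.

.twoModelSetup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- syntheticDatasetSpec(
      seed = 51, families = list(F1 = "EF-G", F2 = "EF-Tu"),
      organellarPairs = list(), membersPerSubfamily = 1L,
      decoys = c(shuffled = 0L, random = 0L, gdomain_only = 0L),
      gLength = 60L, d2Length = 40L,
      taxa = list(list(taxon_id = "t", domain_of_life = "bacteria",
                       level = "d1",
                       subfamilies = c("EF-G", "EF-Tu"))))
    prof <- makeGeneratorProfiles(spec)
    models <- lapply(prof$profiles, calibrate, nRandom = 100,
                     lengthSampler = function(n)
                       sample(100:250, n, replace = TRUE),
                     seed = 13)
    cache <<- list(models = models, gModel = calibrate(
      prof$gProfile, nRandom = 300,
      lengthSampler = function(n) sample(100:250, n, replace = TRUE),
      seed = 14))
    cache
  }
})

test_that("gathering keeps members, drops decoys, and is monotone in the threshold", {
  setup <- .twoModelSetup()
  models <- setup$models
  withr::with_seed(3, {
    member <- sampleSequence(models[["EF-G"]])$sequence
    decoys <- vapply(1:100, function(i)
      trgpipe:::.shuffleSeq(member), character(1))
    prot <- Biostrings::AAStringSet(c(member = member,
      stats::setNames(decoys, paste0("d", 1:100))))
    got <- gatherCandidates(prot, models, eMax = 1e-3)
    expect_true("member" %in% names(got))
    # shuffled decoys: expected <= 0.1 x 2 models pass at E <= 1e-3
    expect_lte(sum(names(got) != "member"), 2)
    # monotone: lowering eMax never adds members
    sets <- lapply(c(1e-10, 1e-3, 1), function(e)
      names(gatherCandidates(prot, models, eMax = e)))
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
    expect_length(gatherCandidates(prot, models, eMax = 0), 0L)
  })
  expect_error(gatherCandidates(Biostrings::AAStringSet(), models),
               "empty proteome")
  raw <- buildProfile(Msa(c(a = "ACDE", b = "ACDE")))
  expect_error(gatherCandidates(
    Biostrings::AAStringSet(c(x = "ACDE")), list(raw)), "uncalibrated")
})

test_that("G-domain check finds embedded domains with accurate envelopes", {
  setup <- .twoModelSetup()
  gModel <- setup$gModel
  withr::with_seed(5, {
    hits <- 0
    for (i in 1:10) {
      core <- sampleSequence(gModel)$sequence
      left <- trgpipe:::.randomSeq(40)
      right <- trgpipe:::.randomSeq(50)
      s <- paste0(left, core, right)
      chk <- checkGDomain(s, gModel, eCut = 1e-3)
      expect_true(chk$hasGDomain)
      truth <- c(40L, 40L + nchar(core))
      inter <- max(0, min(chk$envelope[2], truth[2]) -
                     max(chk$envelope[1], truth[1]))
      unin <- max(chk$envelope[2], truth[2]) -
        min(chk$envelope[1], truth[1])
      expect_gte(inter / unin, 0.5)
    }
    # equal-length pure random sequences should not pass
    fp <- sum(vapply(1:100, function(i)
      checkGDomain(trgpipe:::.randomSeq(150), gModel,
                   eCut = 1e-3)$hasGDomain, logical(1)))
    # expected 0.1 under a perfect fit; allow for tail-fit error
    expect_lte(fp, 3)
  })
  short <- checkGDomain("A", setup$gModel, eCut = 1e-3)
  expect_false(short$hasGDomain)
})

test_that("analysis regions follow the domain II / +100 residue rule", {
  expect_identical(extractRegion(strrep("A", 400), c(10, 190),
                                 c(210, 310)), c(10L, 310L))
  expect_identical(extractRegion(strrep("A", 400), c(10, 190)),
                   c(10L, 290L))
  expect_identical(extractRegion(strrep("A", 250), c(10, 190)),
                   c(10L, 250L))
  expect_error(extractRegion(strrep("A", 100), c(10, 190)),
               "outside sequence")
})

test_that("gap-column filtering respects the strict > threshold and is idempotent", {
  m <- Msa(c(a = "A-CDE", b = "A-CDE", c = "AWCDE", d = "A-C-E",
             e = "A-CDE"))  # col2: 4/5 gaps; col4: 1/5
  f <- filterGapColumns(m, 0.5)
  expect_identical(msaWidth(f), 4L)
  expect_identical(sourceColumns(f), c(1L, 3L, 4L, 5L))
  # exactly-at-threshold columns are retained
  m2 <- Msa(c(a = "A-CD", b = "A-CD", c = "AWCD", d = "AWCD"))
  expect_identical(msaWidth(filterGapColumns(m2, 0.5)), 4L)
  # gap-free alignment unchanged; composition equals single application
  g <- Msa(c(a = "ACDE", b = "ACDE"))
  expect_identical(as.character(msaRows(filterGapColumns(g))),
                   as.character(msaRows(g)))
  for (sd in 1:5) {
    r <- makeRandomMsa(5, 40, seed = sd, gapProb = 0.4)
    once <- filterGapColumns(r, 0.5)
    expect_true(all(gapFractions(once) <= 0.5))
    twice <- filterGapColumns(once, 0.5)
    expect_identical(as.character(msaRows(once)),
                     as.character(msaRows(twice)))
    expect_identical(sourceColumns(once), sourceColumns(twice))
  }
  expect_error(filterGapColumns(Msa(c(a = "--", b = "--")), 0.4),
               "no column survives")
})

test_that("deduplication keeps first occurrences and is idempotent", {
  s <- Biostrings::AAStringSet(c(x = "ACDE", y = "ACDE", z = "ACDF"))
  d <- dedupSequences(s)
  expect_identical(names(d), c("x", "z"))
  many <- Biostrings::AAStringSet(
    stats::setNames(rep("GKLM", 10), paste0("s", 1:10)))
  expect_length(dedupSequences(many), 1L)
  expect_identical(as.character(dedupSequences(d)), as.character(d))
})

test_that("fusion flagging fires on long low-coverage architectures only", {
  consensus <- 100L
  # CysN/CysC-like: scored core covers half of a 2x-consensus protein
  expect_true(flagFusion(strrep("A", 220), c(5, 105), consensus))
  # ordinary member with short flanks
  expect_false(flagFusion(strrep("A", 140), c(20, 120), consensus))
  # shorter than the consensus is never a fusion
  expect_false(flagFusion(strrep("A", 80), c(0, 30), consensus))
})

test_that("site surveys report residues and substitutions at named columns", {
  rows <- c(EFG1 = "GDAG", EFG2 = "GDTG", eIF2g = "GANG")
  msa <- Msa(rows)
  sv <- siteSurvey(msa, c(`P-loop-Asp` = 2L, `SwitchI-Gly` = 3L))
  expect_identical(sv$perSequence["EFG1", "P-loop-Asp"], "D")
  expect_identical(sv$perSequence["eIF2g", "P-loop-Asp"], "A")
  expect_identical(sv$perSequence["eIF2g", "SwitchI-Gly"], "N")
  expect_identical(as.integer(sv$summary[["P-loop-Asp"]][["D"]]), 2L)
  empty <- siteSurvey(msa, stats::setNames(integer(0), character(0)))
  expect_identical(ncol(empty$perSequence), 0L)
  expect_error(siteSurvey(msa, c(bad = 9L)), "out of range")
})

test_that("proteome and taxon sidecar readers validate their input", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "ACDE", ">s2", "GKLM"), fa)
  p <- readProteome(fa)
  expect_identical(names(p), c("s1", "s2"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tname\tdomain_of_life\tlineage",
               "t1\tTaxon one\tbacteria\tBacteria;Proteo"), tsv)
  tx <- readTaxonInfo(tsv)
  expect_identical(tx$domain_of_life, "bacteria")
  expect_identical(tx$lineage[[1]], c("Bacteria", "Proteo"))
  writeLines(c("taxon_id\tname\tdomain_of_life\tlineage",
               "t1\tx\tviruses\ta;b"), tsv)
  expect_error(readTaxonInfo(tsv), "unknown domain")
})

test_that("Stockholm alignments read identically to their FASTA equivalent", {
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               "seq1  ACD-",
               "seq2  ACDE",
               "", "seq1  GK", "seq2  GK", "//"), sto)
  m <- readStockholm(sto)
  expect_identical(as.character(msaRows(m)),
                   c(seq1 = "ACD-GK", seq2 = "ACDEGK"))
  bad <- tempfile()
  writeLines("seq1 ACDE", bad)
  expect_error(readStockholm(bad), "STOCKHOLM")
})
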