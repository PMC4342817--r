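# Competitive assignment, dual notation, iteration and reporting.

reg <- loadRegistry()

.fakeHits <- function(sid, models, evalues, bits = NULL,
                      taxon = "t1") {
  if (!length(models))
    return(data.frame(taxon_id = character(), sequence_id = character(),
                      model_name = character(), bits = numeric(),
                      evalue = numeric(), env_start = integer(),
                      env_end = integer(), stringsAsFactors = FALSE))
  data.frame(taxon_id = taxon, sequence_id = sid,
             model_name = models, bits = if (is.null(bits))
               -log10(evalues) else bits,
             evalue = evalues, env_start = 0L, env_end = 10L,
             stringsAsFactors = FALSE)
}

test_that("configuration thresholds are validated", {
  expect_error(pipelineConfig(gatherEMax = 1e-20, memberEMax = 1e-3),
               "memberEMax")
  expect_error(pipelineConfig(maxRounds = 0), "maxRounds")
  expect_error(pipelineConfig(calibrationN = 10), "calibrationN")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("gatherEMax: 1.0e-3", "memberEMax: 1.0e-25",
               "maxRounds: 4"), yml)
  cfg <- readPipelineConfig(yml)
  expect_identical(cfg$memberEMax, 1e-25)
  expect_identical(cfg$maxRounds, 4L)
  writeLines("unknownKey: 2", yml)
  expect_error(readPipelineConfig(yml), "unknown configuration key")
})

test_that("assignment follows the e-20 membership cutoff", {
  cfg <- pipelineConfig()
  taxon <- list(taxon_id = "t1", domain_of_life = "bacteria")
  clear <- assignSequence(
    .fakeHits("s1", c("EF-G", "EFGII"), c(1e-80, 1e-35)),
    taxon, reg, cfg)
  expect_identical(clear$status, "classified")
  expect_identical(clear$primary_label, "EF-G")
  expect_identical(clear$report_label, "EF-G")
  expect_identical(clear$runner_up_label, "EFGII")
  weak <- assignSequence(.fakeHits("s2", "EF-G", 1e-10), taxon, reg,
                         cfg)
  expect_identical(weak$status, "superfamily-nonmember")
  expect_true(is.na(weak$primary_label))
  none <- assignSequence(.fakeHits("s3", character(0), numeric(0)),
                         taxon, reg, cfg)
  expect_identical(none$status, "candidate-unassigned")
  expect_error(assignSequence(
    rbind(.fakeHits("a", "EF-G", 1e-30), .fakeHits("b", "EF-G", 1e-30)),
    taxon, reg, cfg), "multiple sequences")
  expect_error(assignSequence(.fakeHits("s4", "NotAModel", 1e-30),
                              taxon, reg, cfg), "absent from the registry")
})

test_that("ties are broken deterministically and flagged", {
  cfg <- pipelineConfig()
  taxon <- list(taxon_id = "t1", domain_of_life = "bacteria")
  tie <- assignSequence(
    .fakeHits("s1", c("LepA", "EF-G"), c(1e-40, 1e-40),
              bits = c(100, 100)), taxon, reg, cfg)
  expect_identical(tie$primary_label, "EF-G")  # lexicographic
  expect_match(tie$flags, "ambiguous-tie")
  byBits <- assignSequence(
    .fakeHits("s1", c("LepA", "EF-G"), c(1e-40, 1e-40),
              bits = c(120, 100)), taxon, reg, cfg)
  expect_identical(byBits$primary_label, "LepA")
})

test_that("dual notation fires only for bacterial taxa won by organellar models", {
  cfg <- pipelineConfig()
  cyano <- list(taxon_id = "cy", domain_of_life = "bacteria")
  dual <- assignSequence(
    .fakeHits("s1", c("cEFTu", "EF-Tu"), c(1e-60, 1e-55)),
    cyano, reg, cfg)
  expect_identical(dual$primary_label, "cEFTu")
  expect_identical(dual$bacterial_equivalent_label, "EF-Tu")
  expect_identical(dual$report_label, "cEFTu(EF-Tu)")
  # same hits, eukaryotic taxon: no dual label
  plant <- list(taxon_id = "pl", domain_of_life = "eukaryote")
  single <- assignSequence(
    .fakeHits("s1", c("cEFTu", "EF-Tu"), c(1e-60, 1e-55)),
    plant, reg, cfg)
  expect_true(is.na(single$bacterial_equivalent_label))
  expect_identical(single$report_label, "cEFTu")
  # equivalent not hitting: no dual label even for bacteria
  lone <- assignSequence(.fakeHits("s1", "cEFTu", 1e-60), cyano, reg,
                         cfg)
  expect_identical(lone$report_label, "cEFTu")
  # property: random winner/taxon combinations
  rec <- registryRecords(reg)
  set.seed(23)
  for (i in 1:40) {
    ri <- sample(nrow(rec), 1)
    dom <- sample(c("bacteria", "archaea", "eukaryote"), 1)
    winner <- rec$name[ri]
    beq <- rec$bacterial_equivalent[ri]
    hitModels <- c(winner, if (!is.na(beq)) beq)
    res <- assignSequence(
      .fakeHits("sx", hitModels,
                c(1e-50, rep(1e-45, length(hitModels) - 1))),
      list(taxon_id = "tx", domain_of_life = dom), reg, cfg)
    fired <- !is.na(res$bacterial_equivalent_label)
    expect_identical(fired,
                     dom == "bacteria" && rec$organellar[ri] &&
                       !is.na(beq))
  }
})

.miniDataset <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- syntheticDatasetSpec(
      seed = 61,
      families = list(EF1S = c("EF-Tu", "cEFTu"), EF2 = "EF-G"),
      organellarPairs = list(c("cEFTu", "EF-Tu")),
      membersPerSubfamily = 4L,
      decoys = c(shuffled = 10L, random = 5L, gdomain_only = 5L),
      gLength = 80L, d2Length = 50L,
      taxa = list(list(taxon_id = "cyano", domain_of_life = "bacteria",
                       level = "d1",
                       subfamilies = c("EF-Tu", "cEFTu", "EF-G"))))
    prof <- makeGeneratorProfiles(spec)
    ds <- generateProteomes(spec, prof)
    cfg <- pipelineConfig(seed = 17, calibrationN = 100L)
    run <- iterateClassify(ds$proteomes, ds$seedAlignments, ds$taxa,
                           reg, cfg)
    cache <<- list(spec = spec, ds = ds, cfg = cfg, run = run)
    cache
  }
})

test_that("scanning yields source-model best hits for members and none for decoys at e-20", {
  md <- .miniDataset()
  hits <- scanProteomes(md$ds$proteomes, md$run$models, md$cfg)
  truth <- md$ds$truth
  members <- truth[truth$class == "member", ]
  for (i in seq_len(nrow(members))) {
    h <- hits[hits$sequence_id == members$sequence_id[i], ]
    expect_gt(nrow(h), 0)
    expect_identical(h$model_name[which.min(h$evalue)],
                     members$subfamily[i])
  }
  decoyIds <- truth$sequence_id[truth$class == "decoy-shuffled"]
  dh <- hits[hits$sequence_id %in% decoyIds, ]
  expect_identical(sum(dh$evalue <= 1e-20), 0L)
  expect_identical(nrow(scanProteomes(
    list(t = Biostrings::AAStringSet()), md$run$models, md$cfg)), 0L)
  expect_error(scanProteomes(md$ds$proteomes, list(), md$cfg),
               "empty model collection")
})

test_that("no classified sequence ever violates the membership cutoff", {
  md <- .miniDataset()
  cls <- md$run$classifications
  classified <- cls[cls$status == "classified", ]
  expect_true(all(classified$best_evalue <= md$cfg$memberEMax))
  expect_true(all(is.na(cls$primary_label) |
                    cls$status == "classified"))
})

test_that("iteration converges and recovers the generated labels", {
  md <- .miniDataset()
  log <- md$run$roundLog
  expect_lte(nrow(log), 3)
  expect_identical(log$nChanged[nrow(log)], 0L)
  tr <- merge(md$run$classifications, md$ds$truth,
              by = c("sequence_id", "taxon_id"))
  members <- tr[tr$class == "member", ]
  expect_true(all(members$primary_label == members$subfamily))
  decoys <- tr[tr$class != "member", ]
  expect_identical(sum(decoys$status == "classified"), 0L)
  # at least one dual-notation call for the organellar pair
  expect_gte(sum(grepl("^cEFTu\\(EF-Tu\\)$",
                       tr$report_label[tr$subfamily == "cEFTu"],
                       perl = FALSE)), 1L)
  expect_error(iterateClassify(list(), list(), NULL, reg, md$cfg),
               "empty proteome list")
})

test_that("rebuilding keeps assignments stable and handles edge cases", {
  md <- .miniDataset()
  cls <- md$run$classifications
  rebuilt <- rebuildModels(cls, md$ds$proteomes, md$run$models,
                           md$cfg, round = 9L)
  cls2 <- classifyProteomes(md$ds$proteomes, rebuilt, md$ds$taxa, reg,
                            md$cfg)
  expect_identical(cls2$primary_label, cls$primary_label)
  # a subfamily with zero members carries its model over with a warning
  noEFG <- cls[!(cls$primary_label %in% "EF-G") | is.na(cls$primary_label), ]
  expect_warning(
    rebuildModels(noEFG, md$ds$proteomes, md$run$models, md$cfg),
    "no classified member")
  # all members fusion-flagged is an error naming the subfamily
  fused <- cls[cls$primary_label %in% "EF-G" & !is.na(cls$primary_label), , drop = FALSE]
  prot <- md$ds$proteomes
  long <- lapply(prot, function(p) {
    x <- as.character(p)
    x[fused$sequence_id[fused$sequence_id %in% names(x)]] <-
      paste0(strrep("A", 900),
             x[fused$sequence_id[fused$sequence_id %in% names(x)]])
    Biostrings::AAStringSet(x)
  })
  expect_error(
    rebuildModels(fused, long, md$run$models[ "EF-G"], md$cfg),
    "EF-G")
})

test_that("reports carry presence counts and dual-notation strings verbatim", {
  md <- .miniDataset()
  cls <- md$run$classifications
  rep <- classificationReport(cls, reg)
  expect_identical(rep$presence$`EF-Tu`[rep$presence$taxon_id == "cyano"],
                   4L)
  expect_identical(rep$presence$cEFTu[rep$presence$taxon_id == "cyano"],
                   4L)
  expect_true(any(grepl("cEFTu(EF-Tu)", rep$perSequence$report_label,
                        fixed = TRUE)))
  # a taxon with zero classified sequences keeps its all-zero row
  extra <- cls[1, ]
  extra$taxon_id <- "emptyTaxon"
  extra$status <- "candidate-unassigned"
  extra$primary_label <- NA_character_
  rep2 <- classificationReport(rbind(cls, extra), reg)
  row <- rep2$presence[rep2$presence$taxon_id == "emptyTaxon", -1]
  expect_true(all(row == 0))
})
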