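# Distances, neighbor joining, bootstrap, clade extraction, Newick I/O.

test_that("p-distances count mismatches over comparable columns", {
  m <- Msa(c(a = "ACDE", b = "ACDF", c = "ACDE"))
  d <- pDistance(m)
  expect_identical(unname(d["a", "c"]), 0)
  expect_equal(unname(d["a", "b"]), 0.25)
  m2 <- Msa(c(a = "AC", b = "WD"))
  expect_identical(unname(pDistance(m2)["a", "b"]), 1)
  expect_error(pDistance(Msa(c(a = "A-", b = "-C"))),
               "no comparable columns")
})

test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("ape")
  set.seed(12)
  for (i in 1:25) {
    nl <- sample(5:8, 1)
    tr <- ape::rtree(nl, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
    dm <- stats::cophenetic(tr)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    est <- njTree(dm)
    expect_identical(as.numeric(ape::dist.topo(tr, est)), 0)
    got <- stats::cophenetic(est)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(got - dm)), 1e-9)
  }
})

test_that("three-taxon trees use the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njTree(dm)
  bl <- stats::setNames(t3$edge.length,
                        t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("a perfectly ultrametric star collapses its internal branches", {
  dm <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(dm) <- 0
  st <- suppressWarnings(njTree(dm))
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_true(all(abs(st$edge.length[internal]) < 1e-9))
})

test_that("degenerate distance inputs are rejected", {
  dm <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"),
                                                 c("a", "b")))
  expect_error(njTree(dm), "at least 3")
  dm3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(dm3), "asymmetric")
})

test_that("our NJ agrees with the reference implementation in ape", {
  skip_if_not_installed("ape")
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    base <- matrix(stats::runif(n * n, 0.1, 1), n)
    dm <- (base + t(base)) / 2
    dm <- dm + 0.5 * as.matrix(stats::dist(matrix(stats::rnorm(n * 3),
                                                  n)))
    diag(dm) <- 0
    dimnames(dm) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- njTree(dm)
    ref <- ape::nj(stats::as.dist(dm))
    expect_identical(as.numeric(ape::dist.topo(mine, ref)), 0)
  }
})

.separatedMsa <- function() {
  # two tight 5-leaf groups with a large between-group divergence
  withr::with_seed(7, {
    core1 <- sample(AA_ALPHABET20, 60, replace = TRUE)
    core2 <- sample(AA_ALPHABET20, 60, replace = TRUE)
    perturb <- function(core, k) {
      idx <- sample(60, k)
      core[idx] <- sample(AA_ALPHABET20, k, replace = TRUE)
      paste(core, collapse = "")
    }
    rows <- c(
      stats::setNames(vapply(1:5, function(i) perturb(core1, 3),
                             character(1)), paste0("g1_", 1:5)),
      stats::setNames(vapply(1:5, function(i) perturb(core2, 3),
                             character(1)), paste0("g2_", 1:5)))
    Msa(rows)
  })
}

test_that("bootstrap gives full support to a clean bipartition", {
  msa <- .separatedMsa()
  tr <- bootstrapSupport(msa, nReps = 30, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # find the edge separating g1 from g2
  parts <- ape::prop.part(tr)
  tipsets <- lapply(parts, function(p) sort(tr$tip.label[p]))
  g1 <- sort(paste0("g1_", 1:5))
  sep <- which(vapply(tipsets, function(s)
    identical(s, g1) || identical(s, sort(paste0("g2_", 1:5))),
    logical(1)))
  expect_true(any(sup[sep] == 100))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # reproducibility and single-replicate degeneracy
  tr2 <- bootstrapSupport(msa, nReps = 30, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  tr1 <- bootstrapSupport(msa, nReps = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("clade extraction returns maximal pure non-overlapping groups", {
  msa <- .separatedMsa()
  tree <- njTree(pDistance(msa))
  labels <- stats::setNames(rep(c("A", "B"), each = 5),
                            tree$tip.label[order(tree$tip.label)])
  labels <- labels[tree$tip.label]
  labels[] <- ifelse(grepl("^g1", names(labels)), "A", "B")
  clades <- extractClades(tree, labels, minPurity = 0.9, minSize = 3)
  expect_length(clades, 2L)
  expect_setequal(vapply(clades, `[[`, character(1), "label"),
                  c("A", "B"))
  expect_true(all(vapply(clades, `[[`, numeric(1), "purity") == 1))
  # one mislabeled leaf in a 10-leaf group passes exactly at 0.9
  labels2 <- labels
  labels2["g1_3"] <- "B"
  cl2 <- extractClades(tree, labels2, minPurity = 0.9, minSize = 3)
  pur <- vapply(cl2, `[[`, numeric(1), "purity")
  expect_true(any(abs(pur - 0.9) < 1e-9 |
                    vapply(cl2, function(x)
                      length(x$tips) == 5, logical(1))))
  # non-overlap
  tips <- unlist(lapply(cl2, `[[`, "tips"))
  expect_false(anyDuplicated(tips) > 0)
  expect_length(extractClades(tree, labels, minSize = 50), 0L)
  expect_error(extractClades(tree, labels[-1]), "unlabeled")
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  t4 <- readNewick("(A:1,B:2,(C:3,D:4):5);", text = TRUE)
  expect_identical(sort(t4$tip.label), c("A", "B", "C", "D"))
  internal <- t4$edge[, 2] > length(t4$tip.label)
  expect_equal(t4$edge.length[internal], 5)
  expect_error(readNewick("(A:1,(B:2;", text = TRUE), "malformed")
  set.seed(17)
  for (nl in c(10, 100, 500)) {
    tr <- ape::rtree(nl)
    tr$node.label <- as.character(sample(0:100, tr$Nnode,
                                         replace = TRUE))
    back <- readNewick(writeNewick(tr), text = TRUE)
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr),
                                               ape::unroot(back))), 0)
    expect_identical(back$node.label[-1], tr$node.label[-1])
    ord <- match(back$tip.label, tr$tip.label)
    d1 <- stats::cophenetic(tr)
    d2 <- stats::cophenetic(back)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-9)
  }
})
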