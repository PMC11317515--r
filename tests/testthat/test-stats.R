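# The statistical kernel against independent oracles and base R.

test_that("two-sample t-test matches the textbook formulas and base t.test", {
  a <- c(5.1, 4.9, 5.3, 5.0)
  b <- c(4.1, 4.0, 4.2, 3.9)
  got <- twoSampleTTest(a, b, equalVar = TRUE)
  exp <- oracleTTest(a, b, equalVar = TRUE)
  expect_equal(got$estimate, exp$estimate, tolerance = 1e-12)
  expect_equal(got$tStat, exp$t, tolerance = 1e-12)
  expect_equal(got$p, exp$p, tolerance = 1e-12)
  expect_equal(got$df, exp$df)

  base <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$tStat, unname(base$statistic), tolerance = 1e-12)
  expect_equal(got$p, base$p.value, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 3))
    b <- rnorm(nb, 1, sd = runif(1, 0.5, 3))
    ev <- i %% 2 == 0
    got <- twoSampleTTest(a, b, equalVar = ev)
    exp <- oracleTTest(a, b, equalVar = ev)
    expect_equal(got$tStat, exp$t, tolerance = 1e-10)
    expect_equal(got$p, exp$p, tolerance = 1e-10)
    expect_equal(got$df, exp$df, tolerance = 1e-10)
  }
})

test_that("t-test handles degenerate inputs per the contract", {
  expect_identical(twoSampleTTest(c(1, 2, 3), c(1, 2, 3))$tStat, 0)
  expect_identical(twoSampleTTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  shifted <- twoSampleTTest(c(1, 2, 3) + 0.7, c(1, 2, 3))
  expect_equal(shifted$estimate, 0.7)
  expect_gt(shifted$tStat, 0)
  expect_error(twoSampleTTest(c(2, 2, 2), c(2, 2, 2)), "zero_variance")
  expect_error(twoSampleTTest(1, c(1, 2)), ">= 2 observed")
  # sign(t) == sign(estimate) on random draws
  set.seed(1)
  for (i in 1:50) {
    r <- twoSampleTTest(rnorm(4), rnorm(4))
    expect_identical(sign(r$tStat), sign(r$estimate))
  }
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_equal(q, oracleBH(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  # NA propagation: NA p-values stay NA and do not change the others
  p <- c(0.01, NA, 0.04, 0.03)
  q <- bhAdjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[-2], p.adjust(p[-2], "BH"), tolerance = 1e-12)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric tail equals enumeration and phyper", {
  expect_equal(hypergeometricTail(0, 5, 5, 10), 1)
  expect_equal(hypergeometricTail(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeometricTail(3, 6, 7, 20), oracleHyperTail(3, 6, 7, 20),
               tolerance = 1e-12)
  # spot checks at realistic ORA scale against base phyper
  for (case in list(c(5, 40, 100, 2000), c(0, 10, 50, 500),
                    c(12, 60, 120, 1709))) {
    k <- case[1]; K <- case[2]; n <- case[3]; N <- case[4]
    expect_equal(hypergeometricTail(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometricTail(6, 5, 7, 20), "k must")
  expect_error(hypergeometricTail(1, 25, 7, 20), "exceed")
})

test_that("ORA counts overlaps definitionally and ranks a perfect hit first", {
  universe <- sprintf("G%03d", 1:200)
  sets <- GeneSetCollection(list(
    planted = universe[1:10],
    decoyA = universe[51:80],
    decoyB = universe[101:120],
    outside = paste0("X", 1:5)))
  expect_message(res <- ora(universe[1:10], universe, sets), "skipped")
  expect_false("outside" %in% res$setName)
  expect_identical(metadata(res)$skipped, "outside")
  # definitional k
  for (i in seq_len(nrow(res)))
    expect_identical(res$k[i],
                     length(intersect(universe[1:10],
                                      sets[[res$setName[i]]])))
  expect_equal(res$setName[which.min(res$pHyper)], "planted")
  expect_equal(res$pHyper[res$setName == "planted"],
               oracleHyperTail(10, 10, 10, 200), tolerance = 1e-12)
  expect_error(ora(character(0), universe, sets), "empty selection")
  expect_error(ora("Z9", universe, sets), "subset")
})

test_that("ORA p-values are calibrated under a null selection", {
  universe <- sprintf("G%04d", 1:500)
  set.seed(11)
  sets <- GeneSetCollection(setNames(
    lapply(1:20, function(i) sample(universe, 25)), paste0("s", 1:20)))
  hits <- 0; total <- 0
  for (r in 1:500) {
    sel <- sample(universe, 30)
    p <- suppressMessages(ora(sel, universe, sets)$pHyper)
    hits <- hits + sum(p <= 0.05)
    total <- total + length(p)
  }
  frac <- hits / total
  # discrete test is conservative: observed rate should not exceed nominal
  # by more than Monte-Carlo noise
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("GSEA running sum matches hand and naive-oracle computations", {
  ids <- paste0("g", 1:10)
  metric <- 10:1
  res <- prerankedGsea(ids, metric, list(top = ids[1:2]), pWeight = 0,
                       nPerm = 50, minSize = 2, seed = 1)
  expect_equal(res$es, 1.0)  # 2 x 0.5 before any miss
  expect_identical(res$leadingEdge, "g1,g2")

  set.seed(5)
  for (i in 1:100) {
    N <- sample(10:50, 1)
    ids <- paste0("g", seq_len(N))
    metric <- rnorm(N)
    size <- sample(3:min(8, N - 2), 1)
    members <- sample(ids, size)
    got <- prerankedGsea(ids, metric, list(s = members), pWeight = 0,
                         nPerm = 10, minSize = 2, seed = i)
    ranked <- ids[order(metric, decreasing = TRUE)]
    expect_equal(got$es, oracleGseaES(ranked, members), tolerance = 1e-12)
  }
})

test_that("GSEA is antisymmetric in the metric and deterministic by seed", {
  set.seed(9)
  ids <- paste0("g", 1:80)
  metric <- rnorm(80)
  sets <- list(a = sample(ids, 10), b = sample(ids, 15))
  r1 <- prerankedGsea(ids, metric, sets, nPerm = 100, seed = 3)
  r2 <- prerankedGsea(ids, -metric, sets, nPerm = 100, seed = 3)
  expect_equal(r1$es, -r2$es, tolerance = 1e-12)
  r3 <- prerankedGsea(ids, metric, sets, nPerm = 100, seed = 3)
  expect_identical(r1, r3)
  expect_error(prerankedGsea(ids, metric, sets, nPerm = 5, seed = 1),
               "nPerm")
  expect_error(prerankedGsea(c("a", "a"), c(1, 2), sets), "unique")
})

test_that("GSEA agrees with fgsea on the enrichment score", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  ids <- paste0("g", 1:300)
  metric <- rnorm(300)
  sets <- list(s1 = sample(ids, 20), s2 = sample(ids, 40))
  got <- prerankedGsea(ids, metric, sets, pWeight = 1, nPerm = 100, seed = 2)
  stats <- setNames(metric, ids)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, stats, nPermSimple = 100, scoreType = "std"))
  expect_equal(got$es[match(ref$pathway, got$setName)], ref$ES,
               tolerance = 1e-6)
})

test_that("GSEA null NES is centred near 1 with well-behaved p-values", {
  set.seed(31)
  ids <- paste0("g", 1:1000)
  nonSig <- 0
  absNes <- numeric(100)
  for (r in 1:100) {
    metric <- rnorm(1000)
    members <- sample(ids, 25)
    res <- prerankedGsea(ids, metric, list(s = members), nPerm = 200,
                         seed = r)
    nonSig <- nonSig + (res$pPerm > 0.05)
    absNes[r] <- abs(res$nes)
  }
  expect_gte(nonSig, 90)
  expect_lt(abs(mean(absNes) - 1), 0.25)
})

test_that("PCA scores behave like a centered SVD and match prcomp", {
  # rank-1: all variation along one protein-space direction
  base <- rnorm(10)
  m <- outer(rnorm(20), base)
  rownames(m) <- paste0("P", 1:20); colnames(m) <- paste0("s", 1:10)
  ev <- pcaScores(m, 2)$explainedVariance
  expect_equal(ev[1], 1, tolerance = 1e-9)

  set.seed(13)
  m <- matrix(rnorm(200, 25), 20, 10,
              dimnames = list(paste0("P", 1:20), paste0("s", 1:10)))
  s1 <- pcaScores(m, 3)
  s2 <- pcaScores(m + 5, 3)
  expect_equal(s1$scores, s2$scores, tolerance = 1e-9)

  ref <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (j in 1:3)
    expect_equal(unname(abs(s1$scores[, j])), abs(unname(ref$x[, j])),
                 tolerance = 1e-8)
  expect_equal(s1$explainedVariance,
               unname(ref$sdev^2 / sum(ref$sdev^2))[1:3], tolerance = 1e-8)

  # two clusters 10x the noise apart separate perfectly on PC1
  cl <- cbind(matrix(rnorm(100, 0, 0.5), 10, 10),
              matrix(rnorm(100, 5, 0.5), 10, 10))
  rownames(cl) <- paste0("P", 1:10)
  sc <- pcaScores(cl, 1)$scores[, 1]
  expect_identical(length(unique(sign(sc[1:10]))), 1L)
  expect_identical(unique(sign(sc[1:10])), -unique(sign(sc[11:20])))

  m[1, 1] <- NA
  expect_error(pcaScores(m, 2), "missing")
})
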