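## fixture: a colony induced at 25 min whose first division (at 20 min) is a
## testable pre-induction node; the 8 leaves carry chosen phenotype values
nodeFixture <- function(vals) {
  balancedTree(3, Td = 20, frameInt = 2, inductionTime = 25,
               fluorFun = function(i, tt) {
                 rep(if (i >= 8) vals[i - 7] else 100, length(tt))
               })
}

test_that("sister-progeny Welch test matches the textbook oracle", {
  ## identical groups: t = 0, p = 1
  tr0 <- nodeFixture(rep(7, 8))
  res0 <- nodeProgenyTest(tr0, "b001", tEnd = 75)
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$p_value, 1)
  expect_true(is.na(res0$direction))
  ## {10,11,10,11} vs {30,31,30,31}
  tr <- nodeFixture(c(10, 11, 10, 11, 30, 31, 30, 31))
  res <- nodeProgenyTest(tr, "b001", tEnd = 75)
  orc <- welchOracle(c(10, 11, 10, 11), c(30, 31, 30, 31))
  expect_lt(res$p_value, 0.01)
  expect_equal(res$t_stat, orc$t, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  ## pooled-variance variant agrees with stats::t.test var.equal
  resP <- nodeProgenyTest(tr, "b001", tEnd = 75, varEqual = TRUE)
  ref <- t.test(c(10, 11, 10, 11), c(30, 31, 30, 31), var.equal = TRUE)
  expect_equal(resP$p_value, ref$p.value, tolerance = 1e-10)
  ## a node that divided after induction is refused
  expect_error(nodeProgenyTest(tr, "b002", tEnd = 75), "after induction")
})

test_that("resampling null keeps the significant fraction near alpha", {
  ## 16 descendants (8 + 8): a rich enough pool for near-continuous p-values
  fixture16 <- function(vals) {
    balancedTree(4, Td = 20, frameInt = 2, inductionTime = 25,
                 fluorFun = function(i, tt) {
                   rep(if (i >= 16) vals[i - 15] else 100, length(tt))
                 })
  }
  set.seed(3)
  tr <- fixture16(rnorm(16, 100, 10))
  fr <- randomizedNodeTest(tr, "b001", tEnd = 95, nRand = 5000,
                           alpha = 0.05, seed = 99)
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(fr - 0.05), max(3 * se, 0.025))
  ## a huge true effect is destroyed by pooling and re-assignment
  trBig <- fixture16(rep(c(0, 1, 100, 101), each = 4)[c(1:4, 9:12, 5:8, 13:16)])
  frBig <- randomizedNodeTest(trBig, "b001", tEnd = 95, nRand = 2000,
                              alpha = 0.05, seed = 7)
  expect_lt(frBig, 0.15)
  expect_error(randomizedNodeTest(tr, "b001", 95, nRand = 0), "parameter")
})

test_that("internal fast Welch p agrees with stats::t.test", {
  set.seed(8)
  for (r in 1:50) {
    x <- rnorm(sample(3:10, 1), 0, sample(1:3, 1))
    y <- rnorm(sample(3:10, 1), 0.5, sample(1:3, 1))
    expect_equal(lineagevar:::.lv_welch_p(x, y), t.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("tree probability reproduces the combinatorial formula and binomial tail", {
  p <- treeProbability(15, 12, 0.02, "paper")
  expect_equal(p, choose(15, 12) * 0.02^12, tolerance = 1e-12)
  expect_equal(p, 1.86368e-18, tolerance = 1e-4)
  expect_equal(signif(p, 1), 2e-18)
  expect_equal(treeProbability(7, 7, 1, "paper"), 1)
  expect_equal(treeProbability(7, 7, 1, "binomial_tail"), 1)
  ## exact tail equals exhaustive enumeration over all outcomes, n <= 12
  for (n in c(4, 9, 12)) {
    for (pp in c(0.02, 0.3, 0.7)) {
      outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
      w <- apply(outcomes, 1, function(o)
        prod(ifelse(o == 1, pp, 1 - pp)))
      k <- rowSums(outcomes)
      for (ks in c(0, 2, n)) {
        expect_equal(treeProbability(n, ks, pp, "binomial_tail"),
                     sum(w[k >= ks]), tolerance = 1e-12)
      }
    }
  }
  expect_error(treeProbability(5, 6, 0.1), "domain error")
})

test_that("direction-bias binomial test matches closed forms and enumeration", {
  more <- "brighter_sister_more_stressed"
  less <- "brighter_sister_less_stressed"
  expect_equal(biasBinomialTest(rep(more, 10)), 2^-10, tolerance = 1e-12)
  ## 9 of 11: exhaustive enumeration of 2^11 equally likely outcomes
  outcomes <- as.matrix(expand.grid(rep(list(0:1), 11)))
  pEnum <- mean(rowSums(outcomes) >= 9)
  expect_equal(biasBinomialTest(c(rep(more, 9), rep(less, 2))), pEnum,
               tolerance = 1e-12)
  expect_error(biasBinomialTest(character(0)), "no direction")
})

test_that("feedback colonies carry predisposition: bright induction-time cells seed death", {
  ## cell-level mechanism, pooled over colonies
  rho <- vapply(1:6, function(s) {
    tr <- cachedSim("stressed", seed = s)
    ce <- cellTable(tr)
    leaves <- ce$cell_id[ce$end_state != "divided"]
    arr <- ce$cell_id[ce$end_state == "arrested"]
    t0 <- inductionTime(tr) + 5
    ids <- cellsAliveAt(tr, t0)
    f <- phenotypeAt(tr, t0, "fluorescence")[ids]
    frac <- vapply(ids, function(id) {
      sub <- intersect(descendantsOf(tr, id, TRUE), leaves)
      mean(sub %in% arr)
    }, numeric(1))
    suppressWarnings(cor(f, frac, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rho, na.rm = TRUE), 0.05)
  ## and some pre-induction nodes reach significance at alpha = 0.01
  nsig <- 0L
  for (s in 9:11) {
    tr <- cachedSim("stressed", seed = s)
    nt <- nodeProgenyTests(tr, max(sampleTable(tr)$time))
    nsig <- nsig + sum(nt$p_value < 0.01)
  }
  expect_gt(nsig, 0L)
})

test_that("lineage switch randomization preserves records and destroys ancestry signal", {
  tr <- cachedSim("stressed", seed = 9)
  ## zero swaps: identity
  expect_identical(cellTable(lineageSwitchRandomization(tr, 0, seed = 1)),
                   cellTable(tr))
  rt <- lineageSwitchRandomization(tr, seed = 5)
  ce0 <- cellTable(tr); ce1 <- cellTable(rt)
  ## lifetimes, per-generation counts and the measurement multiset survive
  expect_equal(sort(ce1$end_time - ce1$birth_time),
               sort(ce0$end_time - ce0$birth_time))
  expect_equal(table(generationOf(rt)), table(generationOf(tr)))
  expect_equal(sort(sampleTable(rt)$fluor_yfp),
               sort(sampleTable(tr)$fluor_yfp))
  ## IDCV is untouched at every frame; SLCV collapses toward IDCV
  times <- sort(unique(sampleTable(tr)$time))
  big <- times[vapply(times, function(t)
    length(cellsAliveAt(tr, t)) >= 8, logical(1))]
  probe <- big[round(seq(1, length(big), length.out = 5))]
  for (t in probe) {
    expect_equal(idcv(phenotypeAt(rt, t, "fluorescence")),
                 idcv(phenotypeAt(tr, t, "fluorescence")), tolerance = 1e-12)
  }
  tEnd <- max(times); s8 <- firstTimeAtSize(tr, 8)
  ratio0 <- slcv(tr, s8, tEnd) / idcv(phenotypeAt(tr, tEnd, "fluorescence"))
  ratio1 <- slcv(rt, s8, tEnd) / idcv(phenotypeAt(rt, tEnd, "fluorescence"))
  expect_gt(ratio0, 2)
  expect_lt(ratio1, ratio0 / 2)
  expect_lt(ratio1, 2)
  ## randomization requires an induction time
  trNull <- balancedTree(2)
  expect_error(lineageSwitchRandomization(trNull, 5, seed = 1),
               "induction")
})
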