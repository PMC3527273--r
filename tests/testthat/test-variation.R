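test_that("idcv matches hand values and the lognormal closed form", {
  expect_equal(idcv(rep(5, 10)), 0)
  expect_equal(idcv(c(1, 2, 3)), 0.5)                 # sd 1, mean 2
  set.seed(11)
  x <- rlnorm(1e4, meanlog = 0, sdlog = 0.4)
  expect_equal(idcv(x), sqrt(exp(0.4^2) - 1), tolerance = 0.02)
  expect_error(idcv(c(3)), "sample-size")
  expect_error(idcv(c(-2, -1, 3)), "domain error")
})

## a depth-2 balanced fixture whose 4 leaves carry chosen values, grouped by
## their generation-1 ancestors
slcvFixture <- function(vals) {
  balancedTree(2, fluorFun = function(i, tt) {
    rep(if (i >= 4) vals[i - 3] else 100, length(tt))
  })
}

test_that("slcv detects sub-lineage differentiation and reduces to idcv at s = t", {
  ## groups {1,1} vs {3,3}: SLCV 1.0, IDCV sqrt(4/3)/2
  tr <- slcvFixture(c(1, 1, 3, 3))
  sl <- slcv(tr, s = 25, t = 45)       # ancestors = the 2 gen-1 cells
  expect_equal(sl, 1.0, tolerance = 1e-12)
  iv <- idcv(phenotypeAt(tr, 45, "fluorescence"))
  expect_equal(iv, sqrt(4 / 3) / 2, tolerance = 1e-12)
  expect_gt(sl, iv)                     # differentiation flag
  ## s = t: every group a singleton, SLCV == IDCV exactly
  expect_equal(slcv(tr, 45, 45), iv, tolerance = 1e-12)
})

test_that("slcv(s = t) equals idcv exactly on 100 random fixtures", {
  set.seed(21)
  for (r in 1:100) {
    depth <- sample(2:3, 1)
    vals <- rlnorm(2^depth, meanlog = log(100), sdlog = 0.5)
    tr <- balancedTree(depth, fluorFun = function(i, tt) {
      rep(if (i >= 2^depth) vals[i - 2^depth + 1] else 100, length(tt))
    })
    t0 <- depth * 20 + 5
    expect_equal(slcv(tr, t0, t0),
                 idcv(phenotypeAt(tr, t0, "fluorescence")),
                 tolerance = 1e-12)
  }
})

test_that("slcv ignores within-group labels; idcv ignores group structure", {
  vals <- c(2, 8, 5, 5)
  tr1 <- slcvFixture(vals)
  tr2 <- slcvFixture(vals[c(2, 1, 4, 3)])   # permute within each sister pair
  expect_equal(slcv(tr1, 25, 45), slcv(tr2, 25, 45), tolerance = 1e-12)
  tr3 <- slcvFixture(vals[c(3, 2, 1, 4)])   # values moved across groups
  expect_equal(idcv(phenotypeAt(tr1, 45, "fluorescence")),
               idcv(phenotypeAt(tr3, 45, "fluorescence")),
               tolerance = 1e-12)
})

test_that("random grouping of i.i.d. phenotypes gives no SLCV excess", {
  ## paired comparison of the squared statistics: the between-group mean
  ## square and the all-cell variance both estimate sigma^2 under the null
  set.seed(31)
  R <- 600
  d <- vapply(seq_len(R), function(r) {
    x <- rlnorm(32, log(100), 0.3)
    grp <- sample(rep(1:8, each = 4))
    means <- tapply(x, grp, mean)
    msb <- sum(4 * (means - mean(x))^2) / 7
    (msb - var(x)) / mean(x)^2
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(R))
})

test_that("variation curves: null colonies track, stressed colonies diverge", {
  nulls <- lapply(1:3, function(s) cachedSim("null", seed = s))
  cv <- suppressWarnings(variationCurves(nulls, nsList = c(8, 16)))
  post <- cv[!is.na(cv$slcv) & !is.na(cv$idcv) & cv$n_t >= 16, ]
  ## no differentiation: SLCV and IDCV indistinguishable on average
  expect_gt(nrow(post), 20)
  expect_equal(mean(post$slcv) / mean(post$idcv), 1, tolerance = 0.25)
  ## stressed colony: SLCV/IDCV ratio grows after induction
  tr <- cachedSim("stressed", seed = 9)
  tEnd <- max(sampleTable(tr)$time)
  s8 <- firstTimeAtSize(tr, 8)
  ratioEnd <- slcv(tr, s8, tEnd) / idcv(phenotypeAt(tr, tEnd, "fluorescence"))
  early <- inductionTime(tr) + 10
  ratioEarly <- slcv(tr, s8, early) /
    idcv(phenotypeAt(tr, early, "fluorescence"))
  expect_gt(ratioEnd, ratioEarly)
  expect_gt(ratioEnd, 1.5)
  ## colony never reaching N_s is dropped with a warning
  expect_warning(variationCurves(nulls[[1]], nsList = c(8, 10000)),
                 "never reaches")
})

test_that("growth-expression correlation: exact affine case and stressed sign", {
  tr <- cachedSim("stressed", seed = 9)
  res <- phenotypeGrowthCorrelation(tr, inductionTime(tr) + 130)
  expect_lt(res$spearman, -0.3)   # stressed cells are bright and slow
  expect_lt(res$pearson, 0)
  ## affine intensity = a + b * growth rate gives |r| = 1
  tr0 <- cachedSim("null", seed = 42, maxColonySize = 24)
  t0 <- max(sampleTable(tr0)$time) - 5
  k <- phenotypeAt(tr0, t0, "growth_rate")
  sa <- sampleTable(tr0)
  keep <- !is.na(k)
  for (id in names(k)[keep]) {
    rows <- sa$cell_id == id
    sa$fluor_yfp[rows] <- 1000 - 5000 * k[id]
  }
  tr0@samples <- sa
  res0 <- phenotypeGrowthCorrelation(tr0, t0)
  expect_equal(res0$pearson, -1, tolerance = 1e-9)
})
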