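test_that("unstressed deterministic dynamics relax to the expression fixed point", {
  p <- simParams(DOut = 0, noise = 0, stressBasal = 0)
  kmax <- log(2) / p$doublingTime
  st <- list(length = 2, D = 0, S = 0, F = 0, F2 = 0)
  for (i in 1:4000) st <- stepCell(st, p, 0.15)
  expect_equal(st$F, p$exprBasal / kmax, tolerance = 1e-3)
  expect_equal(st$S, 0)
  expect_error(stepCell(st, p, 10), "frame interval")
})

test_that("coarse integration tracks a 100x finer reference without feedback", {
  p <- simParams(DOut = 0.2, feedbackGain = 0, noise = 0,
                 stressGain = 0.05)
  run <- function(dt, tmax = 12) {
    st <- list(length = 2, D = 0.1, S = 0.05, F = 100, F2 = 0)
    for (i in seq_len(round(tmax / dt))) {
      st <- stepCell(st, p, dt, DOut = p$DOut)
    }
    st
  }
  coarse <- run(0.15)
  fine <- run(0.0015)
  for (fld in c("D", "S", "F", "length")) {
    expect_equal(coarse[[fld]], fine[[fld]], tolerance = 1e-3)
  }
})

test_that("division conserves molecule contents exactly", {
  p <- simParams(seed = 1)
  set.seed(42)
  for (r in 1:100) {
    st <- list(length = runif(1, 2, 6), D = runif(1, 0, 2),
               S = runif(1, 0, 1), F = runif(1, 10, 500), F2 = runif(1, 0, 50))
    dl <- divideCell(st, p)
    L1 <- dl[[1]]$length; L2 <- dl[[2]]$length
    expect_equal(L1 + L2, st$length, tolerance = 1e-12)
    for (fld in c("D", "S", "F", "F2")) {
      sc <- if (fld %in% c("D", "S")) p$moleculeScaleStress
            else p$moleculeScaleExpr
      got <- dl[[1]][[fld]] * L1 * sc + dl[[2]][[fld]] * L2 * sc
      expect_equal(got, round(st[[fld]] * st$length * sc), tolerance = 1e-9)
    }
  }
  ## deterministic even split
  pd <- simParams(partitionCV = 0, deterministicPartition = 1)
  st <- list(length = 4, D = 1, S = 0.5, F = 100, F2 = 0)
  dl <- divideCell(st, pd)
  expect_equal(dl[[1]]$F, dl[[2]]$F, tolerance = 1e-12)
  expect_equal(dl[[1]]$length, 2)
})

test_that("binomial partitioning has the n q (1 - q) count variance", {
  p <- simParams(partitionCV = 0)    # q = 0.5 exactly
  st <- list(length = 4, D = 0, S = 0, F = 100, F2 = 0)
  n <- round(100 * 4 * p$moleculeScaleExpr)
  set.seed(13)
  counts <- vapply(1:8000, function(i) {
    dl <- divideCell(st, p)
    dl[[1]]$F * dl[[1]]$length * p$moleculeScaleExpr
  }, numeric(1))
  expect_equal(mean(counts), n / 2, tolerance = 0.005)
  expect_equal(var(counts), n * 0.25, tolerance = 0.1)
})

test_that("the noiseless limit grows a perfectly regular balanced colony", {
  tr <- simulateTree(simPreset("null", noise = 0, partitionCV = 0,
                               lengthNoise = 0, maxColonySize = 32,
                               seed = 1))
  ce <- cellTable(tr)
  iv <- ce$end_time[ce$end_state == "divided"] -
    ce$birth_time[ce$end_state == "divided"]
  ## interdivision = doubling time, up to one integration substep
  expect_lt(max(abs(iv - 23)), 0.16)
  gen <- generationOf(tr)
  expect_equal(sort(as.integer(table(gen))), c(1L, 2L, 4L, 8L, 16L, 32L))
  k <- phenotypeAt(tr, 50, "growth_rate")
  expect_equal(unname(k[!is.na(k)]),
               rep(log(2) / 23, sum(!is.na(k))), tolerance = 1e-4)
})

test_that("with noise the mean interdivision time stays near the doubling time", {
  ivs <- unlist(lapply(1:20, function(s) {
    tr <- cachedSim("null", seed = 300 + s, maxColonySize = 64)
    ce <- cellTable(tr)
    ce$end_time[ce$end_state == "divided"] -
      ce$birth_time[ce$end_state == "divided"]
  }))
  expect_equal(mean(ivs), 23, tolerance = 0.05)
})

test_that("identical seeds give bit-identical colonies; different seeds differ", {
  a <- simulateTree(simPreset("null", maxColonySize = 24, seed = 5))
  b <- simulateTree(simPreset("null", maxColonySize = 24, seed = 5))
  expect_identical(cellTable(a), cellTable(b))
  expect_identical(sampleTable(a), sampleTable(b))
  d <- simulateTree(simPreset("null", maxColonySize = 24, seed = 6))
  expect_false(identical(sampleTable(a), sampleTable(d)))
})

test_that("stressed colonies die in clusters with bimodal growth", {
  tr <- cachedSim("stressed", seed = 9)
  ce <- cellTable(tr)
  expect_gt(sum(ce$end_state == "arrested"), 0)
  ## growth rates at +130 min: a slow sub-population below half k_max
  k <- phenotypeAt(tr, inductionTime(tr) + 130, "growth_rate")
  k <- k[!is.na(k)]
  expect_gt(mean(k < 0.015), 0.02)
  expect_gt(mean(k > 0.02), 0.3)
  ## arrested cells cluster within sub-lineages: an arrested cell's sister
  ## subtree is enriched for arrest relative to the colony average
  arr <- ce$cell_id[ce$end_state == "arrested"]
  base <- length(arr) / sum(ce$end_state != "divided")
  sibArr <- c()
  for (id in arr) {
    par <- ce$parent_id[ce$cell_id == id]
    if (is.na(par)) next
    sib <- setdiff(ce$cell_id[!is.na(ce$parent_id) & ce$parent_id == par], id)
    leaves <- intersect(descendantsOf(tr, sib, TRUE),
                        ce$cell_id[ce$end_state != "divided"])
    if (length(leaves)) sibArr <- c(sibArr, mean(leaves %in% arr))
  }
  expect_gt(mean(sibArr), base)
})

test_that("co-reporter correlates with the stress reporter only through the feedback", {
  rs <- vapply(1:2, function(s) {
    tr <- cachedSim("stressed_coreporter", seed = s)
    tE <- max(sampleTable(tr)$time)
    cor(phenotypeAt(tr, tE, "fluorescence", channel = "fluor_yfp"),
        phenotypeAt(tr, tE, "fluorescence", channel = "fluor_tet"))
  }, numeric(1))
  expect_true(all(rs > 0.2))
  r0 <- vapply(1:2, function(s) {
    tr <- cachedSim("stressed_coreporter", seed = s, feedbackGain = 0)
    tE <- max(sampleTable(tr)$time)
    cor(phenotypeAt(tr, tE, "fluorescence", channel = "fluor_yfp"),
        phenotypeAt(tr, tE, "fluorescence", channel = "fluor_tet"))
  }, numeric(1))
  expect_true(all(abs(r0) < 0.1))
})

test_that("moment matching adjusts the induced expression to a doubled mean", {
  over <- list(maxColonySize = 48, tMax = 200)
  p0 <- do.call(simPreset, c(list("stressed", seed = 1), over))
  measure <- function(p) {
    vals <- unlist(lapply(1:3, function(i) {
      pr <- p@params; pr$seed <- i
      tr <- suppressWarnings(simulateTree(methods::new("SimParams",
                                                       params = pr)))
      unname(phenotypeAt(tr, max(sampleTable(tr)$time), "fluorescence"))
    }))
    c(mean(vals), var(vals))
  }
  m0 <- measure(p0)
  ## already-achieved targets: zero iterations, parameters unchanged
  fitSame <- fitMoments(m0[1], m0[2], p0, nTrees = 3, seed = 1)
  expect_equal(fitSame$iterations, 0L)
  expect_equal(fitSame$params@params, p0@params)
  ## doubled mean with the induced production free
  fit2 <- fitMoments(2 * m0[1], m0[2], p0, freeNames = "exprInduced",
                     nTrees = 3, seed = 1)
  expect_equal(fit2$achievedMean, 2 * m0[1], tolerance = 0.05)
  expect_gt(fit2$params$exprInduced, p0$exprInduced)
  ## infeasible target
  expect_error(fitMoments(100, 0, p0), "fit error")
})
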