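## Programmatic fixtures: no data files, everything built in code.

## Balanced binary lineage forest in heap indexing (cell i has children 2i,
## 2i+1), one division every `Td` minutes, frames every `frameInt` minutes.
## `fluorFun(i, times)` supplies the fluor_yfp samples of cell i.
balancedTree <- function(depth, Td = 20, frameInt = 2,
                         fluorFun = function(i, times) rep(100, length(times)),
                         lengthRate = log(2) / Td, inductionTime = NA) {
  n <- 2^(depth + 1) - 1
  ids <- sprintf("b%03d", seq_len(n))
  gen <- floor(log2(seq_len(n)))
  birth <- gen * Td
  end <- (gen + 1) * Td
  state <- ifelse(gen < depth, "divided", "censored")
  pidx <- seq_len(n) %/% 2L
  parent <- ifelse(pidx == 0L, NA_character_, ids[pmax(pidx, 1L)])
  cells <- data.frame(cell_id = ids, parent_id = parent,
                      birth_time = birth, end_time = end,
                      end_state = state, stringsAsFactors = FALSE)
  samp <- lapply(seq_len(n), function(i) {
    tt <- seq(birth[i], end[i] - if (state[i] == "divided") frameInt else 0,
              by = frameInt)
    data.frame(cell_id = ids[i], time = tt,
               length = 1.0 * exp(lengthRate * (tt - birth[i])),
               x = 0, y = 0, fluor_yfp = fluorFun(i, tt),
               stringsAsFactors = FALSE)
  })
  lineageTree(cells, do.call(rbind, samp), inductionTime = inductionTime,
              frameInterval = frameInt, colonyId = "fixture")
}

## hand-built 3-generation unbalanced tree:
## f divides at 10 into a, b; b divides at 20 into ba, bb; a, ba, bb leaves
threeGenTree <- function() {
  cells <- data.frame(
    cell_id = c("f", "a", "b", "ba", "bb"),
    parent_id = c(NA, "f", "f", "b", "b"),
    birth_time = c(0, 10, 10, 20, 20),
    end_time = c(10, 30, 20, 30, 30),
    end_state = c("divided", "censored", "divided", "censored", "censored"),
    stringsAsFactors = FALSE)
  samp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    tt <- seq(cells$birth_time[i], cells$end_time[i] - 2, by = 2)
    data.frame(cell_id = cells$cell_id[i], time = tt,
               length = exp(0.03 * (tt - cells$birth_time[i])),
               x = 0, y = 0, fluor_yfp = 100 + i,
               stringsAsFactors = FALSE)
  }))
  lineageTree(cells, samp, frameInterval = 2)
}

## textbook Welch two-sample test (statistic, df, two-sided p)
welchOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

## textbook Pearson correlation from raw sums
pearsonOracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

## brute-force lineage AF: explicit pair enumeration by parent-walking
afOracle <- function(tree, s, g, channel = "fluor_yfp") {
  ce <- cellTable(tree)
  times <- sort(unique(sampleTable(tree)$time))
  times <- times[times >= s - 1e-9]
  stage <- vapply(times, function(t)
    floor(log2(length(cellsAliveAt(tree, t)))), numeric(1))
  tg <- times[which(stage >= stage[1] + g)[1]]
  if (is.na(tg)) return(NULL)
  sa <- sampleTable(tree)
  val <- function(id, t) {
    rows <- sa[sa$cell_id == id, ]
    rows[[channel]][which.min(abs(rows$time - t))]
  }
  xs <- c(); ys <- c()
  for (d in cellsAliveAt(tree, tg)) {
    a <- d
    i <- match(a, ce$cell_id)
    while (ce$birth_time[i] > s + 1e-9) {
      a <- ce$parent_id[i]
      i <- match(a, ce$cell_id)
    }
    xs <- c(xs, val(a, s)); ys <- c(ys, val(d, tg))
  }
  list(af = pearsonOracle(xs, ys), n = length(xs), t = tg)
}

firstTimeAtSize <- function(tree, n) {
  times <- sort(unique(sampleTable(tree)$time))
  times[which(vapply(times, function(t)
    length(cellsAliveAt(tree, t)) >= n, logical(1)))[1]]
}

afStartStage <- function(tree, offset) {
  ind <- inductionTime(tree)
  target <- colonyStageGeneration(tree, ind) + offset
  times <- sort(unique(sampleTable(tree)$time))
  times[which(vapply(times, function(t)
    length(cellsAliveAt(tree, t)) >= 2^target, logical(1)))[1]]
}

simCache <- new.env(parent = emptyenv())

## simulate once per (preset, seed, ...) per test run
cachedSim <- function(preset, seed, ...) {
  key <- paste(preset, seed, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (is.null(simCache[[key]])) {
    simCache[[key]] <- suppressWarnings(
      simulateTree(simPreset(preset, seed = seed, ...)))
  }
  simCache[[key]]
}
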