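#' @include fate.R
NULL

#' Sister-progeny phenotype test at a pre-induction division node
#'
#' For a mother cell that divided before stress induction, compares the
#' phenotype values (at \code{tEnd}) of the two sisters' descendant groups
#' with a two-sample t-test (Welch by default; the pooled-variance version is
#' available via \code{varEqual}). When the difference is significant at
#' \code{alpha}, the direction records whether the sister that was brighter
#' at the division gave rise to the more stressed descendant group (higher
#' fluorescence, or lower growth rate for the growth phenotype).
#'
#' No multiple-testing correction is applied across nodes; combine nodes with
#' \code{\link{treeProbability}} and \code{\link{biasBinomialTest}}.
#'
#' @param tree a \linkS4class{LineageTree} with \code{inductionTime} set
#' @param nodeId the dividing mother's cell id
#' @param tEnd comparison time, minutes (typically the end of the record)
#' @param phenotype,channel,window passed to \code{\link{phenotypeAt}}
#' @param alpha significance level (default 0.01)
#' @param varEqual pooled-variance t-test instead of Welch
#' @return one-row data.frame: \code{node_id}, \code{t_stat}, \code{p_value},
#'   \code{n1}, \code{n2}, \code{direction} (NA unless \code{p < alpha}),
#'   \code{rand_sig_fraction} (NA; see \code{\link{randomizedNodeTest}})
#' @export
nodeProgenyTest <- function(tree, nodeId, tEnd, phenotype = "fluorescence",
                            channel = NULL, window = 5L, alpha = 0.01,
                            varEqual = FALSE) {
  gr <- .lv_node_groups(tree, nodeId, tEnd, phenotype, channel, window)
  if (length(gr$g1) < 2L || length(gr$g2) < 2L) {
    .lv_stop("degenerate group: each sister needs >= 2 descendants at tEnd")
  }
  if (stats::sd(gr$g1) == 0 && stats::sd(gr$g2) == 0) {
    if (mean(gr$g1) == mean(gr$g2)) {
      return(data.frame(node_id = nodeId, t_stat = 0, p_value = 1,
                        n1 = length(gr$g1), n2 = length(gr$g2),
                        direction = NA_character_,
                        rand_sig_fraction = NA_real_))
    }
    .lv_stop("degenerate group: zero variance in both descendant groups")
  }
  tt <- stats::t.test(gr$g1, gr$g2, var.equal = varEqual)
  direction <- NA_character_
  if (tt$p.value < alpha) {
    stressed1 <- if (phenotype == "growth_rate") {
      mean(gr$g1) < mean(gr$g2)   # slower growth = more stressed
    } else {
      mean(gr$g1) > mean(gr$g2)   # brighter reporter = more stressed
    }
    brighter1 <- gr$birthF[1] > gr$birthF[2]
    direction <- if (stressed1 == brighter1) {
      "brighter_sister_more_stressed"
    } else {
      "brighter_sister_less_stressed"
    }
  }
  data.frame(node_id = nodeId, t_stat = unname(tt$statistic),
             p_value = tt$p.value, n1 = length(gr$g1), n2 = length(gr$g2),
             direction = direction, rand_sig_fraction = NA_real_)
}

## descendant phenotype groups of the two sisters + sisters' own birth
## fluorescence
.lv_node_groups <- function(tree, nodeId, tEnd, phenotype, channel, window) {
  ce <- cellTable(tree)
  i <- match(nodeId, ce$cell_id)
  if (is.na(i)) .lv_stop("unknown node id: %s", nodeId)
  if (ce$end_state[i] != "divided") .lv_stop("node %s never divided", nodeId)
  if (!is.na(inductionTime(tree)) &&
      ce$end_time[i] > inductionTime(tree) + 1e-9) {
    .lv_stop("node %s divided after induction; only pre-induction nodes are tested",
             nodeId)
  }
  sisters <- ce$cell_id[!is.na(ce$parent_id) & ce$parent_id == nodeId]
  x <- phenotypeAt(tree, tEnd, phenotype, channel, window)
  x <- x[!is.na(x)]
  anc <- .lv_ancestors_at(tree, names(x), ce$end_time[i] + 1e-6)
  ## map each measured cell to whichever sister's subtree it sits in
  side <- rep(NA_integer_, length(x))
  for (k in seq_along(sisters)) {
    sub <- descendantsOf(tree, sisters[k], includeSelf = TRUE)
    side[anc %in% sisters[k] | names(x) %in% sub] <- k
  }
  sa <- sampleTable(tree)
  channel2 <- .lv_channel(tree, channel)
  ## each sister's own brightness: mean intensity over its lifetime, which
  ## integrates the damage load it inherited at the division under test
  birthF <- vapply(sisters, function(id) {
    rows <- sa[sa$cell_id == id, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    mean(rows[[channel2]], na.rm = TRUE)
  }, numeric(1))
  list(g1 = unname(x[which(side == 1L)]), g2 = unname(x[which(side == 2L)]),
       sisters = sisters, birthF = birthF)
}

#' Eligible pre-induction division nodes
#'
#' Division nodes whose mother ended before stress induction and whose two
#' sisters each contribute at least \code{minPerGroup} measured descendants
#' at \code{tEnd}.
#'
#' @inheritParams nodeProgenyTest
#' @param minPerGroup minimum descendants per sister group (default 2)
#' @return character vector of node ids
#' @export
preInductionNodes <- function(tree, tEnd, phenotype = "fluorescence",
                              channel = NULL, window = 5L, minPerGroup = 2L) {
  ce <- cellTable(tree)
  ind <- inductionTime(tree)
  if (is.na(ind)) .lv_stop("tree has no induction time set")
  cand <- ce$cell_id[ce$end_state == "divided" & ce$end_time <= ind + 1e-9]
  keep <- vapply(cand, function(id) {
    gr <- tryCatch(.lv_node_groups(tree, id, tEnd, phenotype, channel,
                                   window),
                   error = function(e) NULL)
    !is.null(gr) && length(gr$g1) >= minPerGroup &&
      length(gr$g2) >= minPerGroup
  }, logical(1))
  cand[keep]
}

#' Run sister-progeny tests at every eligible pre-induction node
#'
#' @inheritParams nodeProgenyTest
#' @return data.frame, one row per node (see \code{\link{nodeProgenyTest}})
#' @export
nodeProgenyTests <- function(tree, tEnd, phenotype = "fluorescence",
                             channel = NULL, window = 5L, alpha = 0.01,
                             varEqual = FALSE) {
  nodes <- preInductionNodes(tree, tEnd, phenotype, channel, window)
  if (length(nodes) == 0L) {
    return(data.frame(node_id = character(), t_stat = numeric(),
                      p_value = numeric(), n1 = integer(), n2 = integer(),
                      direction = character(),
                      rand_sig_fraction = numeric()))
  }
  out <- do.call(rbind, lapply(nodes, function(id) {
    nodeProgenyTest(tree, id, tEnd, phenotype, channel, window, alpha,
                    varEqual)
  }))
  rownames(out) <- NULL
  out
}

## closed-form Welch two-sample p-value (two-sided); fast path for resampling
.lv_welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Resampling null for a sister-progeny test
#'
#' Pools the two sisters' descendant values and, \code{nRand} times, splits
#' the pool at random into groups of the original sizes (without
#' replacement), recording the fraction of splits whose Welch test is
#' significant at \code{alpha}. Random re-assignment destroys any lineage
#' effect, so on any data the fraction converges to \code{alpha} as
#' \code{nRand} grows; a real tree whose observed test is significant while
#' the resampled fraction stays near \code{alpha} carries a genuine
#' sub-lineage difference.
#'
#' @inheritParams nodeProgenyTest
#' @param nRand number of random re-assignments (default 500)
#' @param seed integer seed for reproducibility (optional)
#' @return fraction of significant splits, in [0, 1]
#' @export
randomizedNodeTest <- function(tree, nodeId, tEnd,
                               phenotype = "fluorescence", channel = NULL,
                               window = 5L, nRand = 500L, alpha = 0.01,
                               seed = NULL) {
  if (nRand < 1L) .lv_stop("parameter error: nRand must be >= 1")
  gr <- .lv_node_groups(tree, nodeId, tEnd, phenotype, channel, window)
  if (length(gr$g1) < 2L || length(gr$g2) < 2L) {
    .lv_stop("degenerate group: each sister needs >= 2 descendants at tEnd")
  }
  pool <- c(gr$g1, gr$g2)
  n <- length(pool); n1 <- length(gr$g1)
  .lv_with_seed(seed, {
    hits <- 0L
    for (r in seq_len(nRand)) {
      idx <- sample.int(n, n1)
      if (.lv_welch_p(pool[idx], pool[-idx]) < alpha) hits <- hits + 1L
    }
    hits / nRand
  })
}

#' Probability of a tree's significant-node count arising by chance
#'
#' With \code{nNodes} independent node tests, each significant with
#' probability \code{pNode} under the null, the chance of observing
#' \code{nSig} significant nodes. \code{mode = "paper"} is the literal
#' combinatorial product \eqn{C(n, k) p^k} (the omitted \eqn{(1-p)^{n-k}}
#' factor is negligible at small \code{p}); \code{mode = "binomial_tail"} is
#' the exact tail \eqn{P[X \ge k]}, \eqn{X \sim Binom(n, p)}.
#'
#' @param nNodes number of tested nodes
#' @param nSig number of significant nodes observed
#' @param pNode per-node null significance probability
#' @param mode \code{"paper"} or \code{"binomial_tail"}
#' @return probability
#' @examples
#' treeProbability(15, 12, 0.02)                    # ~1.9e-18
#' treeProbability(15, 12, 0.02, "binomial_tail")
#' @export
treeProbability <- function(nNodes, nSig, pNode,
                            mode = c("paper", "binomial_tail")) {
  mode <- match.arg(mode)
  if (nSig < 0 || nSig > nNodes) .lv_stop("domain error: need 0 <= nSig <= nNodes")
  if (pNode < 0 || pNode > 1) .lv_stop("domain error: need 0 <= pNode <= 1")
  if (mode == "paper") {
    choose(nNodes, nSig) * pNode^nSig
  } else {
    stats::pbinom(nSig - 1, nNodes, pNode, lower.tail = FALSE)
  }
}

#' Direction-bias exact binomial test
#'
#' Tests whether significant sister-progeny events share a direction more
#' often than a fair coin: by default one-sided for an excess of
#' \code{"brighter_sister_more_stressed"} events (the directional hypothesis
#' that the sister with higher basal reporter activity seeds the more
#' stressed sub-lineage).
#'
#' @param directions character vector of per-node directions (values
#'   \code{"brighter_sister_more_stressed"} /
#'   \code{"brighter_sister_less_stressed"}; NAs dropped)
#' @param alternative \code{"greater"} (one-sided, default) or
#'   \code{"two.sided"}
#' @return p-value
#' @export
biasBinomialTest <- function(directions,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  directions <- directions[!is.na(directions)]
  if (length(directions) == 0L) .lv_stop("no direction events supplied")
  k <- sum(directions == "brighter_sister_more_stressed")
  stats::binom.test(k, length(directions), p = 0.5,
                    alternative = alternative)$p.value
}

#' Same-generation lineage switch randomization
#'
#' Destroys lineage structure while preserving every measurement: repeatedly
#' draws two distinct post-induction cells of the same lineage generation and
#' swaps the subtrees rooted at them (each cell keeps its own descendants and
#' its own record; only the attachment to the tree changes). Per-generation
#' cell counts, all lifetimes and the full multiset of per-frame measurements
#' are unchanged, so IDCV at every time point is invariant; SLCV of a
#' genuinely differentiated colony collapses onto IDCV because ancestry no
#' longer predicts phenotype. \code{mode = "values"} instead swaps the two
#' cells' measured length/fluorescence values frame-by-frame (truncated to
#' the shorter record), leaving the topology untouched.
#'
#' Because same-generation cells are born at slightly different times, the
#' subtree mode necessarily relaxes the child-birth == parent-end identity;
#' the returned tree is flagged \code{randomized} and ancestor lookups walk
#' by birth time.
#'
#' @param tree a \linkS4class{LineageTree} with \code{inductionTime} set
#' @param nPairs number of swaps; default = final population size (enough
#'   for thorough mixing)
#' @param seed integer seed (optional)
#' @param mode \code{"subtree"} (default) or \code{"values"}
#' @return a randomized \linkS4class{LineageTree}
#' @export
lineageSwitchRandomization <- function(tree, nPairs = NULL, seed = NULL,
                                       mode = c("subtree", "values")) {
  mode <- match.arg(mode)
  ind <- inductionTime(tree)
  if (is.na(ind)) .lv_stop("randomization error: induction time not set")
  ce <- cellTable(tree)
  if (is.null(nPairs)) {
    nPairs <- length(cellsAliveAt(tree, max(ce$end_time)))
  }
  if (nPairs == 0L) return(tree)
  gen <- generationOf(tree)
  eligible <- ce$cell_id[ce$birth_time > ind + 1e-9]
  bygen <- split(eligible, gen[eligible])
  bygen <- bygen[lengths(bygen) >= 2L]
  if (length(bygen) == 0L) {
    .lv_stop("randomization error: no same-generation pair of post-induction cells")
  }
  wt <- vapply(bygen, function(g) choose(length(g), 2), numeric(1))
  sa <- tree@samples
  .lv_with_seed(seed, {
    for (r in seq_len(nPairs)) {
      g <- bygen[[sample.int(length(bygen), 1L, prob = wt)]]
      pair <- sample(g, 2L)
      i <- match(pair[1], ce$cell_id); j <- match(pair[2], ce$cell_id)
      if (mode == "subtree") {
        tmp <- ce$parent_id[i]
        ce$parent_id[i] <- ce$parent_id[j]
        ce$parent_id[j] <- tmp
      } else {
        ri <- which(sa$cell_id == pair[1])
        rj <- which(sa$cell_id == pair[2])
        m <- min(length(ri), length(rj))
        cols <- c("length", grep("^fluor_", names(sa), value = TRUE))
        tmp <- sa[ri[seq_len(m)], cols]
        sa[ri[seq_len(m)], cols] <- sa[rj[seq_len(m)], cols]
        sa[rj[seq_len(m)], cols] <- tmp
      }
    }
    lineageTree(ce, sa, inductionTime = ind,
                frameInterval = frameInterval(tree),
                colonyId = paste0(tree@colonyId, "_rand"),
                randomized = (mode == "subtree"))
  })
}
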