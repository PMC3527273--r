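#' @include predisposition.R
NULL

#' Within-lineage phenotype autocorrelation
#'
#' Quantifies non-genetic memory: how long a cell's phenotype predicts its
#' descendants'. Starting from time \code{s}, for each number of colony-stage
#' generations \code{g} elapsed (stage = floor(log2(population size))), every
#' cell alive when the colony has advanced \code{g} stages is paired with its
#' ancestor alive at \code{s}, and AF(g) is the Pearson correlation over
#' pairs between the ancestor's phenotype at \code{s} and the descendant's
#' phenotype at the later frame. Pairs are weighted equally
#' (descendant-weighted); \code{ancestorWeighted = TRUE} averages descendant
#' values within each ancestor first. Points with fewer than \code{minPairs}
#' pairs are omitted (small samples make the correlation estimate fluctuate
#' wildly).
#'
#' For a stable reporter with constant stochastic production and no feedback,
#' AF decays as \code{2^-g}: a half-life of one generation, set by dilution
#' at division. Positive feedback slows the decay; see
#' \code{\link{linearModelHalflife}}.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param s start time, minutes
#' @param phenotype,channel,window passed to \code{\link{phenotypeAt}}
#' @param minPairs minimum pairs per reported point (default 16)
#' @param maxG largest g to attempt (default: all reachable)
#' @return an \linkS4class{AFCurve}
#' @export
lineageAF <- function(tree, s, phenotype = "fluorescence", channel = NULL,
                      window = 5L, minPairs = 16L, maxG = Inf) {
  ## snap the start point to the sampling grid so the g = 0 pairs compare a
  ## cell with itself at the same frame
  allTimes <- sort(unique(sampleTable(tree)$time))
  s <- allTimes[which.min(abs(allTimes - s))]
  startIds <- cellsAliveAt(tree, s)
  if (length(startIds) < minPairs) {
    .lv_stop("only %d cells alive at s = %g; need >= minPairs = %d",
             length(startIds), s, minPairs)
  }
  x0 <- phenotypeAt(tree, s, phenotype, channel, window)
  times <- sort(unique(sampleTable(tree)$time))
  times <- times[times >= s - 1e-9]
  stage <- vapply(times, function(t)
    as.integer(floor(log2(length(cellsAliveAt(tree, t))))), integer(1))
  g0 <- stage[1]
  pts <- list()
  for (g in 0:min(maxG, max(stage) - g0)) {
    i <- which(stage >= g0 + g)[1]
    if (is.na(i)) break
    tg <- times[i]
    ids <- cellsAliveAt(tree, tg)
    anc <- .lv_ancestors_at(tree, ids, s)
    xv <- x0[anc]
    yv <- phenotypeAt(tree, tg, phenotype, channel, window)[ids]
    keep <- !is.na(xv) & !is.na(yv)
    npairs <- sum(keep)
    if (npairs < minPairs) next
    if (stats::sd(xv[keep]) == 0 || stats::sd(yv[keep]) == 0) {
      .lv_stop("undefined-correlation error: zero variance at g = %d", g)
    }
    pts[[length(pts) + 1L]] <- data.frame(
      g = g, t = tg, af = stats::cor(xv[keep], yv[keep]),
      n_pairs = npairs)
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(g = integer(), t = numeric(), af = numeric(),
               n_pairs = integer())
  methods::new("AFCurve", startTime = s, phenotype = phenotype,
               points = points, halflife = NA_real_)
}

#' @rdname afPoints
#' @param x an \linkS4class{AFCurve}
#' @export
setMethod("afPoints", "AFCurve", function(x) x@points)

#' Accessors for AFCurve objects
#'
#' \code{afPoints} returns the (g, t, af, n_pairs) table; \code{afHalflife}
#' the fitted half-life in generations (NA before fitting).
#' @name afPoints
#' @aliases afHalflife
#' @export
setMethod("afHalflife", "AFCurve", function(x) x@halflife)

#' Exponential half-life of an autocorrelation curve
#'
#' Least-squares slope of \code{log2(AF)} against generations, using only
#' points with \code{AF > floor} (near-zero or negative correlations carry no
#' information about the decay rate and would wreck the log). The half-life
#' is \code{-1/slope} in generations; multiply by the doubling time for
#' minutes.
#'
#' @param afCurve an \linkS4class{AFCurve}, or a data.frame with columns
#'   \code{g} and \code{af}
#' @param floor smallest usable AF value (default 0.1)
#' @return half-life in generations
#' @export
fitHalflife <- function(afCurve, floor = 0.1) {
  pts <- if (methods::is(afCurve, "AFCurve")) afPoints(afCurve) else afCurve
  use <- pts[!is.na(pts$af) & pts$af > floor, , drop = FALSE]
  if (nrow(use) < 3L) {
    .lv_stop("fit error: need >= 3 points with AF > %g, have %d",
             floor, nrow(use))
  }
  g <- use$g; y <- log2(use$af)
  slope <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  if (slope >= 0) .lv_stop("fit error: non-decaying autocorrelation (slope %.3g)",
                           slope)
  -1 / slope
}

#' Autocorrelation half-life predicted by the linear birth-dilution model
#'
#' For a gene product produced at a constant rate, diluted by growth (rate
#' \code{ln2 / doublingTime}), degraded at an extra rate \code{extraDecay}
#' and amplified by an effective linear feedback gain \code{feedbackGain},
#' the lineage autocorrelation decays as \code{exp(-gamma * t)} with
#' effective relaxation rate \code{gamma = ln2/doublingTime + extraDecay -
#' feedbackGain}. The half-life is \code{ln2 / gamma} minutes. In the
#' simplest case (stable product, no feedback) this equals the doubling time
#' exactly: one generation. As the feedback gain approaches the total decay
#' rate the half-life diverges - memory never decays.
#'
#' @param doublingTime cell doubling time, minutes
#' @param extraDecay active degradation rate, 1/min (default 0)
#' @param feedbackGain linearized positive-feedback gain, 1/min (default 0)
#' @return half-life in minutes
#' @examples
#' linearModelHalflife(23)               # 23 min: one generation
#' linearModelHalflife(23, log(2) / 23)  # degradation equal to dilution
#' @export
linearModelHalflife <- function(doublingTime, extraDecay = 0,
                                feedbackGain = 0) {
  gamma <- log(2) / doublingTime + extraDecay - feedbackGain
  if (gamma <= 0) {
    .lv_stop("divergence error: effective relaxation rate %.3g <= 0 (memory never decays)",
             gamma)
  }
  log(2) / gamma
}

#' Export an AF curve as TSV
#'
#' Writes (s, g, t, af, n_pairs) rows plus a trailing comment line with the
#' fitted half-life when available.
#'
#' @param afCurve an \linkS4class{AFCurve}
#' @param path output path
#' @param halflife optional half-life (generations) to record
#' @return \code{path}, invisibly
#' @export
writeAFCurve <- function(afCurve, path, halflife = afHalflife(afCurve)) {
  pts <- afPoints(afCurve)
  out <- cbind(s = afCurve@startTime, phenotype = afCurve@phenotype, pts)
  con <- file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.na(halflife)) {
    writeLines(sprintf("#halflife_generations\t%s", .lv_num(halflife)), con)
  }
  invisible(path)
}
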