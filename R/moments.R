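#' @include simulate.R
NULL

#' Match simulated reporter moments to targets
#'
#' Coordinate-descent moment matching: adjusts the named free parameters so
#' that the simulated population mean and variance of the reporter F (over
#' cells at the end of each colony record) hit the targets. Mean-type
#' parameters (\code{exprInduced}, \code{exprBasal}) are updated
#' multiplicatively toward the target mean, the noise amplitude toward the
#' target variance; every iteration re-simulates with the same seeds (common
#' random numbers), so the objective is smooth in the parameters.
#'
#' @param targetMean,targetVar target population mean and variance of F
#' @param params starting \linkS4class{SimParams}; its \code{seed} (or
#'   \code{seed}) fixes the simulation seeds
#' @param freeNames parameters to adjust; supported: \code{"exprInduced"} or
#'   \code{"exprBasal"} (drives the mean) and \code{"noise"} (drives the
#'   variance). Default \code{c("exprInduced", "noise")}.
#' @param nTrees colonies per evaluation (default 3)
#' @param tol relative tolerance on both moments (default 0.05)
#' @param maxIter iteration cap (default 25)
#' @param seed overrides \code{params$seed} for the evaluation seeds
#' @return list with \code{params} (updated \linkS4class{SimParams}),
#'   \code{achievedMean}, \code{achievedVar}, \code{iterations},
#'   \code{trace} (data.frame of the search path)
#' @export
fitMoments <- function(targetMean, targetVar, params,
                       freeNames = c("exprInduced", "noise"),
                       nTrees = 3L, tol = 0.05, maxIter = 25L,
                       seed = NULL) {
  meanKnobs <- intersect(freeNames, c("exprInduced", "exprBasal"))
  varKnobs <- intersect(freeNames, "noise")
  bad <- setdiff(freeNames, c("exprInduced", "exprBasal", "noise"))
  if (length(bad)) .lv_stop("unsupported free parameter(s): %s",
                            paste(bad, collapse = ", "))
  if (targetMean <= 0 || targetVar <= 0) {
    .lv_stop("fit error: targets must be positive (variance 0 is infeasible under the noise floor)")
  }
  baseSeed <- if (!is.null(seed)) seed
              else if (!is.na(params$seed)) params$seed else 1
  measure <- function(p) {
    vals <- unlist(lapply(seq_len(nTrees), function(i) {
      pr <- p@params; pr$seed <- baseSeed + i - 1
      tr <- suppressWarnings(
        simulateTree(methods::new("SimParams", params = pr)))
      tEnd <- max(sampleTable(tr)$time)
      unname(phenotypeAt(tr, tEnd, "fluorescence"))
    }))
    c(mean = mean(vals, na.rm = TRUE), var = stats::var(vals, na.rm = TRUE))
  }
  p <- params
  trace <- list()
  for (it in 0:maxIter) {
    mo <- measure(p)
    trace[[it + 1L]] <- data.frame(
      iteration = it, mean = mo["mean"], var = mo["var"],
      t(unlist(p@params[freeNames])))
    okMean <- abs(mo["mean"] - targetMean) <= tol * targetMean ||
      length(meanKnobs) == 0L
    okVar <- abs(mo["var"] - targetVar) <= tol * targetVar ||
      length(varKnobs) == 0L
    if (okMean && okVar) {
      return(list(params = p, achievedMean = unname(mo["mean"]),
                  achievedVar = unname(mo["var"]), iterations = it,
                  trace = do.call(rbind, trace)))
    }
    pr <- p@params
    if (length(meanKnobs) && !okMean) {
      ratio <- max(min(targetMean / mo["mean"], 4), 0.25)
      pr[[meanKnobs[1]]] <- pr[[meanKnobs[1]]] * ratio
    }
    if (length(varKnobs) && !okVar) {
      ratio <- max(min(sqrt(targetVar / mo["var"]), 3), 1 / 3)
      pr$noise <- pr$noise * ratio
    }
    p <- methods::new("SimParams", params = pr)
  }
  tr <- do.call(rbind, trace)
  .lv_stop(paste0("fit error: no convergence after %d iterations ",
                  "(last mean %.4g vs %.4g, var %.4g vs %.4g)"),
           maxIter, tr$mean[nrow(tr)], targetMean, tr$var[nrow(tr)],
           targetVar)
}
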