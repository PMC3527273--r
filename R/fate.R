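#' @include variation.R
NULL

#' Classify cells as live or dead from growth-rate bimodality
#'
#' Under sustained sub-inhibitory antibiotic stress the single-cell growth
#' rate distribution becomes bimodal: a near-arrested, death-prone mode and a
#' growing mode. The threshold separating them is either the equal-posterior
#' point of a two-component Gaussian mixture fitted to growth rates at
#' \code{t} (\code{method = "gmm"}) or a user-supplied constant
#' (\code{method = "manual"}). A cell is called dead when its growth rate
#' stays below the threshold for at least \code{minArrest} minutes through
#' the end of its terminal descendants' records (prolonged growth arrest);
#' the onset of that terminal arrest is returned as the commitment time.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param t time (minutes) whose growth-rate distribution sets the threshold
#' @param method \code{"gmm"} or \code{"manual"}
#' @param threshold growth-rate cut in 1/min, required for \code{"manual"}
#' @param minArrest minimum arrest duration in minutes (default 60)
#' @param window growth-rate estimation window (frames)
#' @return data.frame with columns \code{cell_id}, \code{fate} ("live" or
#'   "dead"), \code{threshold}, \code{commitment_time} (NA for live cells),
#'   one row per cell alive at \code{t}
#' @export
classifyFate <- function(tree, t, method = c("gmm", "manual"),
                         threshold = NULL, minArrest = 60, window = 5L) {
  method <- match.arg(method)
  if (method == "gmm") {
    rates <- phenotypeAt(tree, t, "growth_rate", window = window)
    rates <- rates[!is.na(rates)]
    if (length(rates) < 4L) .lv_stop("need >= 4 growth-rate values at t")
    threshold <- gmmThreshold(rates)
  } else if (is.null(threshold)) {
    .lv_stop("method 'manual' requires a threshold")
  }
  ids <- cellsAliveAt(tree, t)
  arrested <- .lv_arrested_leaves(tree, threshold, minArrest, window)
  ce <- cellTable(tree)
  leaves <- ce$cell_id[ce$end_state != "divided"]
  res <- lapply(ids, function(id) {
    sub <- intersect(descendantsOf(tree, id, includeSelf = TRUE), leaves)
    dead <- length(sub) > 0L && all(sub %in% names(arrested))
    data.frame(cell_id = id, fate = if (dead) "dead" else "live",
               threshold = threshold,
               commitment_time = if (dead) min(arrested[sub]) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Equal-posterior threshold of a two-component Gaussian mixture
#'
#' Fits a two-component unequal-variance Gaussian mixture and returns the
#' point between the component means where the posterior membership
#' probabilities are equal. Errors when the fitted components are not
#' separated (means closer than the pooled standard deviation), in which case
#' a manual threshold is required.
#'
#' @param x numeric values (e.g. growth rates in 1/min)
#' @return the threshold, same units as \code{x}
#' @export
gmmThreshold <- function(x) {
  fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) .lv_stop("mixture fit failed; supply a manual threshold")
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  pro <- fit$parameters$pro
  if (abs(diff(mu)) < sqrt(mean(sig^2))) {
    .lv_stop(paste("unimodal data: mixture means are closer than the pooled",
                   "component SD; use method = 'manual' with an explicit",
                   "threshold"))
  }
  post_diff <- function(z) {
    pro[1] * stats::dnorm(z, mu[1], sig[1]) -
      pro[2] * stats::dnorm(z, mu[2], sig[2])
  }
  lo <- min(mu); hi <- max(mu)
  ## equal posterior between the two means; fall back to midpoint if the
  ## densities do not cross there (extreme weight imbalance)
  thr <- if (post_diff(lo) * post_diff(hi) < 0) {
    stats::uniroot(post_diff, c(lo, hi), tol = 1e-12)$root
  } else {
    mean(mu)
  }
  ## the threshold must sit in a genuine antimode: the fitted mixture
  ## density has to dip between the component means, otherwise the sample
  ## is unimodal and the split is an artifact of forcing two components
  dens <- function(z) {
    pro[1] * stats::dnorm(z, mu[1], sig[1]) +
      pro[2] * stats::dnorm(z, mu[2], sig[2])
  }
  if (dens(thr) >= 0.9 * min(dens(mu[1]), dens(mu[2]))) {
    .lv_stop(paste("unimodal data: no density antimode between the fitted",
                   "means; use method = 'manual' with an explicit threshold"))
  }
  thr
}

## For each leaf: start time of a terminal below-threshold stretch of length
## >= minArrest (following the growth-rate series through the leaf and its
## sampled record); named vector, only leaves that qualify.
.lv_arrested_leaves <- function(tree, threshold, minArrest, window) {
  ce <- cellTable(tree)
  leaves <- ce$cell_id[ce$end_state != "divided"]
  out <- numeric(0)
  for (id in leaves) {
    ser <- .lv_lineage_rate_series(tree, id, window)
    if (nrow(ser) == 0L) next
    below <- ser$value < threshold
    if (!length(below) || !below[length(below)]) next
    runstart <- length(below)
    while (runstart > 1L && below[runstart - 1L]) runstart <- runstart - 1L
    dur <- ser$time[length(below)] - ser$time[runstart]
    if (dur >= minArrest) out[id] <- ser$time[runstart]
  }
  out
}

## growth-rate series along the ancestor chain ending in `id`, concatenated in
## time; lets a short-lived leaf inherit its mother's terminal arrest.
.lv_lineage_rate_series <- function(tree, id, window) {
  ce <- cellTable(tree)
  chain <- id
  repeat {
    p <- ce$parent_id[match(chain[1], ce$cell_id)]
    if (is.na(p)) break
    chain <- c(p, chain)
  }
  parts <- lapply(chain, function(cid) {
    tryCatch(growthRateSeries(tree, cid, window), error = function(e) NULL)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(data.frame(time = numeric(), value = numeric()))
  do.call(rbind, parts)
}

#' Commitment times of death-fated subtrees
#'
#' For each maximal all-dead subtree (the latest common ancestor whose
#' descendants all die), returns the birth time of its root: the moment the
#' lineage committed to death, which may precede the actual growth arrest by
#' generations.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param fateCalls data.frame from \code{\link{classifyFate}} evaluated at
#'   the end of the record, or any table with \code{cell_id} and \code{fate}
#' @return named numeric vector: root cell id -> birth time (minutes); empty
#'   when no cell dies
#' @export
deathCommitmentTime <- function(tree, fateCalls) {
  ce <- cellTable(tree)
  dead_leaves <- fateCalls$cell_id[fateCalls$fate == "dead"]
  dead_leaves <- intersect(dead_leaves, ce$cell_id[ce$end_state != "divided"])
  if (length(dead_leaves) == 0L) return(stats::setNames(numeric(0),
                                                        character(0)))
  leaves <- ce$cell_id[ce$end_state != "divided"]
  allDead <- vapply(ce$cell_id, function(id) {
    sub <- intersect(descendantsOf(tree, id, includeSelf = TRUE), leaves)
    length(sub) > 0L && all(sub %in% dead_leaves)
  }, logical(1))
  ## maximal: all-dead cell whose parent is not all-dead
  pidx <- match(ce$parent_id, ce$cell_id)
  maximal <- allDead & (is.na(pidx) | !allDead[pidx])
  stats::setNames(ce$birth_time[maximal], ce$cell_id[maximal])
}
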