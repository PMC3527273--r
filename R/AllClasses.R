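#' @include AllGenerics.R
NULL

## Central container: a micro-colony lineage forest rooted at a single founder.
## `cells` has one row per cell (identity, parentage, lifetime, terminal state);
## `samples` has one row per cell per frame (time, length, centroid, fluorescence
## channels). Division instants belong to both the mother (end) and daughters
## (birth). `randomized` marks trees produced by the same-generation lineage
## switch randomization, whose reattached subtrees are exempt from the
## child-birth == parent-end check (all other invariants still hold).

#' LineageTree: a micro-colony lineage forest
#'
#' S4 container for a single micro-colony grown from one founder cell, holding
#' per-cell records (identity, parentage, birth/end times in minutes, terminal
#' state) and per-frame measurements (length in micrometres, centroid in
#' pixels, fluorescence channels in arbitrary units).
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{parent_id}
#'   (\code{NA} for the founder), \code{birth_time}, \code{end_time},
#'   \code{end_state} (one of \code{"divided"}, \code{"arrested"},
#'   \code{"censored"}).
#' @slot samples data.frame with columns \code{cell_id}, \code{time},
#'   \code{length}, \code{x}, \code{y} and one or more \code{fluor_*} columns.
#' @slot founderId character scalar, the founder's \code{cell_id}.
#' @slot inductionTime numeric scalar, minutes at which the stress medium was
#'   switched in; \code{NA} if never.
#' @slot frameInterval numeric scalar, minutes between frames.
#' @slot colonyId character scalar label.
#' @slot randomized logical; \code{TRUE} for trees whose ancestry has been
#'   scrambled by \code{\link{lineageSwitchRandomization}}.
#'
#' @seealso \code{\link{lineageTree}}, \code{\link{readTrackingTable}},
#'   \code{\link{simulateTree}}
#' @export
setClass("LineageTree",
  representation(
    cells = "data.frame",
    samples = "data.frame",
    founderId = "character",
    inductionTime = "numeric",
    frameInterval = "numeric",
    colonyId = "character",
    randomized = "logical"
  ),
  prototype(
    inductionTime = NA_real_,
    frameInterval = 1.5,
    colonyId = "colony1",
    randomized = FALSE
  )
)

setValidity("LineageTree", function(object) {
  ce <- object@cells
  sa <- object@samples
  msg <- character()
  need <- c("cell_id", "parent_id", "birth_time", "end_time", "end_state")
  if (!all(need %in% names(ce))) {
    return(paste("cells is missing columns:",
                 paste(setdiff(need, names(ce)), collapse = ", ")))
  }
  sneed <- c("cell_id", "time", "length", "x", "y")
  if (!all(sneed %in% names(sa))) {
    return(paste("samples is missing columns:",
                 paste(setdiff(sneed, names(sa)), collapse = ", ")))
  }
  if (anyDuplicated(ce$cell_id)) msg <- c(msg, "duplicated cell_id")
  founders <- ce$cell_id[is.na(ce$parent_id)]
  if (length(founders) != 1L) {
    msg <- c(msg, sprintf("exactly one founder required, found %d",
                          length(founders)))
  } else if (!identical(object@founderId, founders)) {
    msg <- c(msg, "founderId does not match the parentless cell")
  }
  known <- ce$parent_id %in% ce$cell_id | is.na(ce$parent_id)
  if (!all(known)) {
    msg <- c(msg, sprintf("orphan parent_id for cell(s): %s",
                          paste(ce$cell_id[!known], collapse = ", ")))
  }
  if (any(ce$birth_time >= ce$end_time)) {
    msg <- c(msg, "birth_time must precede end_time for every cell")
  }
  if (!all(ce$end_state %in% c("divided", "arrested", "censored"))) {
    msg <- c(msg, "end_state must be divided/arrested/censored")
  }
  ## children bookkeeping
  if (length(msg) == 0L && all(known)) {
    kids <- table(factor(ce$parent_id[!is.na(ce$parent_id)],
                         levels = ce$cell_id))
    nk <- as.integer(kids)
    div <- ce$end_state == "divided"
    if (any(nk[div] != 2L)) {
      msg <- c(msg, "every divided cell must have exactly 2 children")
    }
    if (any(nk[!div] != 0L)) {
      msg <- c(msg, "arrested/censored cells must have 0 children")
    }
    if (!object@randomized) {
      idx <- match(ce$parent_id, ce$cell_id)
      has <- !is.na(idx)
      if (any(abs(ce$birth_time[has] - ce$end_time[idx[has]]) > 1e-9)) {
        msg <- c(msg, "children birth_time must equal the parent's end_time")
      }
    }
    ## acyclicity: walking up parents must terminate at the founder
    depth <- .lv_depths(ce$cell_id, ce$parent_id)
    if (anyNA(depth)) msg <- c(msg, "parent-child graph is not a tree")
  }
  if (!all(sa$cell_id %in% ce$cell_id)) {
    msg <- c(msg, "samples refer to unknown cell_id")
  }
  if (any(sa$length <= 0, na.rm = TRUE)) msg <- c(msg, "length must be > 0")
  fl <- grep("^fluor_", names(sa), value = TRUE)
  for (ch in fl) {
    if (any(sa[[ch]] < 0, na.rm = TRUE)) {
      msg <- c(msg, sprintf("%s has negative intensities", ch))
    }
  }
  ## per-cell sample times: strictly increasing, within [birth, end]
  ord <- order(match(sa$cell_id, ce$cell_id), sa$time)
  st <- sa$time[ord]
  sid <- sa$cell_id[ord]
  same <- sid[-1L] == sid[-length(sid)]
  if (length(st) > 1L && any(diff(st)[same] <= 0)) {
    msg <- c(msg, "sample times must be strictly increasing within a cell")
  }
  ii <- match(sa$cell_id, ce$cell_id)
  if (any(sa$time < ce$birth_time[ii] - 1e-9 |
          sa$time > ce$end_time[ii] + 1e-9)) {
    msg <- c(msg, "sample times must lie within [birth_time, end_time]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' AFCurve: lineage autocorrelation versus generations elapsed
#'
#' Result container for \code{\link{lineageAF}}: the correlation between a
#' cell's phenotype at a start time and its descendants' phenotype after the
#' colony has advanced by \code{g} colony-stage generations.
#'
#' @slot startTime numeric, start time s in minutes.
#' @slot phenotype character, which phenotype was correlated.
#' @slot points data.frame with columns \code{g} (generations elapsed),
#'   \code{t} (minutes), \code{af} (Pearson correlation), \code{n_pairs}.
#' @slot halflife numeric, fitted exponential half-life in generations
#'   (\code{NA} until \code{\link{fitHalflife}} is called).
#' @export
setClass("AFCurve",
  representation(
    startTime = "numeric",
    phenotype = "character",
    points = "data.frame",
    halflife = "numeric"
  ),
  prototype(halflife = NA_real_)
)

setValidity("AFCurve", function(object) {
  p <- object@points
  if (!all(c("g", "t", "af", "n_pairs") %in% names(p))) {
    return("points must have columns g, t, af, n_pairs")
  }
  if (nrow(p) && any(p$n_pairs < 2L)) return("every point needs n_pairs >= 2")
  if (nrow(p) && any(p$g == 0) && abs(p$af[p$g == 0] - 1) > 1e-12) {
    return("af at g = 0 must be 1")
  }
  TRUE
})

#' SimParams: stochastic lineage simulator parameters
#'
#' Validated parameter set for \code{\link{simulateTree}}. Construct with
#' \code{\link{simParams}} or \code{\link{simPreset}}; read entries with
#' \code{$} or \code{[[}.
#'
#' @seealso \code{\link{simParams}} for the meaning, units and defaults of
#'   every entry.
#' @export
setClass("SimParams", representation(params = "list"))

setValidity("SimParams", function(object) {
  p <- object@params
  miss <- setdiff(.lv_param_names(), names(p))
  if (length(miss)) return(paste("missing parameters:",
                                 paste(miss, collapse = ", ")))
  chk <- setdiff(.lv_param_names(), "seed")
  num <- vapply(p[chk], function(x)
    is.numeric(x) && length(x) == 1L && !is.na(x), logical(1))
  if (!all(num)) return("all parameters must be finite numeric scalars")
  if (p$doublingTime <= 0) return("doublingTime must be > 0")
  if (p$frameInterval <= 0) return("frameInterval must be > 0")
  if (p$partitionCV < 0 || p$partitionCV >= 1) {
    return("partitionCV must be in [0, 1)")
  }
  rates <- c("DOut", "AOut", "uptakeBase", "feedbackGain", "stressGain",
             "stressBasal", "stressDecay", "exprBasal", "exprInduced",
             "inductionK", "hillH", "exprGrowthCoupling", "growthK",
             "hillM", "noise", "lengthNoise", "fluorSaturation",
             "moleculeScaleStress", "moleculeScaleExpr", "deathRateFloor",
             "arrestDuration", "tailMinutes")
  if (any(unlist(p[rates]) < 0)) return("rates and gains must be >= 0")
  TRUE
})

#' @describeIn SimParams extract a parameter by name
#' @param x SimParams object
#' @param name parameter name
#' @export
setMethod("$", "SimParams", function(x, name) x@params[[name]])

#' @describeIn SimParams extract a parameter by name
#' @param i parameter name or index
#' @export
setMethod("[[", "SimParams", function(x, i) x@params[[i]])

setMethod("show", "SimParams", function(object) {
  p <- object@params
  cat("SimParams (stochastic lineage simulator)\n")
  cat(sprintf("  doubling time %g min, frames every %g min, induction at %d cells\n",
              p$doublingTime, p$frameInterval, as.integer(p$inductionColonySize)))
  cat(sprintf("  drug outside %g, uptake %g/min, feedback gain %g, stress gain %g\n",
              p$DOut, p$uptakeBase, p$feedbackGain, p$stressGain))
  cat(sprintf("  expression basal %g, induced %g (K = %g, h = %g), noise %g\n",
              p$exprBasal, p$exprInduced, p$inductionK, p$hillH, p$noise))
  cat(sprintf("  growth inhibition K_g = %g (m = %g); death floor %g/min for %g min\n",
              p$growthK, p$hillM, p$deathRateFloor, p$arrestDuration))
  cat(sprintf("  partition CV %g, molecule scales %g (stress) / %g (reporter)\n",
              p$partitionCV, p$moleculeScaleStress, p$moleculeScaleExpr))
  cat(sprintf("  stop at %d cells or %g min; seed %s\n",
              as.integer(p$maxColonySize), p$tMax,
              if (is.na(p$seed)) "unset" else format(p$seed)))
  invisible(object)
})

setMethod("show", "LineageTree", function(object) {
  ce <- object@cells
  cat(sprintf("LineageTree '%s': %d cells, %d frames of samples\n",
              object@colonyId, nrow(ce), length(unique(object@samples$time))))
  cat(sprintf("  founder %s; span %g-%g min; frame interval %g min\n",
              object@founderId, min(ce$birth_time), max(ce$end_time),
              object@frameInterval))
  cat(sprintf("  induction: %s; end states: %s%s\n",
              if (is.na(object@inductionTime)) "none"
              else paste0(object@inductionTime, " min"),
              paste(sprintf("%d %s", as.integer(table(ce$end_state)),
                            names(table(ce$end_state))), collapse = ", "),
              if (object@randomized) "; ancestry randomized" else ""))
  ch <- grep("^fluor_", names(object@samples), value = TRUE)
  if (length(ch)) cat(sprintf("  channels: %s\n", paste(ch, collapse = ", ")))
  invisible(object)
})

setMethod("show", "AFCurve", function(object) {
  cat(sprintf("AFCurve (%s) from s = %g min: %d points\n",
              object@phenotype, object@startTime, nrow(object@points)))
  if (nrow(object@points)) {
    print(object@points, row.names = FALSE)
  }
  if (!is.na(object@halflife)) {
    cat(sprintf("  fitted half-life: %.3f generations\n", object@halflife))
  }
  invisible(object)
})
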