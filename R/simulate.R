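#' @include sim-params.R
NULL

## growth rate under damage inhibition
.lv_k_of_S <- function(S, p) {
  (log(2) / p$doublingTime) / (1 + (S / p$growthK)^p$hillM)
}

#' One Euler-Maruyama step of the single-cell model
#'
#' Advances one or more cell states by \code{dt} minutes:
#' \deqn{dD/dt = u_0 (1 + \beta S) D_{out} - k D}
#' \deqn{dS/dt = \sigma_s D k + s_0 - (k + d_S) S}
#' \deqn{dF/dt = \alpha_0 + \alpha_1 S^h / (K^h + S^h) - k F + \eta \sqrt{F}\,\xi(t)}
#' \deqn{dF_2/dt = u_0 (1 + \beta S) A_{out} - k F_2}
#' \deqn{k = k_{max} / (1 + (S/K_g)^m), \quad k_{max} = \ln 2 / T_d}
#' \deqn{dL/dt = k L}
#' Drug uptake rises with damage (permeability positive feedback); damage is
#' produced in proportion to drug times translation (which scales with
#' growth), diluted by growth and optionally repaired at rate \eqn{d_S}
#' (chaperone/protease clearance); the reporter is damage-induced with
#' multiplicative noise (\eqn{\xi} white, variance \eqn{1/dt}); growth is
#' damage-inhibited; the optional co-reporter F2 accumulates a passive
#' external inducer through the same permeability. Any component driven
#' negative by the noise is clamped to 0 (counted in the \code{"clamped"}
#' attribute).
#'
#' @param state list of numeric vectors \code{length}, \code{D}, \code{S},
#'   \code{F}, \code{F2} (aligned; one element per cell)
#' @param params a \linkS4class{SimParams}
#' @param dt step size, minutes (at most the frame interval)
#' @param DOut,AOut effective external concentrations (default: the values
#'   in \code{params}; \code{\link{simulateTree}} switches them on at
#'   induction)
#' @return the advanced state, with attribute \code{"clamped"} = number of
#'   clamped components
#' @export
stepCell <- function(state, params, dt, DOut = params$DOut,
                     AOut = params$AOut) {
  if (dt > params$frameInterval + 1e-12) {
    .lv_stop("dt must not exceed the frame interval")
  }
  p <- params
  k <- .lv_k_of_S(state$S, p)
  uptake <- p$uptakeBase * (1 + p$feedbackGain * state$S)
  hill <- state$S^p$hillH / (p$inductionK^p$hillH + state$S^p$hillH)
  n <- length(state$S)
  kmax <- log(2) / p$doublingTime
  ## optional translation coupling: production scales with growth, so
  ## promoter activity collapses in growth-arrested cells
  prodScale <- if (p$exprGrowthCoupling > 0) {
    (k / kmax)^p$exprGrowthCoupling
  } else 1
  D <- state$D + dt * (uptake * DOut - k * state$D)
  S <- state$S + dt * (p$stressGain * state$D * k + p$stressBasal -
                         (k + p$stressDecay) * state$S)
  Fv <- state$F +
    dt * ((p$exprBasal + p$exprInduced * hill) * prodScale - k * state$F) +
    p$noise * sqrt(pmax(state$F, 0) * dt) * stats::rnorm(n)
  F2 <- state$F2 + dt * (uptake * AOut - k * state$F2)
  clamped <- sum(D < 0) + sum(S < 0) + sum(Fv < 0) + sum(F2 < 0)
  out <- list(length = state$length * exp(k * dt),
              D = pmax(D, 0), S = pmax(S, 0), F = pmax(Fv, 0),
              F2 = pmax(F2, 0))
  attr(out, "clamped") <- clamped
  attr(out, "k") <- k
  out
}

#' Divide a single cell state into two daughters
#'
#' The mother's volume (length) is split at a fraction
#' \code{q ~ Normal(0.5, partitionCV/2)} truncated to (0.2, 0.8); her
#' molecule contents (concentration times length, converted to integer copy
#' numbers at the configured molecule scales) are partitioned binomially
#' with success probability \code{q}, so the daughters' contents always sum
#' exactly to the mother's. Asymmetric segregation of the damage species S
#' at division is one of the stochastic seeds of later fate divergence.
#'
#' @param state single-cell state: list with scalar \code{length}, \code{D},
#'   \code{S}, \code{F}, \code{F2}
#' @param params a \linkS4class{SimParams}
#' @return list of two daughter states (each with \code{length},
#'   concentrations, and \code{q} recording the volume fraction)
#' @export
divideCell <- function(state, params) {
  p <- params
  q <- 0.5
  if (p$partitionCV > 0) {
    repeat {
      q <- stats::rnorm(1, 0.5, p$partitionCV / 2)
      if (q > 0.2 && q < 0.8) break
    }
  }
  L <- state$length
  L1 <- q * L; L2 <- (1 - q) * L
  split1 <- function(conc, scale) {
    n <- round(conc * L * scale)
    n1 <- if (p$deterministicPartition > 0) round(n * q)
          else stats::rbinom(1, n, q)
    c(n1, n - n1) / scale
  }
  dD <- split1(state$D, p$moleculeScaleStress)
  dS <- split1(state$S, p$moleculeScaleStress)
  dF <- split1(state$F, p$moleculeScaleExpr)
  dF2 <- split1(state$F2, p$moleculeScaleExpr)
  list(
    list(length = L1, D = dD[1] / L1, S = dS[1] / L1, F = dF[1] / L1,
         F2 = dF2[1] / L1, q = q),
    list(length = L2, D = dD[2] / L2, S = dS[2] / L2, F = dF[2] / L2,
         F2 = dF2[2] / L2, q = q))
}

#' Simulate a micro-colony lineage tree
#'
#' Grows a micro-colony from a single founder under the stochastic
#' positive-feedback model, switching the external drug (and co-inducer) on
#' when the colony reaches \code{inductionColonySize} cells, and stopping at
#' \code{maxColonySize} cells or \code{tMax} minutes. Cells whose growth
#' rate stays below \code{deathRateFloor} for \code{arrestDuration} minutes
#' are marked arrested (prolonged growth arrest = death); they stop dividing
#' but remain in the colony record to the end, as dead cells do in
#' micro-colony images. Integration uses \code{frameInterval/10} steps with
#' division checked every substep. Identical parameters and seed give
#' bit-identical trees.
#'
#' Cell centroids emulate colony packing only crudely (daughters placed
#' beside the mother, with a global rescale keeping the cell density
#' constant); they support border-distance controls, not mechanics.
#'
#' @param params a \linkS4class{SimParams} (see \code{\link{simPreset}})
#' @param colonyId label for the colony (default "sim1")
#' @return a \linkS4class{LineageTree} with channel \code{fluor_yfp} (and
#'   \code{fluor_tet} when the co-reporter is enabled)
#' @examples
#' tr <- simulateTree(simPreset("null", maxColonySize = 16, seed = 1))
#' tr
#' @export
simulateTree <- function(params, colonyId = "sim1") {
  p <- params
  seed <- p$seed
  .lv_with_seed(if (is.na(seed)) NULL else seed,
                .lv_simulate_impl(p, colonyId))
}

.lv_simulate_impl <- function(p, colonyId) {
  kmax <- log(2) / p$doublingTime
  dt <- p$frameInterval / 10
  nsub <- 10L
  ## registry over all cells ever created
  N <- 0L
  parent <- integer(); birthT <- numeric(); endT <- numeric()
  endState <- character(); birthLen <- numeric()
  newCell <- function(par, t, len) {
    N <<- N + 1L
    parent[N] <<- par; birthT[N] <<- t; endT[N] <<- NA_real_
    endState[N] <<- NA_character_; birthLen[N] <<- len
    N
  }
  ## founder: basal steady state
  Sb <- p$stressBasal / kmax
  f0 <- newCell(0L, 0, 2.0)
  idx <- f0
  st <- list(length = 2.0, D = 0, S = Sb,
             F = (p$exprBasal + p$exprInduced *
                    Sb^p$hillH / (p$inductionK^p$hillH + Sb^p$hillH)) / kmax,
             F2 = 0)
  px <- 0; py <- 0
  arrested <- FALSE; aclock <- 0
  indTime <- NA_real_
  clamped <- 0L

  sampL <- list(); nframe <- 0L
  ## measured intensity: soft detector/reporter saturation when configured
  msr <- function(f) {
    if (p$fluorSaturation > 0) p$fluorSaturation * f / (p$fluorSaturation + f)
    else f
  }
  record <- function(t) {
    nframe <<- nframe + 1L
    mlen <- st$length *
      if (p$lengthNoise > 0) exp(p$lengthNoise * stats::rnorm(length(idx)))
      else 1
    sampL[[nframe]] <<- list(cell = idx, time = rep(t, length(idx)),
                             len = mlen, x = px, y = py, f = msr(st$F),
                             f2 = msr(st$F2))
  }
  relax <- function() {
    n <- length(px)
    if (n < 2L) return()
    cx <- mean(px); cy <- mean(py)
    r <- sqrt((px - cx)^2 + (py - cy)^2)
    rms <- sqrt(mean(r^2))
    if (rms > 0) {
      target <- 5.6 * sqrt(n)
      px <<- cx + (px - cx) * target / rms
      py <<- cy + (py - cy) * target / rms
    }
  }
  record(0)
  t <- 0; frame <- 0L; stopAt <- NA_real_
  repeat {
    frame <- frame + 1L
    for (ss in seq_len(nsub)) {
      t <- (frame - 1L) * p$frameInterval + ss * dt
      DOutEff <- if (!is.na(indTime) && t >= indTime) p$DOut else 0
      AOutEff <- if (!is.na(indTime) && t >= indTime) p$AOut else 0
      st <- stepCell(st, p, dt, DOutEff, AOutEff)
      clamped <- clamped + attr(st, "clamped")
      k <- attr(st, "k")
      ## arrest bookkeeping
      below <- k < p$deathRateFloor
      aclock <- ifelse(below, aclock + dt, 0)
      newly <- !arrested & aclock >= p$arrestDuration
      arrested <- arrested | newly
      ## divisions
      ready <- which(!arrested & st$length >= 2 * birthLen[idx])
      if (length(ready)) {
        for (j in ready) {
          mother <- idx[j]
          endT[mother] <- t; endState[mother] <- "divided"
          dl <- divideCell(list(length = st$length[j], D = st$D[j],
                                S = st$S[j], F = st$F[j], F2 = st$F2[j]),
                           p)
          c1 <- newCell(mother, t, dl[[1]]$length)
          c2 <- newCell(mother, t, dl[[2]]$length)
          theta <- stats::runif(1, 0, 2 * pi)
          off <- 10 * st$length[j] / 4  # px; 10 px per um
          ## append daughters, mark mother for removal
          idx <- c(idx, c1, c2)
          st$length <- c(st$length, dl[[1]]$length, dl[[2]]$length)
          st$D <- c(st$D, dl[[1]]$D, dl[[2]]$D)
          st$S <- c(st$S, dl[[1]]$S, dl[[2]]$S)
          st$F <- c(st$F, dl[[1]]$F, dl[[2]]$F)
          st$F2 <- c(st$F2, dl[[1]]$F2, dl[[2]]$F2)
          px <- c(px, px[j] + off * cos(theta), px[j] - off * cos(theta))
          py <- c(py, py[j] + off * sin(theta), py[j] - off * sin(theta))
          arrested <- c(arrested, FALSE, FALSE)
          aclock <- c(aclock, 0, 0)
        }
        keep <- setdiff(seq_along(idx), ready)
        idx <- idx[keep]
        st <- lapply(st, function(v) v[keep])
        px <- px[keep]; py <- py[keep]
        arrested <- arrested[keep]; aclock <- aclock[keep]
      }
      if (is.na(indTime) && length(idx) >= p$inductionColonySize) {
        indTime <- t
      }
      if (length(idx) == 0L) {
        .lv_stop("simulation error: colony extinct (seed %s)",
                 format(p$seed))
      }
    }
    t <- frame * p$frameInterval
    relax()
    record(t)
    if (is.na(stopAt) && length(idx) >= p$maxColonySize) {
      stopAt <- t + p$tailMinutes
    }
    if ((!is.na(stopAt) && t >= stopAt - 1e-9) || t >= p$tMax - 1e-9) break
  }
  if (clamped > 0) {
    warning(sprintf("%d state components clamped to 0 during integration",
                    clamped))
  }
  ## finalize registry
  endT[is.na(endT)] <- t
  alive <- which(is.na(endState))
  endState[alive] <- "censored"
  endState[idx[arrested]] <- "arrested"
  ## a division at the very last instant would leave zero-lifetime daughters:
  ## drop them and keep the mother as censored through the record end
  zero <- which(endT - birthT <= 1e-9)
  keepCell <- rep(TRUE, N)
  if (length(zero)) {
    keepCell[zero] <- FALSE
    moms <- unique(parent[zero])
    endState[moms] <- "censored"
  }
  ids <- sprintf("c%04d", seq_len(N))
  cells <- data.frame(
    cell_id = ids,
    parent_id = ifelse(parent == 0L, NA_character_, ids[pmax(parent, 1L)]),
    birth_time = birthT, end_time = endT, end_state = endState,
    stringsAsFactors = FALSE)[keepCell, , drop = FALSE]
  samples <- data.frame(
    cell_id = ids[unlist(lapply(sampL, `[[`, "cell"))],
    time = unlist(lapply(sampL, `[[`, "time")),
    length = unlist(lapply(sampL, `[[`, "len")),
    x = unlist(lapply(sampL, `[[`, "x")),
    y = unlist(lapply(sampL, `[[`, "y")),
    fluor_yfp = unlist(lapply(sampL, `[[`, "f")),
    stringsAsFactors = FALSE)
  if (p$coReporter > 0) {
    samples$fluor_tet <- unlist(lapply(sampL, `[[`, "f2"))
  }
  samples <- samples[samples$cell_id %in% cells$cell_id, , drop = FALSE]
  lineageTree(cells, samples, inductionTime = indTime,
              frameInterval = p$frameInterval, colonyId = colonyId)
}
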