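#' @include memory.R
NULL

.lv_param_names <- function() c(
  "doublingTime", "frameInterval", "inductionColonySize", "DOut", "AOut",
  "uptakeBase", "feedbackGain", "stressGain", "stressBasal", "stressDecay",
  "exprBasal",
  "exprInduced", "inductionK", "hillH", "exprGrowthCoupling", "growthK",
  "hillM", "noise",
  "lengthNoise", "fluorSaturation", "partitionCV", "moleculeScaleStress",
  "moleculeScaleExpr",
  "deathRateFloor", "arrestDuration", "maxColonySize", "tMax",
  "tailMinutes", "deterministicPartition", "coReporter", "seed")

#' Construct simulator parameters
#'
#' Full parameter set of the stochastic lineage model. The model couples
#' intracellular drug \code{D}, damage/stress \code{S}, a stress reporter
#' \code{F} and growth: drug enters at a permeability that rises with stress
#' (the positive feedback), damage is produced in proportion to drug times
#' translation (which scales with growth) and diluted by growth, the
#' reporter is induced by damage through a Hill function with multiplicative
#' expression noise, and growth is inhibited by damage through a second Hill
#' function. See \code{\link{stepCell}} for the equations.
#'
#' Units: times in minutes, rates in 1/min, concentrations in arbitrary
#' units per unit cell length, lengths in micrometres.
#'
#' @param doublingTime unstressed doubling time, min (default 23)
#' @param frameInterval sampling cadence, min (default 1.5, i.e. 90 s)
#' @param inductionColonySize colony size at which the stress medium is
#'   switched in (default 8, the 8-16 cell stage; the switch time is recorded
#'   whether or not \code{DOut > 0}, so unstressed controls share the time
#'   axis)
#' @param DOut external drug concentration, a.u. (0 = unstressed)
#' @param AOut external passive-inducer concentration for the co-reporter
#'   channel, a.u. (0 disables)
#' @param uptakeBase basal membrane permeation rate, 1/min
#' @param feedbackGain permeability increase per unit damage (dimensionless)
#' @param stressGain damage produced per unit drug per unit growth
#' @param stressBasal basal damage production (misfolding during normal
#'   translation), a.u./min
#' @param stressDecay active damage removal rate (chaperone/protease
#'   repair) on top of dilution, 1/min
#' @param exprBasal basal reporter production, a.u./min
#' @param exprInduced maximal damage-induced reporter production, a.u./min
#' @param inductionK,hillH damage Hill constant/coefficient for induction
#' @param exprGrowthCoupling exponent coupling reporter production to
#'   relative growth \code{(k/k_max)^exprGrowthCoupling}; 0 (default)
#'   decouples them, 1 makes promoter activity collapse in growth-arrested
#'   cells, as severe stress does to translation
#' @param growthK,hillM damage Hill constant/coefficient for growth
#'   inhibition
#' @param noise multiplicative expression-noise amplitude (sqrt(F) scaling)
#' @param lengthNoise multiplicative measurement noise on recorded lengths
#'   (segmentation error; the underlying growth is unaffected)
#' @param fluorSaturation soft saturation level of recorded intensities
#'   (detector/reporter ceiling): measured = sat*F/(sat+F); 0 disables.
#'   Affects only the recorded samples, not the dynamics.
#' @param partitionCV division-asymmetry CV: the volume fraction q of one
#'   daughter is Normal(0.5, partitionCV/2) truncated to (0.2, 0.8)
#' @param moleculeScaleStress,moleculeScaleExpr molecules per a.u. per um for
#'   converting D/S and F/F2 concentrations to integer copy numbers at
#'   division (binomial partitioning)
#' @param deathRateFloor growth rate below which a cell counts as arrested,
#'   1/min
#' @param arrestDuration minutes below the floor before the arrest is called
#' @param maxColonySize stop once the colony reaches this many cells
#' @param tMax hard time limit, min
#' @param tailMinutes minutes of extra frames recorded after the colony cap
#'   is reached, so end-of-record cells carry enough samples for windowed
#'   growth-rate estimation (default 9)
#' @param deterministicPartition 1 = split copy numbers deterministically in
#'   proportion q (testing aid); 0 = binomial (default)
#' @param coReporter 1 = track the passive co-reporter channel F2
#' @param seed integer seed recorded into the parameter set (NA = use the
#'   ambient RNG)
#' @return a validated \linkS4class{SimParams}
#' @seealso \code{\link{simPreset}} for the calibrated named presets
#' @export
simParams <- function(doublingTime = 23, frameInterval = 1.5,
                      inductionColonySize = 8, DOut = 0, AOut = 0,
                      uptakeBase = 0.03, feedbackGain = 1.6,
                      stressGain = 1.0, stressBasal = 0.003,
                      stressDecay = 0,
                      exprBasal = 3.0, exprInduced = 15.0,
                      inductionK = 0.6, hillH = 2,
                      exprGrowthCoupling = 0, growthK = 1.6,
                      hillM = 4, noise = 0.35, lengthNoise = 0.005,
                      fluorSaturation = 0,
                      partitionCV = 0.1, moleculeScaleStress = 50,
                      moleculeScaleExpr = 20, deathRateFloor = 0.01,
                      arrestDuration = 60, maxColonySize = 256,
                      tMax = 480, tailMinutes = 9,
                      deterministicPartition = 0,
                      coReporter = 0, seed = NA_real_) {
  p <- as.list(environment())
  methods::new("SimParams", params = p)
}

#' Named simulator presets
#'
#' \describe{
#'   \item{null}{No drug outside, no feedback path engaged: constant
#'     stochastic reporter production diluted by steady growth. Reproduces
#'     the no-differentiation regime (SLCV tracks IDCV, autocorrelation
#'     half-life of one generation).}
#'   \item{stressed}{Sub-inhibitory drug switched in at the 8-cell stage
#'     with the permeability positive feedback active. Calibrated (not
#'     measured) so that the stressed regime shows its three qualitative
#'     signatures: a bimodal growth-rate distribution with a dead
#'     sub-population clustered in subtrees, SLCV rising above IDCV after
#'     induction, and an autocorrelation half-life of at least three
#'     generations.}
#'   \item{stressed_coreporter}{Permeability read-out analog: mild drug
#'     exposure with the passive co-inducer channel enabled and a gentle
#'     growth coupling, emulating short co-induction experiments on growing
#'     cells. With the feedback on, cells that take up more drug also
#'     accumulate more co-inducer, so the two reporters correlate; with the
#'     feedback off the co-reporter is flat and the correlation vanishes.}
#' }
#'
#' @param name preset name
#' @param ... overrides passed to \code{\link{simParams}}
#' @return a \linkS4class{SimParams}
#' @export
simPreset <- function(name = c("null", "stressed", "stressed_coreporter"),
                      ...) {
  name <- match.arg(name)
  over <- list(...)
  stressedArgs <- list(
    DOut = 1, uptakeBase = 0.1, stressGain = 0.03, feedbackGain = 14,
    growthK = 0.55, stressBasal = 0.001, inductionK = 0.3,
    exprInduced = 20, fluorSaturation = 2000, moleculeScaleStress = 8,
    deathRateFloor = 0.015, maxColonySize = 2000, tMax = 300)
  base <- switch(name,
    null = list(DOut = 0),
    stressed = stressedArgs,
    stressed_coreporter = list(
      DOut = 1, AOut = 1, coReporter = 1, uptakeBase = 0.03,
      stressGain = 0.15, feedbackGain = 4))
  do.call(simParams, utils::modifyList(base, over))
}
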