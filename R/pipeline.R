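#' @include moments.R
NULL

## Pipeline configuration: plain key-value (YAML) mirroring SimParams /
## run-option names. Exactly one of `input` (tracking-table paths) or
## `preset` (simulator preset name) must be set.

.lv_config_defaults <- function() list(
  input = NULL, preset = NULL, params = list(),
  n_trees = 4L, seed = 1L, out_dir = ".",
  phenotype = "fluorescence", channel = NULL,
  ns_list = c(4, 8, 16, 32, 64),
  alpha = 0.01, n_rand = 500L,
  af_start_size = 8L, af_offset_generations = NULL, min_pairs = 16L,
  n_pairs = NULL, window = 5L)

#' Read and validate a pipeline run configuration
#'
#' @param path YAML file, or a named list of options
#' @return validated config list (defaults filled in)
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else as.list(path)
  full <- utils::modifyList(.lv_config_defaults(), cfg)
  hasInput <- !is.null(full$input) && length(full$input) > 0
  hasPreset <- !is.null(full$preset) && nzchar(full$preset)
  if (hasInput == hasPreset) {
    .lv_stop("usage error: exactly one of 'input' (paths) or 'preset' must be set")
  }
  full
}

## obtain the input trees: read tracking tables or simulate from a preset
.lv_config_trees <- function(cfg) {
  if (!is.null(cfg$input) && length(cfg$input)) {
    lapply(cfg$input, readTrackingTable)
  } else {
    lapply(seq_len(cfg$n_trees), function(i) {
      args <- c(list(name = cfg$preset, seed = cfg$seed + i - 1L),
                cfg$params)
      suppressWarnings(simulateTree(do.call(simPreset, args),
                                    colonyId = sprintf("sim%d", i)))
    })
  }
}

.lv_write_log <- function(cfg, cmd, t0, files, extra = list()) {
  log <- c(list(command = cmd, seed = cfg$seed,
                runtime_sec = round(as.numeric(Sys.time()) - t0, 2),
                outputs = unname(files)),
           extra,
           list(config = cfg[!vapply(cfg, is.null, logical(1))]))
  path <- file.path(cfg$out_dir, paste0(cmd, "_log.yaml"))
  yaml::write_yaml(log, path)
  invisible(path)
}

#' Pipeline subcommands
#'
#' Deterministic, file-based orchestration of the package's analyses. Each
#' command takes a config (list or YAML path; see
#' \code{\link{readRunConfig}}), writes TSV outputs plus a structured YAML
#' log (parameters, seeds, runtime) into \code{out_dir}, and returns the
#' output paths invisibly. Identical config and seed give byte-identical
#' data files.
#'
#' \describe{
#'   \item{runSimulate}{simulate \code{n_trees} colonies from \code{preset}
#'     with seeds \code{seed, seed+1, ...} and write tracking tables.}
#'   \item{runVariation}{SLCV/IDCV curves for each starting size in
#'     \code{ns_list}, averaged over the input colonies.}
#'   \item{runMemory}{lineage autocorrelation per colony, the cross-colony
#'     average curve and its fitted half-life.}
#'   \item{runPredisposition}{sister-progeny tests at every eligible
#'     pre-induction node, with resampling null fractions
#'     (\code{n_rand} re-assignments) and the direction-bias binomial p.}
#'   \item{runRandomize}{same-generation lineage switch randomization of
#'     each input colony (\code{n_pairs} swaps; default = final population).}
#' }
#'
#' @param config named list or path to a YAML config
#' @return output file paths, invisibly
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config) {
  cfg <- readRunConfig(config)
  if (is.null(cfg$preset)) .lv_stop("usage error: simulate requires a preset")
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- .lv_config_trees(cfg)
  files <- vapply(seq_along(trees), function(i) {
    f <- file.path(cfg$out_dir, sprintf("tree%02d.tsv", i))
    writeTrackingTable(trees[[i]], f)
    f
  }, character(1))
  .lv_write_log(cfg, "simulate", t0, files,
                list(seeds = cfg$seed + seq_along(trees) - 1L))
  invisible(files)
}

#' @rdname pipeline
#' @export
runVariation <- function(config) {
  cfg <- readRunConfig(config)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- .lv_config_trees(cfg)
  curves <- suppressWarnings(
    variationCurves(trees, cfg$ns_list, cfg$phenotype, cfg$channel,
                    cfg$window))
  f <- file.path(cfg$out_dir,
                 sprintf("variation_%s.tsv", cfg$phenotype))
  writeTidyTSV(curves, f)
  .lv_write_log(cfg, "variation", t0, f)
  invisible(f)
}

#' Average autocorrelation curves across colonies
#'
#' Per-generation mean of the AF values of several colonies (curves are
#' averaged, pairs are never pooled across colonies); points present in
#' fewer colonies are averaged over those colonies only.
#'
#' @param curves list of \linkS4class{AFCurve}s
#' @return an \linkS4class{AFCurve} with summed \code{n_pairs}
#' @export
averageAFCurves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  pts <- do.call(rbind, lapply(curves, afPoints))
  grp <- split(pts, pts$g)
  avg <- do.call(rbind, lapply(grp, function(d) data.frame(
    g = d$g[1], t = mean(d$t), af = mean(d$af),
    n_pairs = sum(d$n_pairs))))
  avg <- avg[order(avg$g), , drop = FALSE]
  rownames(avg) <- NULL
  methods::new("AFCurve", startTime = curves[[1]]@startTime,
               phenotype = curves[[1]]@phenotype, points = avg,
               halflife = NA_real_)
}

## start time for AF: either the first time the colony has af_start_size
## cells, or `af_offset_generations` colony stages after induction
.lv_af_start <- function(tree, cfg) {
  times <- sort(unique(sampleTable(tree)$time))
  if (!is.null(cfg$af_offset_generations)) {
    ind <- inductionTime(tree)
    if (is.na(ind)) .lv_stop("usage error: af_offset_generations needs an induction time")
    target <- colonyStageGeneration(tree, ind) + cfg$af_offset_generations
    ok <- times[vapply(times, function(t)
      colonyStageGeneration(tree, t) >= target, logical(1))]
  } else {
    ok <- times[vapply(times, function(t)
      length(cellsAliveAt(tree, t)) >= cfg$af_start_size, logical(1))]
  }
  if (!length(ok)) .lv_stop("colony never reaches the AF start point")
  ok[1]
}

#' @rdname pipeline
#' @export
runMemory <- function(config) {
  cfg <- readRunConfig(config)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- .lv_config_trees(cfg)
  curves <- lapply(trees, function(tr) {
    lineageAF(tr, .lv_af_start(tr, cfg), cfg$phenotype, cfg$channel,
              cfg$window, cfg$min_pairs)
  })
  files <- vapply(seq_along(curves), function(i) {
    f <- file.path(cfg$out_dir, sprintf("af_tree%02d.tsv", i))
    writeAFCurve(curves[[i]], f)
    f
  }, character(1))
  avg <- averageAFCurves(curves)
  hl <- tryCatch(fitHalflife(avg), error = function(e) NA_real_)
  favg <- file.path(cfg$out_dir, "af_mean.tsv")
  writeAFCurve(avg, favg, halflife = hl)
  .lv_write_log(cfg, "memory", t0, c(files, favg),
                list(halflife_generations = hl))
  invisible(c(files, favg))
}

#' @rdname pipeline
#' @export
runPredisposition <- function(config) {
  cfg <- readRunConfig(config)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- .lv_config_trees(cfg)
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (is.na(inductionTime(tr))) {
      .lv_stop("usage error: tree %d has no induction time; predisposition needs pre-induction nodes",
               i)
    }
    tEnd <- max(sampleTable(tr)$time)
    res <- nodeProgenyTests(tr, tEnd, cfg$phenotype, cfg$channel,
                            cfg$window, cfg$alpha)
    if (nrow(res) == 0L) return(NULL)
    res$rand_sig_fraction <- vapply(res$node_id, function(id) {
      randomizedNodeTest(tr, id, tEnd, cfg$phenotype, cfg$channel,
                         cfg$window, cfg$n_rand, cfg$alpha,
                         seed = cfg$seed + i)
    }, numeric(1))
    cbind(colony = tr@colonyId, res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .lv_stop("no eligible pre-induction nodes in any tree")
  f <- file.path(cfg$out_dir, "node_tests.tsv")
  writeTidyTSV(out, f)
  biasP <- tryCatch(biasBinomialTest(out$direction), error = function(e) NA)
  .lv_write_log(cfg, "predisposition", t0, f,
                list(n_nodes = nrow(out),
                     n_significant = sum(out$p_value < cfg$alpha),
                     bias_binomial_p = biasP))
  invisible(f)
}

#' @rdname pipeline
#' @export
runRandomize <- function(config) {
  cfg <- readRunConfig(config)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- .lv_config_trees(cfg)
  files <- vapply(seq_along(trees), function(i) {
    rt <- lineageSwitchRandomization(trees[[i]], cfg$n_pairs,
                                     seed = cfg$seed + i)
    f <- file.path(cfg$out_dir, sprintf("tree%02d_randomized.tsv", i))
    writeTrackingTable(rt, f)
    f
  }, character(1))
  .lv_write_log(cfg, "randomize", t0, files)
  invisible(files)
}
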