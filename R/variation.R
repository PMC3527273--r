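#' @include phenotypes.R
NULL

#' Individual coefficient of variation (IDCV)
#'
#' Coefficient of variation among all individual cells of the micro-colony at
#' one time point: unbiased sample standard deviation divided by the grand
#' mean (simple mean over all cells). Measures phenotypic heterogeneity
#' regardless of lineage relation.
#'
#' @param x numeric vector of per-cell phenotype values (NA allowed, dropped)
#' @return dimensionless CV
#' @seealso \code{\link{slcv}}
#' @export
idcv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) .lv_stop("sample-size error: need >= 2 cells, have %d",
                               length(x))
  m <- mean(x)
  if (m <= 0) .lv_stop("domain error: grand mean must be positive (is %g)", m)
  stats::sd(x) / m
}

#' Sub-lineage coefficient of variation (SLCV)
#'
#' Cells alive at end point \code{t} are grouped by their ancestor alive at
#' start point \code{s} (groups \code{i = 1..N_s} of sizes \code{n_i}). The
#' SLCV is the square root of the size-weighted between-group mean square,
#' normalized by the grand mean over all \code{N_t} cells:
#' \deqn{SLCV = \sqrt{\sum_i n_i (\bar x_i - \bar x)^2 / (N_s - 1)} / \bar x.}
#' Under no differentiation between sub-lineages the between-group mean
#' square estimates the same variance as the all-cell sample variance, so
#' SLCV tracks IDCV; SLCV rising above IDCV flags lineage differentiation.
#' When \code{s == t} every group is a singleton and SLCV equals
#' \code{\link{idcv}} exactly.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param s start time (minutes); the grouping reference
#' @param t end time (minutes), \code{t >= s}
#' @param phenotype,channel,window passed to \code{\link{phenotypeAt}}
#' @param weighted use the \code{n_i}-weighted between-group mean square
#'   (default); \code{FALSE} uses the unweighted variance of group means
#' @return dimensionless CV
#' @export
slcv <- function(tree, s, t, phenotype = "fluorescence", channel = NULL,
                 window = 5L, weighted = TRUE) {
  if (t < s) .lv_stop("end point t must be >= start point s")
  x <- phenotypeAt(tree, t, phenotype, channel, window)
  x <- x[!is.na(x)]
  if (length(x) < 2L) .lv_stop("sample-size error: need >= 2 cells at t")
  anc <- .lv_ancestors_at(tree, names(x), s)
  grp <- split(unname(x), anc)
  sizes <- lengths(grp)
  if (any(sizes == 0L)) {
    warning("dropping extinct sub-lineage group(s)")
    grp <- grp[sizes > 0L]
  }
  Ns <- length(grp)
  if (Ns < 2L) .lv_stop("sample-size error: < 2 surviving sub-lineage groups")
  xbar <- mean(x)
  if (xbar <= 0) .lv_stop("domain error: grand mean must be positive")
  means <- vapply(grp, mean, numeric(1))
  ssb <- if (weighted) {
    sum(lengths(grp) * (means - xbar)^2)
  } else {
    sum((means - mean(means))^2)
  }
  sqrt(ssb / (Ns - 1)) / xbar
}

#' SLCV/IDCV variation curves over time
#'
#' For each starting colony size \code{N_s}, the start time \code{s} is the
#' first frame at which the colony has at least \code{N_s} cells; SLCV and
#' IDCV are then evaluated at every subsequent frame until the end of the
#' record. With several trees the per-timepoint mean across colonies is
#' reported (curves are averaged, cells are never pooled across colonies).
#'
#' @param trees a \linkS4class{LineageTree} or list of them
#' @param nsList starting sizes (default \code{c(4, 8, 16, 32, 64)})
#' @param phenotype,channel,window passed to \code{\link{phenotypeAt}}
#' @return data.frame with columns \code{phenotype}, \code{n_s}, \code{t},
#'   \code{n_t}, \code{slcv}, \code{idcv}, \code{n_trees}
#' @export
variationCurves <- function(trees, nsList = c(4, 8, 16, 32, 64),
                            phenotype = "fluorescence", channel = NULL,
                            window = 5L) {
  if (methods::is(trees, "LineageTree")) trees <- list(trees)
  per <- lapply(trees, function(tr)
    .lv_curves_one(tr, nsList, phenotype, channel, window))
  all <- do.call(rbind, per)
  if (is.null(all) || nrow(all) == 0L) {
    .lv_stop("no curves could be computed for any tree")
  }
  grp <- split(all, list(all$n_s, all$t), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(d) data.frame(
    phenotype = phenotype, n_s = d$n_s[1], t = d$t[1],
    n_t = mean(d$n_t, na.rm = TRUE),
    slcv = if (all(is.na(d$slcv))) NA_real_ else mean(d$slcv, na.rm = TRUE),
    idcv = if (all(is.na(d$idcv))) NA_real_ else mean(d$idcv, na.rm = TRUE),
    n_trees = sum(!is.na(d$slcv)))))
  out <- out[order(out$n_s, out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.lv_curves_one <- function(tree, nsList, phenotype, channel, window) {
  times <- sort(unique(sampleTable(tree)$time))
  pop <- vapply(times, function(t) length(cellsAliveAt(tree, t)), integer(1))
  res <- list()
  for (Ns in nsList) {
    i0 <- which(pop >= Ns)[1]
    if (is.na(i0)) {
      warning(sprintf("colony %s never reaches %d cells; curve omitted",
                      tree@colonyId, Ns))
      next
    }
    s <- times[i0]
    tgrid <- times[times >= s]
    vals <- lapply(tgrid, function(t) {
      sl <- tryCatch(slcv(tree, s, t, phenotype, channel, window),
                     error = function(e) NA_real_)
      idv <- tryCatch({
        x <- phenotypeAt(tree, t, phenotype, channel, window)
        idcv(x)
      }, error = function(e) NA_real_)
      c(sl, idv, length(cellsAliveAt(tree, t)))
    })
    m <- do.call(rbind, vals)
    res[[length(res) + 1L]] <- data.frame(
      n_s = Ns, s = s, t = tgrid, n_t = m[, 3],
      slcv = m[, 1], idcv = m[, 2])
  }
  do.call(rbind, res)
}

#' Correlation between growth rate and reporter intensity
#'
#' Pairs each cell's growth-rate estimate with its fluorescence intensity at
#' the frame nearest \code{t} and reports Pearson and Spearman coefficients.
#' Under induced stress the reporter is expected to correlate negatively with
#' growth (stressed cells grow slowly), saturating at low growth rates.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param t time in minutes
#' @param channel,window passed to \code{\link{phenotypeAt}}
#' @return list with \code{pairs} (data.frame cell_id, growth_rate,
#'   intensity), \code{pearson}, \code{spearman}
#' @export
phenotypeGrowthCorrelation <- function(tree, t, channel = NULL, window = 5L) {
  k <- phenotypeAt(tree, t, "growth_rate", window = window)
  f <- phenotypeAt(tree, t, "fluorescence", channel = channel)
  keep <- !is.na(k) & !is.na(f)
  k <- k[keep]; f <- f[keep]
  if (length(k) < 3L) .lv_stop("need >= 3 complete (growth, intensity) pairs")
  if (stats::sd(k) == 0 || stats::sd(f) == 0) {
    .lv_stop("undefined-correlation error: constant phenotype vector")
  }
  list(pairs = data.frame(cell_id = names(k), growth_rate = unname(k),
                          intensity = unname(f)),
       pearson = stats::cor(k, f),
       spearman = stats::cor(k, f, method = "spearman"))
}

#' Export variation curves or fate calls as TSV
#'
#' @param x data.frame (e.g. from \code{\link{variationCurves}} or
#'   \code{\link{classifyFate}})
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTidyTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}
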