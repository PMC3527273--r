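#' @include utils.R
NULL

#' Construct a LineageTree from cell and sample tables
#'
#' Validates the full set of structural invariants: exactly one founder, every
#' parent known, a divided cell has exactly two children born at the instant
#' the mother ends, arrested/censored cells are leaves, sample times are
#' strictly increasing within each cell and confined to its lifetime.
#'
#' @param cells data.frame with columns \code{cell_id}, \code{parent_id}
#'   (\code{NA} or \code{"-"} for the founder), \code{birth_time},
#'   \code{end_time} (minutes) and \code{end_state} (\code{"divided"},
#'   \code{"arrested"} or \code{"censored"}).
#' @param samples data.frame with columns \code{cell_id}, \code{time},
#'   \code{length}, \code{x}, \code{y} plus any number of \code{fluor_*}
#'   intensity columns (missing intensities as \code{NA}).
#' @param inductionTime minutes at which stress was switched on, or \code{NA}.
#' @param frameInterval minutes between consecutive frames (default 1.5).
#' @param colonyId label for the micro-colony.
#' @param randomized internal flag set by
#'   \code{\link{lineageSwitchRandomization}}.
#' @return a validated \linkS4class{LineageTree}.
#' @examples
#' cells <- data.frame(
#'   cell_id = c("c1", "c2", "c3"),
#'   parent_id = c(NA, "c1", "c1"),
#'   birth_time = c(0, 15, 15),
#'   end_time = c(15, 30, 30),
#'   end_state = c("divided", "censored", "censored"))
#' samples <- data.frame(
#'   cell_id = rep(c("c1", "c2", "c3"), each = 3),
#'   time = c(0, 6, 12, 15, 21, 27, 15, 21, 27),
#'   length = 2^(c(0, 6, 12, 0, 6, 12, 0, 6, 12) / 23),
#'   x = 0, y = 0, fluor_yfp = 100)
#' tr <- lineageTree(cells, samples, frameInterval = 6)
#' tr
#' @export
lineageTree <- function(cells, samples, inductionTime = NA_real_,
                        frameInterval = 1.5, colonyId = "colony1",
                        randomized = FALSE) {
  cells <- as.data.frame(cells)
  samples <- as.data.frame(samples)
  cells$cell_id <- as.character(cells$cell_id)
  cells$parent_id <- as.character(cells$parent_id)
  cells$parent_id[cells$parent_id %in% "-"] <- NA_character_
  samples$cell_id <- as.character(samples$cell_id)
  if (nrow(cells) == 0L) .lv_stop("empty tree: no cell records")
  founder <- cells$cell_id[is.na(cells$parent_id)]
  if (length(founder) != 1L) {
    .lv_stop("structural error: expected exactly 1 founder, found %d (%s)",
             length(founder), paste(founder, collapse = ", "))
  }
  ## order samples by cell then time for downstream per-cell scans
  samples <- samples[order(match(samples$cell_id, cells$cell_id),
                           samples$time), , drop = FALSE]
  rownames(samples) <- NULL
  rownames(cells) <- NULL
  methods::new("LineageTree", cells = cells, samples = samples,
               founderId = founder,
               inductionTime = as.numeric(inductionTime),
               frameInterval = as.numeric(frameInterval),
               colonyId = as.character(colonyId),
               randomized = isTRUE(randomized))
}
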