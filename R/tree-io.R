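#' @include tree-accessors.R
NULL

## Tracking-table dialect: TSV, UTF-8, one row per cell per frame, missing
## values "NA", founder parent_id "-". Required columns: colony_id, cell_id,
## parent_id, frame, time_min, length_um, x_px, y_px and >= 1 fluor_* column.
## The writer adds birth_time_min, end_time_min and end_state so round-trips
## are exact; the reader reconstructs them when absent (a divided mother ends
## when her daughters' records start).

.lv_required_cols <- c("colony_id", "cell_id", "parent_id", "frame",
                       "time_min", "length_um", "x_px", "y_px")

#' Read a cell-tracking table
#'
#' Parses the TSV tracking dialect (one row per cell per frame) into a
#' validated \linkS4class{LineageTree}. Files written by
#' \code{\link{writeTrackingTable}} round-trip exactly; minimal files from
#' segmentation-tool exports are accepted, with birth/end times inferred from
#' the sample rows.
#'
#' @param path path to a TSV file
#' @param inductionTime stress-switch time in minutes (overrides any
#'   \code{#induction_time_min} header comment in the file)
#' @param frameInterval minutes per frame (overrides any
#'   \code{#frame_interval_min} header comment; default 1.5 when unstated)
#' @return a \linkS4class{LineageTree}
#' @seealso \code{\link{writeTrackingTable}}
#' @export
readTrackingTable <- function(path, inductionTime = NULL,
                              frameInterval = NULL) {
  if (!file.exists(path)) .lv_stop("file not found: %s", path)
  head_lines <- readLines(path, n = 50L)
  meta <- grep("^#", head_lines, value = TRUE)
  getmeta <- function(key) {
    m <- grep(paste0("^#", key, "\t"), meta, value = TRUE)
    if (length(m)) as.numeric(sub(".*\t", "", m[1])) else NA_real_
  }
  tab <- utils::read.delim(path, comment.char = "#", na.strings = "NA",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.lv_required_cols, names(tab))
  if (length(miss)) {
    .lv_stop("format error: missing required column(s): %s",
             paste(miss, collapse = ", "))
  }
  fl <- grep("^fluor_", names(tab), value = TRUE)
  if (length(fl) == 0L) .lv_stop("format error: no fluor_* column present")
  if (nrow(tab) == 0L) .lv_stop("empty tree: file has a header but no rows")

  if (is.null(frameInterval)) frameInterval <- getmeta("frame_interval_min")
  if (is.na(frameInterval) || is.null(frameInterval)) frameInterval <- 1.5
  if (is.null(inductionTime)) inductionTime <- getmeta("induction_time_min")

  tab$cell_id <- as.character(tab$cell_id)
  tab$parent_id <- as.character(tab$parent_id)
  tab$parent_id[tab$parent_id %in% "-"] <- NA_character_

  ## per-cell monotone time check before any reshaping
  ord <- order(tab$cell_id, tab$frame)
  tt <- tab$time_min[ord]
  same <- tab$cell_id[ord][-1L] == tab$cell_id[ord][-nrow(tab)]
  if (nrow(tab) > 1L && any(diff(tt)[same] <= 0)) {
    bad <- unique(tab$cell_id[ord][-1L][same & diff(tt) <= 0])
    .lv_stop("format error: non-monotone times for cell(s) %s",
             paste(bad, collapse = ", "))
  }

  first <- !duplicated(tab$cell_id)
  cells <- data.frame(
    cell_id = tab$cell_id[first],
    parent_id = tab$parent_id[first],
    stringsAsFactors = FALSE)
  unknown <- !is.na(cells$parent_id) & !(cells$parent_id %in% cells$cell_id)
  if (any(unknown)) {
    .lv_stop("structural error: cell(s) %s reference absent parent(s) %s",
             paste(cells$cell_id[unknown], collapse = ", "),
             paste(unique(cells$parent_id[unknown]), collapse = ", "))
  }
  agg <- function(col, fun) {
    as.numeric(tapply(tab[[col]], tab$cell_id, fun)[cells$cell_id])
  }
  firstT <- agg("time_min", min)
  lastT <- agg("time_min", max)
  haskids <- cells$cell_id %in% cells$parent_id

  if ("birth_time_min" %in% names(tab)) {
    cells$birth_time <- as.numeric(
      tapply(tab$birth_time_min, tab$cell_id, function(x) x[1])[cells$cell_id])
    cells$end_time <- as.numeric(
      tapply(tab$end_time_min, tab$cell_id, function(x) x[1])[cells$cell_id])
  } else {
    ## infer: a divided mother ends when her daughters' records begin
    cells$birth_time <- firstT
    cells$end_time <- lastT
    kidstart <- tapply(firstT, cells$parent_id, min)
    has <- cells$cell_id %in% names(kidstart)
    cells$end_time[has] <- as.numeric(kidstart[cells$cell_id[has]])
    cells$birth_time[!is.na(cells$parent_id)] <-
      cells$end_time[match(cells$parent_id, cells$cell_id)][!is.na(cells$parent_id)]
  }
  if ("end_state" %in% names(tab)) {
    cells$end_state <- as.character(
      tapply(tab$end_state, tab$cell_id, function(x) x[1])[cells$cell_id])
  } else {
    cells$end_state <- ifelse(haskids, "divided", "censored")
  }

  samples <- data.frame(
    cell_id = tab$cell_id, time = tab$time_min, length = tab$length_um,
    x = tab$x_px, y = tab$y_px, stringsAsFactors = FALSE)
  for (ch in fl) samples[[ch]] <- tab[[ch]]

  lineageTree(cells, samples,
              inductionTime = if (is.null(inductionTime)) NA_real_
                              else inductionTime,
              frameInterval = frameInterval,
              colonyId = as.character(tab$colony_id[1]),
              randomized = isTRUE(getmeta("randomized") == 1))
}

#' Write a cell-tracking table
#'
#' Serializes a \linkS4class{LineageTree} into the TSV tracking dialect, one
#' row per cell per frame. Frame indices are recomputed from sample times and
#' the tree's frame interval; metadata (frame interval, induction time) go in
#' \code{#key\tvalue} header comments.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTrackingTable <- function(tree, path) {
  ce <- cellTable(tree)
  sa <- sampleTable(tree)
  ii <- match(sa$cell_id, ce$cell_id)
  fl <- fluorChannels(tree)
  out <- data.frame(
    colony_id = tree@colonyId,
    cell_id = sa$cell_id,
    parent_id = ifelse(is.na(ce$parent_id[ii]), "-", ce$parent_id[ii]),
    frame = as.integer(round(sa$time / frameInterval(tree))),
    time_min = .lv_num(sa$time),
    length_um = .lv_num(sa$length),
    x_px = .lv_num(sa$x),
    y_px = .lv_num(sa$y),
    stringsAsFactors = FALSE)
  for (ch in fl) out[[ch]] <- .lv_num(sa[[ch]])
  out$birth_time_min <- .lv_num(ce$birth_time[ii])
  out$end_time_min <- .lv_num(ce$end_time[ii])
  out$end_state <- ce$end_state[ii]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#frame_interval_min\t%s", .lv_num(frameInterval(tree))),
             con)
  if (!is.na(inductionTime(tree))) {
    writeLines(sprintf("#induction_time_min\t%s",
                       .lv_num(inductionTime(tree))), con)
  }
  if (tree@randomized) writeLines("#randomized\t1", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

## print numerics with enough digits that read-back is exact to 1e-9
.lv_num <- function(x) {
  ifelse(is.na(x), NA, sprintf("%.12g", x))
}

#' Export lineage topology as Newick
#'
#' Writes the division topology with cell ids as labels, branch lengths equal
#' to cell lifetimes in minutes, and each cell's terminal state in a bracket
#' comment (\code{[&end_state=...]}) after its label.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param path optional file to write to
#' @param comments include end-state comments (default TRUE; disable for
#'   strict parsers)
#' @return the Newick string, invisibly if \code{path} is given
#' @export
exportNewick <- function(tree, path = NULL, comments = TRUE) {
  ce <- cellTable(tree)
  kids <- split(ce$cell_id[!is.na(ce$parent_id)],
                ce$parent_id[!is.na(ce$parent_id)])
  life <- stats::setNames(ce$end_time - ce$birth_time, ce$cell_id)
  state <- stats::setNames(ce$end_state, ce$cell_id)
  rec <- function(id) {
    lab <- paste0(id, if (comments) sprintf("[&end_state=%s]", state[[id]])
                      else "")
    br <- sprintf("%s:%s", lab, .lv_num(life[[id]]))
    ch <- kids[[id]]
    if (is.null(ch)) br
    else paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","),
                ")", br)
  }
  nwk <- paste0(rec(founderId(tree)), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
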