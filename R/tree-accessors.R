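#' @include tree-build.R
NULL

#' Accessors for LineageTree objects
#'
#' \code{cellTable} and \code{sampleTable} return the per-cell and per-frame
#' tables; \code{founderId}, \code{inductionTime}, \code{frameInterval},
#' \code{cellIds}, \code{nCells} and \code{fluorChannels} return the obvious
#' scalars/vectors.
#'
#' @param x a \linkS4class{LineageTree}
#' @param value replacement induction time in minutes
#' @name cellTable
#' @aliases sampleTable founderId inductionTime inductionTime<- frameInterval
#'   cellIds nCells fluorChannels
NULL

#' @rdname cellTable
#' @export
setMethod("cellTable", "LineageTree", function(x) x@cells)

#' @rdname cellTable
#' @export
setMethod("sampleTable", "LineageTree", function(x) x@samples)

#' @rdname cellTable
#' @export
setMethod("founderId", "LineageTree", function(x) x@founderId)

#' @rdname cellTable
#' @export
setMethod("inductionTime", "LineageTree", function(x) x@inductionTime)

#' @rdname cellTable
#' @export
setMethod("inductionTime<-", "LineageTree", function(x, value) {
  x@inductionTime <- as.numeric(value)
  x
})

#' @rdname cellTable
#' @export
setMethod("frameInterval", "LineageTree", function(x) x@frameInterval)

#' @rdname cellTable
#' @export
setMethod("cellIds", "LineageTree", function(x) x@cells$cell_id)

#' @rdname cellTable
#' @export
setMethod("nCells", "LineageTree", function(x) nrow(x@cells))

#' @rdname cellTable
#' @export
setMethod("fluorChannels", "LineageTree", function(x) {
  grep("^fluor_", names(x@samples), value = TRUE)
})

#' Cells alive at a time point
#'
#' A cell is alive at \code{t} if \code{birth_time <= t <= end_time}, except
#' that a divided mother is excluded at the division instant itself (her
#' daughters take over; the instant belongs to both records but the population
#' must not be double-counted).
#'
#' @param tree a \linkS4class{LineageTree}
#' @param t time in minutes
#' @return character vector of cell ids
#' @export
cellsAliveAt <- function(tree, t) {
  ce <- cellTable(tree)
  alive <- ce$birth_time <= t + 1e-9 &
    (t < ce$end_time - 1e-9 |
       (abs(t - ce$end_time) <= 1e-9 & ce$end_state != "divided"))
  ce$cell_id[alive]
}

#' Lineage generation of cells
#'
#' Number of division edges separating a cell from the founder (founder = 0).
#'
#' @param tree a \linkS4class{LineageTree}
#' @param cellId cell ids (default: all cells)
#' @return named integer vector
#' @export
generationOf <- function(tree, cellId = cellIds(tree)) {
  ce <- cellTable(tree)
  depth <- .lv_depths(ce$cell_id, ce$parent_id)
  names(depth) <- ce$cell_id
  out <- depth[cellId]
  if (anyNA(out)) .lv_stop("unknown cell id(s): %s",
                           paste(cellId[is.na(out)], collapse = ", "))
  out
}

#' Colony-stage generation at a time point
#'
#' \code{floor(log2(population size))}: the generation axis used for lineage
#' autocorrelation curves, determined by the number of cells in the
#' micro-colony rather than by any one cell's division count.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param t time in minutes
#' @return integer stage
#' @export
colonyStageGeneration <- function(tree, t) {
  n <- length(cellsAliveAt(tree, t))
  if (n < 1L) .lv_stop("no cells alive at t = %g", t)
  as.integer(floor(log2(n)))
}

#' Ancestor of a cell alive at an earlier time
#'
#' Walks up the parent chain from \code{cellId} until it reaches the unique
#' ancestor (possibly the cell itself) whose lifetime contains \code{s}. For
#' randomized trees (scrambled ancestry) the walk is by birth time only.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param cellId a single cell id
#' @param s reference time in minutes
#' @return the ancestor's cell id
#' @export
ancestorAt <- function(tree, cellId, s) {
  ce <- cellTable(tree)
  i <- match(cellId, ce$cell_id)
  if (is.na(i)) .lv_stop("unknown cell id: %s", cellId)
  if (s > ce$end_time[i] + 1e-9) {
    .lv_stop("s = %g is after the end of cell %s's record", s, cellId)
  }
  while (ce$birth_time[i] > s + 1e-9) {
    p <- match(ce$parent_id[i], ce$cell_id)
    if (is.na(p)) .lv_stop("s = %g precedes the founder's birth", s)
    i <- p
  }
  ce$cell_id[i]
}

## vectorized ancestor map for all cells alive at/after s (internal)
.lv_ancestors_at <- function(tree, ids, s) {
  ce <- cellTable(tree)
  idx <- match(ids, ce$cell_id)
  pidx <- match(ce$parent_id, ce$cell_id)
  cur <- idx
  repeat {
    up <- ce$birth_time[cur] > s + 1e-9
    if (!any(up)) break
    nxt <- pidx[cur[up]]
    if (anyNA(nxt)) .lv_stop("s = %g precedes the founder's birth", s)
    cur[up] <- nxt
  }
  stats::setNames(ce$cell_id[cur], ids)
}

#' Distance of each cell to the micro-colony border
#'
#' Border cells are the vertices of the convex hull of all cell centroids at
#' time \code{t} and get distance 0; every interior cell gets the minimum
#' centroid-to-centroid distance to a border cell, in pixels. With fewer than
#' 3 cells all distances are 0. The vertex definition approximates the true
#' pixel-level colony boundary well for near-convex colonies.
#'
#' @param tree a \linkS4class{LineageTree}
#' @param t time in minutes
#' @return named numeric vector (px) over cells alive at \code{t}
#' @export
distanceToBorder <- function(tree, t) {
  ids <- cellsAliveAt(tree, t)
  sa <- sampleTable(tree)
  xy <- t(vapply(ids, function(id) {
    rows <- sa[sa$cell_id == id, , drop = FALSE]
    j <- which.min(abs(rows$time - t))
    c(rows$x[j], rows$y[j])
  }, numeric(2)))
  n <- nrow(xy)
  out <- stats::setNames(numeric(n), ids)
  if (n < 3L) return(out)
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  inner <- setdiff(seq_len(n), hull)
  if (length(inner)) {
    d <- sqrt(outer(xy[inner, 1], xy[hull, 1], "-")^2 +
                outer(xy[inner, 2], xy[hull, 2], "-")^2)
    out[inner] <- apply(d, 1, min)
  }
  out
}

#' Descendants of a cell
#'
#' @param tree a \linkS4class{LineageTree}
#' @param cellId a single cell id
#' @param includeSelf include \code{cellId} itself (default FALSE)
#' @return character vector of descendant ids
#' @export
descendantsOf <- function(tree, cellId, includeSelf = FALSE) {
  ce <- cellTable(tree)
  if (!cellId %in% ce$cell_id) .lv_stop("unknown cell id: %s", cellId)
  out <- character()
  frontier <- cellId
  while (length(frontier)) {
    kids <- ce$cell_id[!is.na(ce$parent_id) & ce$parent_id %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  if (includeSelf) c(cellId, out) else out
}
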