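test_that("a minimal hand-written tracking table loads with the documented topology", {
  ## founder over frames 0-9, two daughters over frames 10-19
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("colony_id", "cell_id", "parent_id", "frame", "time_min",
                 "length_um", "x_px", "y_px", "fluor_yfp"), collapse = "\t")
  rows <- c(
    sprintf("col1\tm\t-\t%d\t%g\t%g\t0\t0\t100", 0:9, (0:9) * 1.5,
            2 * exp(0.03 * (0:9) * 1.5)),
    sprintf("col1\td1\tm\t%d\t%g\t%g\t0\t0\t110", 10:19, (10:19) * 1.5,
            2 * exp(0.03 * ((10:19) - 10) * 1.5)),
    sprintf("col1\td2\tm\t%d\t%g\t%g\t0\t0\t90", 10:19, (10:19) * 1.5,
            2 * exp(0.03 * ((10:19) - 10) * 1.5)))
  writeLines(c(hdr, rows), path)
  tr <- readTrackingTable(path)
  expect_s4_class(tr, "LineageTree")
  expect_equal(nCells(tr), 3L)
  expect_equal(founderId(tr), "m")
  expect_equal(unname(generationOf(tr, c("d1", "d2"))), c(1L, 1L))
  ## inferred division instant: daughters' first frame
  ce <- cellTable(tr)
  expect_equal(ce$end_time[ce$cell_id == "m"], 15)
  expect_equal(ce$birth_time[ce$cell_id == "d1"], 15)
  expect_setequal(cellsAliveAt(tr, 20), c("d1", "d2"))
})

test_that("malformed tracking tables produce the specific errors", {
  hdr <- paste(c("colony_id", "cell_id", "parent_id", "frame", "time_min",
                 "length_um", "x_px", "y_px", "fluor_yfp"), collapse = "\t")
  ## header-only file
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, p1)
  expect_error(readTrackingTable(p1), "empty tree")
  ## daughter referencing an absent parent
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "col1\tc1\t-\t0\t0\t2\t0\t0\t100",
               "col1\tc1\t-\t1\t1.5\t2.1\t0\t0\t100",
               "col1\tc9\tghost\t2\t3\t2\t0\t0\t100"), p2)
  expect_error(readTrackingTable(p2), "structural error.*ghost")
  ## non-monotone times within a cell
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "col1\tc1\t-\t0\t3\t2\t0\t0\t100",
               "col1\tc1\t-\t1\t1.5\t2.1\t0\t0\t100"), p3)
  expect_error(readTrackingTable(p3), "non-monotone")
  ## missing required column
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("colony_id\tcell_id\tparent_id\tframe\ttime_min",
               "col1\tc1\t-\t0\t0"), p4)
  expect_error(readTrackingTable(p4), "missing required column")
})

test_that("write/read round-trips preserve a simulated tree", {
  tr <- cachedSim("null", seed = 41, maxColonySize = 24)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrackingTable(tr, path)
  tr2 <- readTrackingTable(path)
  expect_identical(cellIds(tr2), cellIds(tr))
  expect_identical(cellTable(tr2)$end_state, cellTable(tr)$end_state)
  expect_equal(cellTable(tr2)$birth_time, cellTable(tr)$birth_time,
               tolerance = 1e-9)
  expect_equal(sampleTable(tr2)$length, sampleTable(tr)$length,
               tolerance = 1e-9)
  expect_equal(sampleTable(tr2)$fluor_yfp, sampleTable(tr)$fluor_yfp,
               tolerance = 1e-9)
  expect_equal(inductionTime(tr2), inductionTime(tr))
  expect_equal(frameInterval(tr2), frameInterval(tr))
  ## a second write is byte-identical (stable serialization)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeTrackingTable(tr2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid forests are rejected at construction", {
  tr <- threeGenTree()
  ce <- cellTable(tr); sa <- sampleTable(tr)
  ## two founders
  ce2 <- ce; ce2$parent_id[2] <- NA
  expect_error(lineageTree(ce2, sa), "founder")
  ## divided cell with one child
  ce3 <- ce; ce3 <- ce3[ce3$cell_id != "a", ]
  expect_error(lineageTree(ce3, sa[sa$cell_id != "a", ]), "2 children")
  ## daughter birth not at mother's end
  ce4 <- ce; ce4$birth_time[ce4$cell_id == "ba"] <- 21
  expect_error(lineageTree(ce4, sa), "birth_time")
})

test_that("Newick export carries topology, lifetimes and end states", {
  tr <- threeGenTree()
  nwk <- exportNewick(tr)
  expect_match(nwk, "\\[&end_state=divided\\]")
  expect_match(nwk, "ba\\[&end_state=censored\\]:10")
  skip_if_not_installed("ape")
  plain <- gsub("\\[[^]]*\\]", "", nwk)
  phy <- ape::read.tree(text = plain)
  expect_setequal(phy$tip.label, c("a", "ba", "bb"))
  ## branch lengths are lifetimes in minutes
  expect_equal(sort(phy$edge.length),
               sort(c(20, 10, 10, 10)))  # a, b, ba, bb
})
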