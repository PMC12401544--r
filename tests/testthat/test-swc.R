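make_records <- function() {
  data.frame(id = c(1L, 2L, 3L, 4L), type = 2L,
             x = c(0, 1, 2, 2), y = c(0, 0, 0.5, -0.5), z = c(0, 0, 0, 0),
             radius = 3, parent = c(-1L, 1L, 2L, 2L))
}

test_that("SWC write/read round trip is exact", {
  rec <- make_records()
  path <- tempfile(fileext = ".swc")
  write_swc(rec, path)
  back <- read_swc(path)
  expect_equal(back, rec)
  unlink(path)
})

test_that("SWC reader ignores comments and blank lines", {
  path <- tempfile(fileext = ".swc")
  writeLines(c("# header", "", "1 2 0 0 0 3 -1", "  # indented comment",
               "2 2 1 0 0 3 1"), path)
  rec <- read_swc(path)
  expect_equal(rec$id, c(1L, 2L))
  expect_equal(rec$parent, c(-1L, 1L))
  unlink(path)
})

test_that("SWC validation rejects malformed inputs", {
  path <- tempfile(fileext = ".swc")
  writeLines("1 2 0 0 0 3", path)                       # 6 columns
  expect_error(read_swc(path), "malformed")
  writeLines(c("1 2 0 0 0 3 -1", "1 2 1 0 0 3 1"), path) # duplicate id
  expect_error(read_swc(path), "unique")
  writeLines(c("1 2 0 0 0 3 5"), path)                   # dangling parent
  expect_error(read_swc(path), "missing id")
  writeLines(c("1 2 0 0 0 3 2", "2 2 1 0 0 3 1"), path)  # cycle
  expect_error(read_swc(path), "cycle")
  unlink(path)
})

test_that("trees round trip through SWC records", {
  rec <- make_records()
  trees <- pointneurite:::swc_to_trees(rec)
  expect_length(trees, 1)
  expect_equal(nrow(trees[[1]]$pos), 4)
  rec2 <- pointneurite:::trees_to_swc(trees, radius = 3)
  expect_equal(nrow(rec2), 4)
  expect_equal(sum(rec2$parent == -1), 1)
  # same point set
  expect_equal(sort(rec2$x), sort(rec$x))
})

test_that("reconstruction_to_swc writes a readable file", {
  tr <- neurite_tree(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                     head = c(0L, 1L, 2L), left = c(2L, 3L, 0L),
                     right = c(0L, 0L, 0L))
  path <- tempfile(fileext = ".swc")
  reconstruction_to_swc(list(tr), path, radius = 2)
  rec <- read_swc(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$radius, rep(2, 3))
  unlink(path)
})
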