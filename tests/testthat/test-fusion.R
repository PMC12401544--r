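chain_tree_f <- function(pos) {
  n <- nrow(pos)
  neurite_tree(pos, head = c(0L, seq_len(n - 1)),
               left = c(seq_len(n - 1) + 1L, 0L), right = integer(n))
}

test_that("boundary extraction keeps only terminals near the face", {
  a <- chain_tree_f(cbind(100:120, 50, 50))   # terminal at x = 120 near face
  b <- chain_tree_f(cbind(0:40, 10, 10))      # nowhere near the face
  face <- list(axis = 1, coord = 128)
  bn <- extract_boundary_nodes(list(a, b), face, margin = 10)
  expect_equal(nrow(bn), 1)
  expect_equal(bn$tree, 1)
  expect_equal(bn$x, 120)
  # the fitted direction lies along the chain (x axis)
  expect_gt(abs(bn$dx), 0.99)
  # empty input gives an empty frame with the documented columns
  e <- extract_boundary_nodes(list(), face)
  expect_equal(nrow(e), 0)
  expect_true(all(c("tree", "node", "x", "dx") %in% names(e)))
})

test_that("cost formula is gap * (2 - |cos|) with auxiliary threshold 20", {
  cfg <- pn_config()$fusion
  expect_equal(cfg$auxiliary_cost, 20)
  # aligned pair 6 apart across the face: cost 6 * (2 - 1) = 6 < 20 -> joined
  a <- chain_tree_f(cbind(103:125, 50, 50))
  b <- chain_tree_f(cbind(131:153, 50, 50))
  face <- list(axis = 1, coord = 128)
  fused <- fuse_adjacent_blocks(list(a), list(b), face, mift = FALSE)
  expect_length(fused, 1)
  expect_equal(nrow(fused[[1]]$pos), 46)
  # far-apart boundary terminals: minimum cost 25 * (2 - 1) = 25 > 20 -> kept
  c2 <- chain_tree_f(cbind(131:153, 75, 50))
  fused2 <- fuse_adjacent_blocks(list(a), list(c2), face, mift = FALSE)
  expect_length(fused2, 2)
})

test_that("parallel tubes crossing the face do not swap partners", {
  # two parallel chains on each side, 10 apart; collinear continuation must
  # win over the diagonal swap
  mk <- function(y, xs) chain_tree_f(cbind(xs, y, 50))
  left <- list(mk(40, 100:126), mk(50, 100:126))
  right <- list(mk(40, 130:156), mk(50, 130:156))
  face <- list(axis = 1, coord = 128)
  fused <- fuse_adjacent_blocks(left, right, face, mift = FALSE)
  expect_length(fused, 2)
  for (tr in fused) {
    expect_lt(diff(range(tr$pos[, 2])), 1)   # each tree stays at one y
    expect_equal(diff(range(tr$pos[, 1])), 56)
  }
})

test_that("block-grid fusion stitches a straight tube split across blocks", {
  sp <- phantom_spec(shape = c(128, 64, 64), n_neurites = 2, rng_seed = 13)
  ph <- generate_phantom(sp)
  blocks <- reconstruct_blocks(ph$skeleton,
                               list(c(0L, 0L, 0L), c(64L, 0L, 0L)),
                               c(64, 64, 64))
  fused <- fuse_block_grid(blocks)
  ev <- evaluate_reconstruction(fused, ph$skeleton)
  expect_gt(ev$weighted$f1, 0.9)
})
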