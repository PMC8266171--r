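vv_defaults <- function(...) {
  v <- default_config(2)$vasa_vasorum
  utils::modifyList(v, list(...))
}

test_that("2D tree: segment count by enumeration and unit-ratio lengths", {
  v <- vv_defaults(jitter = 0)
  set.seed(1)
  tr <- generate_tree_2d(v, anchor = c(40, 0), inward_direction = c(-1, 0))
  # binary branching through levels 2..4: 1 + 2 + 4 + 8 segments
  expect_equal(nrow(tr$segments), 1 + 2 + 4 + 8)
  expect_equal(as.vector(table(tr$segments$level)), c(1, 2, 4, 8))
  # lambda_k = 1, jitter = 0: every segment has the trunk length 3 um
  len <- sqrt((tr$segments$x1 - tr$segments$x0)^2 +
                (tr$segments$y1 - tr$segments$y0)^2)
  expect_equal(len, rep(3, 15), tolerance = 1e-12)
  # trunk only
  v1 <- vv_defaults(jitter = 0, n_levels = 1L)
  tr1 <- generate_tree_2d(v1, c(40, 0), c(-1, 0))
  expect_equal(nrow(tr1$segments), 1L)
})

test_that("branch lengths scale by lambda_k relative to the parent", {
  v <- vv_defaults(jitter = 0, lambda = c(0.8, 0.6, 0.5))
  tr <- generate_tree_2d(v, c(40, 0), c(-1, 0))
  len <- sqrt((tr$segments$x1 - tr$segments$x0)^2 +
                (tr$segments$y1 - tr$segments$y0)^2)
  expect_equal(unique(round(len[tr$segments$level == 2], 9)), 3 * 0.8)
  expect_equal(unique(round(len[tr$segments$level == 3], 9)), 3 * 0.8 * 0.6)
  expect_equal(unique(round(len[tr$segments$level == 4], 9)),
               3 * 0.8 * 0.6 * 0.5)
})

test_that("3D tree: one branching level gives 1+3 segments at the elevation angle", {
  v <- vv_defaults(jitter = 0, n_levels = 2L)
  tr <- generate_tree_3d(v, anchor = c(40, 0, 50), inward_direction = c(-1, 0, 0))
  expect_equal(nrow(tr$segments), 4L)
  for (k in 2:4) {
    d <- as.numeric(tr$segments[k, 4:6] - tr$segments[k, 1:3])
    d <- d / sqrt(sum(d^2))
    expect_equal(acos(sum(d * c(-1, 0, 0))), pi / 2 - pi / 3,
                 tolerance = 1e-12)
  }
})

test_that("tree generation is deterministic for a fixed seed", {
  v <- vv_defaults()
  set.seed(7); a <- generate_tree_2d(v, c(40, 0), c(-1, 0))
  set.seed(7); b <- generate_tree_2d(v, c(40, 0), c(-1, 0))
  expect_identical(a, b)
  cfg <- default_config(2); cfg$vasa_vasorum$enabled <- TRUE
  cfg$geometry$h <- 2.5
  mesh <- make_annulus_mesh(cfg$geometry)
  t1 <- generate_vv_network(cfg, mesh)
  t2 <- generate_vv_network(cfg, mesh)
  expect_identical(t1, t2)
})

test_that("network trees stay inside the outer half of the wall", {
  cfg <- default_config(2); cfg$geometry$h <- 2.5
  mesh <- make_annulus_mesh(cfg$geometry)
  trees <- generate_vv_network(cfg, mesh)
  segs <- do.call(rbind, lapply(trees, function(t) t$segments))
  r <- c(sqrt(segs$x0^2 + segs$y0^2), sqrt(segs$x1^2 + segs$y1^2))
  r_mid <- (mesh$r_in + mesh$r_out) / 2
  expect_true(all(r >= r_mid - 1e-9))
  expect_true(all(r <= mesh$r_out + 1e-9))
  expect_length(trees, cfg$vasa_vasorum$n_trees)
})

test_that("cut-element tagging matches the brute-force all-pairs oracle", {
  cfg <- default_config(2); cfg$geometry$h <- 2.5
  mesh <- make_annulus_mesh(cfg$geometry)
  trees <- generate_vv_network(cfg, mesh)
  tags <- tag_cut_elements(mesh, trees)
  segs <- do.call(rbind, lapply(trees, function(t) t$segments))
  oracle <- which(vapply(seq_len(nrow(mesh$elems)), function(e) {
    quad <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (s in seq_len(nrow(segs))) {
      if (seg_quad_intersects(c(segs$x0[s], segs$y0[s]),
                              c(segs$x1[s], segs$y1[s]), quad)) return(TRUE)
    }
    FALSE
  }, logical(1)))
  expect_setequal(tags, oracle)
  expect_gt(length(tags), 0)
})

test_that("tagging is endpoint- and boundary-inclusive", {
  cfg <- default_config(2); cfg$geometry$h <- 2.5
  mesh <- make_annulus_mesh(cfg$geometry)
  # a short segment strictly inside one element tags exactly that element
  e <- 10L
  ctr <- colMeans(mesh$nodes[mesh$elems[e, ], ])
  tr <- structure(list(segments = data.frame(
    x0 = ctr[1] - 0.1, y0 = ctr[2], x1 = ctr[1] + 0.1, y1 = ctr[2],
    level = 1), anchor = ctr, dim = 2L), class = "fractal_tree")
  expect_equal(tag_cut_elements(mesh, tr), e)
  # a segment along a shared radial facet tags both adjacent elements
  n1 <- mesh$elems[e, 1]; n2 <- mesh$elems[e, 2] # radial edge of element e
  p1 <- mesh$nodes[n1, ]; p2 <- mesh$nodes[n2, ]
  tr2 <- structure(list(segments = data.frame(
    x0 = p1[1], y0 = p1[2], x1 = p2[1], y1 = p2[2], level = 1),
    anchor = p1, dim = 2L), class = "fractal_tree")
  tags <- tag_cut_elements(mesh, tr2)
  expect_true(e %in% tags)
  expect_gte(length(tags), 2)
  # empty tree
  tr0 <- structure(list(segments = data.frame(), anchor = p1, dim = 2L),
                   class = "fractal_tree")
  expect_length(tag_cut_elements(mesh, tr0), 0)
})

test_that("tagged area shrinks toward a tube neighbourhood under refinement", {
  cfg <- default_config(2)
  v <- cfg$vasa_vasorum
  set.seed(3)
  tr <- generate_tree_2d(v, c(40, 0), c(-1, 0), r_clip = c(32.5, 40))
  areas <- sapply(c(5, 2.5, 1.25), function(h) {
    m <- make_annulus_mesh(utils::modifyList(cfg$geometry, list(h = h)))
    tags <- tag_cut_elements(m, tr)
    sum(element_volumes(m)[tags])
  })
  # non-increase beyond a factor ~2 between successive refinements
  expect_lt(areas[2], 2 * areas[1])
  expect_lt(areas[3], 2 * areas[2])
  expect_lt(areas[3], areas[1])
})
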