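test_that("registry expands subjects x wrists x sessions deterministically", {
  reg <- make_registry(160, 2, seed = 5)
  expect_equal(nrow(reg), 640)
  expect_equal(nrow(make_registry(1, 1, 0)), 2)
  expect_setequal(unique(reg$wrist), c("left", "right"))
  expect_identical(make_registry(10, 2, 7), make_registry(10, 2, 7))
  expect_error(make_registry(0, 2, 1), "positive")
  expect_error(make_registry(3, 0, 1), "positive")
})

test_that("adding subjects never perturbs existing registry rows", {
  a <- make_registry(5, 2, seed = 3)
  b <- make_registry(9, 2, seed = 3)
  expect_equal(a, b[seq_len(nrow(a)), ], ignore_attr = TRUE)
})

test_that("vein trees are reproducible, branched, long enough and contained", {
  spec <- subject_spec("s1", "left", 1234)
  t1 <- grow_vein_tree(spec, c(128, 128))
  expect_identical(t1, grow_vein_tree(spec, c(128, 128)))
  expect_gte(tree_branch_points(t1), 2)
  expect_gte(tree_length(t1), 0.5 * 128)
  expect_true(all(t1$nodes >= 0 & t1$nodes[, 1] < 128 & t1$nodes[, 2] < 128))
  expect_error(grow_vein_tree(spec, c(32, 32)), "64")
})

test_that("tree radii taper from root to leaves", {
  tr <- grow_vein_tree(subject_spec("s2", "right", 88), c(128, 128))
  # along every root-to-leaf path the per-edge radius is non-increasing
  for (e in seq_len(nrow(tr$edges))) {
    parent_edge <- which(tr$edges[, 2] == tr$edges[e, 1])
    if (length(parent_edge))
      expect_lte(tr$radii[e], tr$radii[parent_edge] + 1e-12)
  }
})

test_that("different subjects give dissimilar masks (Dice < 0.5)", {
  for (k in 1:20) {
    ma <- rasterize_tree(grow_vein_tree(subject_spec("a", "left", 2 * k), c(128, 128)))
    mb <- rasterize_tree(grow_vein_tree(subject_spec("b", "left", 2 * k + 1), c(128, 128)))
    expect_lt(dice_coefficient(ma, mb), 0.5)
  }
})

test_that("degenerate scene renders a constant image with the mask intact", {
  fx <- fixture_scene()
  p0 <- scene_params(gradient_amp = 0, vein_contrast = 0, noise_sigma = 0,
                     blur_sigma = 0)
  out <- render_session(fx$tree, p0, 1, jitter = FALSE)
  expect_equal(length(unique(as.numeric(out$image))), 1)
  expect_identical(out$mask, rasterize_tree(fx$tree))
})

test_that("rendered sessions stay in range with a binary, aligned mask", {
  fx <- fixture_scene()
  out <- fx$session
  expect_true(all(out$image >= 0 & out$image <= 255))
  expect_true(all(out$mask %in% c(0, 1)))
  expect_true(mean(out$mask) > 0.005)
})

test_that("same tree re-registered across sessions overlaps (Dice > 0.6)", {
  fx <- fixture_scene()
  r1 <- render_session(fx$tree, scene_params(), 21)
  r2 <- render_session(fx$tree, scene_params(), 22)
  m1 <- apply_affine(r1$mask, invert_affine(r1$jitter), "nearest")
  m2 <- apply_affine(r2$mask, invert_affine(r2$jitter), "nearest")
  expect_gt(dice_coefficient(m1, m2), 0.6)
})

test_that("mask pixel fraction stays in [0.02, 0.25] under default params", {
  fr <- vapply(1:50, function(k) {
    tr <- grow_vein_tree(subject_spec(paste0("f", k), "left", 500 + k), c(256, 256))
    mean(render_session(tr, scene_params(), k)$mask)
  }, numeric(1))
  expect_true(all(fr >= 0.02 & fr <= 0.25))
})

test_that("genuine pairs beat impostor pairs in mean mask Dice", {
  trees <- lapply(1:25, function(k)
    grow_vein_tree(subject_spec(paste0("g", k), "left", 900 + k), c(128, 128)))
  p <- scene_params()
  gen <- imp <- numeric(100)
  set.seed(1)
  for (k in 1:100) {
    tr <- trees[[(k %% 25) + 1]]
    gen[k] <- dice_coefficient(render_session(tr, p, 3000 + k)$mask,
                               render_session(tr, p, 4000 + k)$mask)
    ab <- sample(25, 2)
    imp[k] <- dice_coefficient(render_session(trees[[ab[1]]], p, 5000 + k)$mask,
                               render_session(trees[[ab[2]]], p, 6000 + k)$mask)
  }
  expect_gt(mean(gen), mean(imp))
})

test_that("vein centrelines are intensity minima across the vessel", {
  # noiseless render, no jitter: at each edge midpoint the pixel is darker
  # than its two neighbours two pixels away along the vessel normal
  # (tolerance one gray level for half-pixel rasterisation offsets)
  fx <- fixture_scene()
  out <- render_session(fx$tree, scene_params(noise_sigma = 0), 3, jitter = FALSE)
  tr <- fx$tree
  vessel <- rasterize_tree(tr)
  n_checked <- 0
  for (e in seq_len(nrow(tr$edges))) {
    p0 <- tr$nodes[tr$edges[e, 1], ]; p1 <- tr$nodes[tr$edges[e, 2], ]
    mid <- round((p0 + p1) / 2) + 1
    off <- ceiling(tr$radii[e]) + 1
    v <- p1 - p0; nv <- c(-v[2], v[1]) / sqrt(sum(v^2))
    q1 <- round(mid + off * nv); q2 <- round(mid - off * nv)
    pts <- rbind(mid, q1, q2)
    if (any(pts < 3) || any(pts > 126)) next
    # probe points must sit on skin, not inside this or another vessel
    if (vessel[q1[1], q1[2]] == 1 || vessel[q2[1], q2[2]] == 1) next
    n_checked <- n_checked + 1
    expect_lte(out$image[mid[1], mid[2]],
               min(out$image[q1[1], q1[2]], out$image[q2[1], q2[2]]) + 1)
  }
  expect_gt(n_checked, 20)
})

test_that("full dataset generation is deterministic and writes the layout", {
  d1 <- synthesize_dataset(2, 2, seed = 42, dim = c(64, 64))
  d2 <- synthesize_dataset(2, 2, seed = 42, dim = c(64, 64))
  expect_identical(d1, d2)
  root <- withr::local_tempdir()
  d3 <- synthesize_dataset(1, 2, seed = 8, dim = c(64, 64), dir = root)
  expect_true(file.exists(file.path(root, "registry.csv")))
  expect_true(all(file.exists(d3$registry$image_path)))
  expect_true(all(file.exists(d3$registry$mask_path)))
  expect_identical(read_mask(d3$registry$mask_path[1]), d3$masks[[1]])
  expect_equal(read_vein_image(d3$registry$image_path[1]), d3$images[[1]])
})
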