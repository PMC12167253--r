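test_that("tree generation is deterministic and honors the zero-tortuosity case", {
  a <- generate_tree(seed = 1L)
  b <- generate_tree(seed = 1L)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$radius, b$radius)

  straight <- generate_tree(tree_params(tortuosity_amplitude = 0), seed = 7L)
  trunk <- straight$nodes[straight$branch == "trunk", ]
  # all interior trunk points collinear with the endpoints
  d <- trunk[nrow(trunk), ] - trunk[1L, ]
  cross <- abs(d[1] * (trunk[, 2] - trunk[1, 2]) -
                 d[2] * (trunk[, 1] - trunk[1, 1])) / sqrt(sum(d^2))
  expect_lt(max(cross), 1e-9)
})

test_that("generated trees satisfy the structural invariants across 100 seeds", {
  for (s in 1:100) {
    side <- if (s %% 2) "right" else "left"
    tree <- generate_tree(tree_params(side = side), seed = s)
    expect_silent(validate_tree(tree))
  }
})

test_that("invalid tree parameters raise errors naming the field", {
  expect_error(generate_tree(tree_params(trunk_length = -1)), "trunk_length")
  expect_error(generate_tree(tree_params(bifurcation_angle = 190)),
               "bifurcation_angle")
  expect_error(generate_tree(tree_params(trunk_radius = 0)), "trunk_radius")
})

test_that("target sampling is uniform over ten candidates and side-consistent", {
  tree <- default_tree(3L)
  draws <- vapply(1:10000, function(s) {
    sample_target(tree, seed = s)$centerline_index
  }, integer(1))
  freq <- tabulate(draws + 1L, nbins = 10L) / 10000
  expect_true(all(freq >= 0.08 & freq <= 0.12))
  # chi-square goodness of fit against the uniform law
  expect_gt(chisq.test(tabulate(draws + 1L, nbins = 10L))$p.value, 1e-4)

  right <- sample_target(default_tree(4L, "right"), seed = 1L)
  left <- sample_target(default_tree(5L, "left"), seed = 1L)
  expect_identical(right$branch_side, "right")
  expect_identical(left$branch_side, "left")

  single <- vapply(1:20, function(s) {
    sample_target(tree, n_points = 1L, seed = s)$node
  }, integer(1))
  expect_length(unique(single), 1L)
})

test_that("scaling augmentation acts about the root and preserves structure", {
  tree <- default_tree(6L)
  expect_equal(augment_scale(tree, 1, 1)$nodes, tree$nodes)

  sc <- augment_scale(tree, 1.3, 0.7)
  bb0 <- apply(tree$nodes, 2, function(x) diff(range(x)))
  bb1 <- apply(sc$nodes, 2, function(x) diff(range(x)))
  expect_equal(bb1, bb0 * c(1.3, 0.7), tolerance = 1e-9)
  expect_identical(sc$branch, tree$branch)
  expect_equal(sc$radius, tree$radius * 1.0)

  expect_error(augment_scale(tree, 0.5, 1), "0.7")
  expect_error(augment_scale(tree, 1, 1.5), "0.7")

  set.seed(42)
  for (i in 1:50) {
    s <- augment_scale(tree, runif(1, 0.7, 1.3), runif(1, 0.7, 1.3))
    expect_silent(validate_tree(s))
  }
})

test_that("geodesic distance matches coincidence, straight-line and Dijkstra oracles", {
  # straight single-branch tree of length 100
  st <- straight_tree(trunk_length = 60, branch_length = 40)
  tip <- structure(list(position = st$nodes[nrow(st$nodes), ],
                        branch_side = "right", centerline_index = 9L,
                        node = nrow(st$nodes)), class = "target_spec")
  expect_equal(geodesic_distance(st, tip$position, tip), 0)
  expect_equal(geodesic_distance(st, st$nodes[1L, ], tip), 100,
               tolerance = 1)

  # Y-tree: from the distractor branch, distance = back to bifurcation
  # plus bifurcation-to-target, checked against an independent Dijkstra
  tree <- default_tree(8L)
  target <- sample_target(tree, seed = 9L)
  distr <- which(tree$branch == "distractor_branch")
  probe <- distr[round(length(distr) / 2)]
  expect_equal(geodesic_distance(tree, tree$nodes[probe, ], target),
               dijkstra_to_target(tree, probe, target$node),
               tolerance = 1e-9)
})

test_that("geodesic distance is equivariant under isotropic scaling", {
  tree <- default_tree(10L)
  target <- sample_target(tree, seed = 11L)
  for (s in c(0.8, 1.0, 1.25)) {
    st <- augment_scale(tree, s, s)
    starget <- target
    root <- tree$nodes[1L, ]
    starget$position <- root + s * (target$position - root)
    p <- tree$nodes[40L, ]
    sp <- root + s * (p - root)
    expect_equal(geodesic_distance(st, sp, starget),
                 s * geodesic_distance(tree, p, target), tolerance = 1e-6)
  }
})

test_that("centerline files round-trip", {
  tree <- default_tree(12L)
  stem <- file.path(withr::local_tempdir(), "case")
  write_centerline(tree, stem)
  back <- read_centerline(paste0(stem, ".ctl.tsv"))
  expect_equal(back$nodes, tree$nodes, tolerance = 1e-6)
  expect_identical(back$branch, tree$branch)
  expect_identical(back$side, tree$side)
  expect_identical(back$seed, tree$seed)
  # writing the re-read tree reproduces the file byte for byte
  stem2 <- file.path(withr::local_tempdir(), "case2")
  write_centerline(back, stem2)
  expect_identical(readLines(paste0(stem, ".ctl.tsv")),
                   readLines(paste0(stem2, ".ctl.tsv")))
})

test_that("case sets alternate sides and split into train/test", {
  trees <- generate_case_set(12L, seed = 2L)
  expect_length(trees, 12L)
  expect_identical(vapply(trees, function(t) t$side, character(1)),
                   rep(c("right", "left"), 6L))
  sp <- split_cases(trees, 2L)
  expect_length(sp$train, 10L)
  expect_length(sp$test, 2L)
})
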