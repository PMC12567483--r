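test_that("pose RMSD handles identity, translation, and mismatches", {
  p <- toy_pose(6, seed = 1)
  expect_equal(pose_rmsd(p, p), 0.0)
  q <- pose(sweep(p$coords, 2, c(2, 0, 0), "+"), p$elements, ea = -7)
  expect_equal(pose_rmsd(p, q), 2.0)
  expect_error(pose_rmsd(p, toy_pose(5, seed = 2)), "atom-count mismatch")
  expect_error(pose_rmsd(p, toy_pose(6, elements = rep("N", 6), seed = 3)),
               "element multisets differ")
})

test_that("symmetry-aware RMSD equals the brute-force automorphism minimum", {
  ref <- hexagon_pose()
  # relabel the ring by a rotation: plain order differs, symmetry fixes it
  rot <- hexagon_pose(perm = c(2, 3, 4, 5, 6, 1))
  expect_gt(pose_rmsd(ref, rot, symmetry_aware = FALSE) /
              max(pose_rmsd(ref, rot, symmetry_aware = TRUE), 1e-15), 1e6)
  expect_equal(pose_rmsd(ref, rot, symmetry_aware = TRUE), 0.0, tolerance = 1e-9)

  # jittered + relabeled ring vs exhaustive permutation oracle
  set.seed(4)
  jit <- ref$coords + matrix(rnorm(18, 0, 0.1), 6)
  moved <- pose(jit[c(3, 4, 5, 6, 1, 2), ], rep("C", 6), ea = -7,
                bonds = ref$bonds)
  got <- pose_rmsd(moved, ref, symmetry_aware = TRUE)
  adj <- matrix(FALSE, 6, 6)
  for (k in 1:6) { adj[k, k %% 6 + 1] <- TRUE; adj[k %% 6 + 1, k] <- TRUE }
  best <- Inf
  for (pm in asplit(gtools_perms <- do.call(rbind, combinat_perms <- {
    # all 720 permutations of 1:6, base R
    p <- list(1L)
    for (n in 2:6) p <- unlist(lapply(p, function(v)
      lapply(0:(n - 1), function(k) append(v, n, after = k))), recursive = FALSE)
    p
  }), 1)) {
    pm <- as.integer(pm)
    # keep only graph automorphisms of the ring
    ok <- TRUE
    for (k in 1:6) if (!adj[pm[k], pm[k %% 6 + 1]]) { ok <- FALSE; break }
    if (!ok) next
    best <- min(best, sqrt(mean(rowSums((moved$coords[pm, ] - ref$coords)^2))))
  }
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("pose RMSD is a pseudometric on random triples", {
  set.seed(9)
  for (i in 1:25) {
    a <- toy_pose(7); b <- toy_pose(7); c <- toy_pose(7)
    dab <- pose_rmsd(a, b); dba <- pose_rmsd(b, a)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_gte(dab, 0)
    expect_lte(pose_rmsd(a, c), dab + pose_rmsd(b, c) + 1e-9)
  }
})

test_that("best-pose selection applies both cuts and picks the lowest energy", {
  ref <- toy_pose(5, seed = 10)
  near <- function(ea, shift, run = 1L, idx = 1L)
    pose(sweep(ref$coords, 2, c(shift, 0, 0), "+"), ref$elements, ea = ea,
         run = run, index = idx)

  # none below -6.0 kcal/mol: rejected
  res <- select_best_pose(list(near(-5.0, 0.5), near(-5.5, 0.3)), ref)
  expect_identical(res$verdict, "rejected")
  expect_null(res$best)

  # only the pose passing both cuts survives
  res2 <- select_best_pose(list(near(-7.0, 1.0), near(-9.0, 3.0)), ref)
  expect_identical(res2$verdict, "accepted")
  expect_equal(res2$best$ea, -7.0)
  expect_lt(res2$best_rmsd, 2.0)

  expect_error(select_best_pose(list()), "empty pose set")
})

test_that("selection equals brute force and ignores pose order", {
  ref <- toy_pose(5, seed = 20)
  set.seed(21)
  poses <- lapply(1:100, function(i)
    pose(ref$coords + matrix(rnorm(15, 0, runif(1, 0.05, 2)), 5),
         ref$elements, ea = runif(1, -11, -4), run = (i - 1L) %/% 20 + 1L,
         index = (i - 1L) %% 20 + 1L))
  res <- select_best_pose(poses, ref, symmetry_aware = FALSE)
  # brute force: filter then argmin
  ea <- vapply(poses, `[[`, numeric(1), "ea")
  rmsd <- vapply(poses, function(p) sqrt(mean(rowSums((p$coords - ref$coords)^2))),
                 numeric(1))
  keep <- which(ea < -6 & rmsd < 2)
  expect_identical(res$verdict, if (length(keep)) "accepted" else "rejected")
  expect_equal(res$best$ea, min(ea[keep]))
  shuf <- sample(length(poses))
  res2 <- select_best_pose(poses[shuf], ref, symmetry_aware = FALSE)
  expect_equal(res2$best$coords, res$best$coords)
  expect_equal(res2$best$ea, res$best$ea)
})

test_that("grid boxes report the inside fraction with half-open faces", {
  box <- grid_box(c(0, 0, 0), c(10, 10, 10))
  inside <- pose(matrix(c(0, 0, 0, 1, 1, 1), 2, byrow = TRUE), c("C", "C"))
  expect_equal(gridbox_contains(box, inside), 1.0)
  outside <- pose(matrix(c(50, 50, 50), 1), "C")
  expect_equal(gridbox_contains(box, outside), 0.0)
  # min face inside, max face outside
  faces <- pose(matrix(c(-5, 0, 0, 5, 0, 0), 2, byrow = TRUE), c("C", "C"))
  expect_equal(gridbox_contains(box, faces), 0.5)
  expect_error(grid_box(c(0, 0, 0), c(-1, 10, 10)), "positive")

  boxes <- default_grid_boxes()
  expect_equal(boxes[["2IKH"]]$center, c(14.17, -0.095, 23.464))
  expect_equal(boxes[["2IKH"]]$dims, c(60, 40, 56))
  expect_equal(boxes[["4IXC"]]$center, c(63.267, 25.856, 0.231))
  expect_equal(boxes[["4IXC"]]$dims, c(66, 72, 66))
  yml <- read_grid_boxes(extdata("grid_boxes.yaml"))
  expect_equal(yml[["4IXC"]]$dims, c(66, 72, 66))
})

test_that("SDF pose records carry coordinates and the E_A data field", {
  m <- parse_structure("CCO", id = "p1")
  mf <- sub("\\$\\$\\$\\$", "> <E_A>\n-7.5\n\n$$$$", m$molfile)
  f <- tempfile(fileext = ".sdf")
  writeLines(mf, f)
  p <- read_sdf_poses(f)
  expect_length(p, 1L)
  expect_equal(p[[1]]$ea, -7.5)
  expect_identical(p[[1]]$elements, c("C", "C", "O"))
  expect_identical(nrow(p[[1]]$bonds), 2L)
})

test_that("Vina-style PDBQT poses parse with energies and elements", {
  poses <- read_pdbqt_poses(extdata("vina_poses_example.pdbqt"))
  expect_length(poses, 2L)
  expect_equal(poses[[1]]$ea, -8.598)
  expect_equal(poses[[2]]$ea, -5.200)
  expect_identical(poses[[1]]$elements, c("C", "C", "N", "O"))
  expect_equal(poses[[1]]$coords[1, ], c(14.2, 0.1, 23.5))
  # redock gate on the parsed pool: the -8.598 pose validates the protocol
  res <- select_best_pose(poses, reference = poses[[1]],
                          symmetry_aware = FALSE)
  expect_identical(res$verdict, "accepted")
  expect_equal(res$best$ea, -8.598)
})
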