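# Procrustes superposition, pose similarity measures and clique clustering.

test_that("kabsch recovers known rigid transforms", {
  set.seed(1)
  x <- matrix(rnorm(30, sd = 5), ncol = 3)
  # identity
  fit <- kabsch(x, x)
  expect_equal(fit$rot, diag(3), tolerance = 1e-10)
  expect_equal(fit$shift, c(0, 0, 0), tolerance = 1e-10)
  # 90 degrees about z plus a shift
  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  y <- x %*% t(rot90) + matrix(c(1, 2, 3), nrow(x), 3, byrow = TRUE)
  fit <- kabsch(x, y)
  moved <- x %*% t(fit$rot) + matrix(fit$shift, nrow(x), 3, byrow = TRUE)
  expect_lt(sqrt(mean(rowSums((moved - y)^2))), 1e-8)
  expect_equal(det(fit$rot), 1, tolerance = 1e-10)
})

test_that("kabsch agrees with an independent superposition on a fixture", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  x <- matrix(rnorm(24, sd = 4), ncol = 3)
  tr <- random_rigid_transform()
  y <- transform_points(x, tr)
  fit <- kabsch(x, y)
  moved <- transform_points(x, fit)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(y)), mobile = as.numeric(t(x))))
  expect_equal(moved, matrix(as.numeric(ref), ncol = 3, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("kabsch refuses degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))   # collinear
  expect_error(kabsch(line, line + 1), "degenerate")
  expect_error(kabsch(matrix(0, 4, 3), matrix(1, 4, 3)), "degenerate")
})

test_that("superpose_poses aligns reference subunits and errors on mismatch", {
  sim <- simulate_dimer_poses(n_clusters = 1, poses_per_cluster = 3,
                              noise_sd = 0, seed = 2)
  sup <- superpose_poses(sim$poses, "P01")
  expect_identical(attr(sup, "superposed_on"), "P01")
  for (p in sup)
    expect_lt(max(abs(p$ref - sup[["P01"]]$ref)), 1e-8)
  bad <- sim$poses
  bad[[2]]$ref <- bad[[2]]$ref[-1, ]
  expect_error(superpose_poses(bad, "P01"), "P02")
  expect_error(superpose_poses(sim$poses, "nope"), "not found")
})

test_that("pose_angle matches hand geometry", {
  mk <- function(center) {
    off <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, -1, -1, -1), ncol = 3,
                  byrow = TRUE) * 0.1
    dimer_pose("p", ref = diag(3) * 5,
               mob = sweep(off, 2, center, "+"))
  }
  v <- c(0, 0, 0)
  expect_equal(pose_angle(mk(c(5, 0, 0)), mk(c(5, 0, 0)), v), 0)
  expect_equal(pose_angle(mk(c(1, 0, 0)), mk(c(0, 1, 0)), v), 90)
  expect_equal(pose_angle(mk(c(1, 0, 0)), mk(c(-1, 0, 0)), v), 180)
  expect_error(pose_angle(mk(c(0, 0, 0)), mk(c(1, 0, 0)), v), "coincides")
})

test_that("pose_min_correlation matches per-axis Pearson formulas", {
  a <- matrix(c(0, 0, 0,  1, 2, 1,  2, 1, 3,  3, 4, 2), ncol = 3,
              byrow = TRUE)
  p1 <- dimer_pose("a", ref = diag(3) * 5, mob = a)
  expect_equal(pose_min_correlation(p1, p1), 1)
  # mirror through the centroid on y: y-correlation -1
  b <- a
  b[, 2] <- 2 * mean(a[, 2]) - a[, 2]
  p2 <- dimer_pose("b", ref = diag(3) * 5, mob = b)
  expect_equal(pose_min_correlation(p1, p2), -1)
  # generic 4-atom case against cor() per axis
  set.seed(3)
  c_ <- a + matrix(rnorm(12), ncol = 3)
  p3 <- dimer_pose("c", ref = diag(3) * 5, mob = c_)
  expect_equal(pose_min_correlation(p1, p3),
               min(cor(a[, 1], c_[, 1]), cor(a[, 2], c_[, 2]),
                   cor(a[, 3], c_[, 3])))
  # zero-variance axis: flat vs varying -> 0 with a warning
  flat <- a; flat[, 3] <- 2
  p4 <- dimer_pose("d", ref = diag(3) * 5, mob = flat)
  expect_warning(mc <- pose_min_correlation(p4, p3), "zero-variance")
  expect_equal(mc, 0)
  expect_warning(mc2 <- pose_min_correlation(p4, p4), "zero-variance")
  expect_equal(mc2, 1)
})

test_that("similarity requires both the angle and the correlation gate", {
  sim <- simulate_dimer_poses(n_clusters = 2, poses_per_cluster = 2,
                              noise_sd = 0, seed = 4)
  sup <- superpose_poses(sim$poses)
  s <- similarity_matrix(sup, angle_max = 45, corr_min = 0.5)
  ang <- attr(s, "angle"); co <- attr(s, "corr")
  expect_true(isSymmetric(ang))
  expect_true(isSymmetric(co))
  expect_true(s["P01", "P02"])            # same planted cluster
  expect_false(s["P01", "P03"])           # angle beyond threshold
  expect_gt(ang["P01", "P03"], 45)
  expect_false(any(diag(s)))
  # strict bounds: a perfect correlation does not exceed corr_min = 1,
  # and a zero angle is not below angle_max = 0
  expect_false(any(similarity_matrix(sup, angle_max = 45, corr_min = 1)))
  expect_false(any(similarity_matrix(sup, angle_max = 0, corr_min = 0.5)))
  expect_error(similarity_matrix(sim$poses), "superposed")
})

test_that("find_clusters reproduces hand-worked clique examples", {
  mk_sim <- function(n, pairs) {
    ids <- sprintf("p%02d", seq_len(n))
    m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (pr in pairs) m[pr[1], pr[2]] <- m[pr[2], pr[1]] <- TRUE
    m
  }
  # 3 mutually similar poses: below min_group, all unclustered
  tri <- mk_sim(3, list(c(1, 2), c(1, 3), c(2, 3)))
  cl <- find_clusters(tri, min_group = 4)
  expect_length(cl$clusters, 0)
  expect_length(cl$unclustered, 3)

  # two disjoint 5-cliques -> two clusters of 5
  m <- matrix(FALSE, 10, 10)
  m[1:5, 1:5] <- TRUE; m[6:10, 6:10] <- TRUE; diag(m) <- FALSE
  cl2 <- find_clusters(m, min_group = 4)
  expect_length(cl2$clusters, 2)
  expect_equal(sort(lengths(cl2$clusters)), c(5L, 5L))

  # two 4-cliques sharing 2 poses -> one merged cluster of 6
  m3 <- matrix(FALSE, 6, 6)
  m3[1:4, 1:4] <- TRUE
  m3[3:6, 3:6] <- TRUE
  diag(m3) <- FALSE
  cl3 <- find_clusters(m3, min_group = 4)
  expect_length(cl3$clusters, 1)
  expect_length(cl3$clusters[[1]], 6)
  expect_length(cl3$unclustered, 0)
})

test_that("find_clusters equals the brute-force clique-and-merge oracle", {
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(4:12, 1)
    s <- random_sim_matrix(n, runif(1, 0.2, 0.8))
    got <- find_clusters(s, min_group = 4)
    want <- oracle_clusters(s, min_group = 4)
    expect_identical(canon_clusters(got$clusters), canon_clusters(want))
    expect_setequal(c(unlist(got$clusters), got$unclustered), rownames(s))
  }
})

test_that("measures and clusters are invariant to a global rigid transform", {
  sim <- simulate_dimer_poses(n_clusters = 2, poses_per_cluster = 4,
                              n_singletons = 1, noise_sd = 0.2, seed = 12)
  sup1 <- superpose_poses(sim$poses)
  s1 <- similarity_matrix(sup1)
  set.seed(5)
  tr <- random_rigid_transform()
  moved <- dimer_poses(lapply(sim$poses, function(p) {
    p$ref <- transform_points(p$ref, tr)
    p$mob <- transform_points(p$mob, tr)
    p
  }))
  s2 <- similarity_matrix(superpose_poses(moved))
  expect_equal(attr(s1, "angle"), attr(s2, "angle"), tolerance = 1e-6)
  expect_equal(attr(s1, "corr"), attr(s2, "corr"), tolerance = 1e-6)
  expect_identical(s1 == TRUE, s2 == TRUE)
  expect_identical(canon_clusters(find_clusters(s1)$clusters),
                   canon_clusters(find_clusters(s2)$clusters))
})

test_that("representative choice is uniform, seeded and reproducible", {
  cl <- c("a", "b", "c", "d")
  expect_identical(pick_representative(cl, seed = 42),
                   pick_representative(cl, seed = 42))
  expect_identical(pick_representative("only", seed = 1), "only")
  expect_error(pick_representative(character(0)), "empty")
  draws <- vapply(1:10000, function(s) pick_representative(cl, seed = s),
                  character(1))
  freq <- table(draws) / 10000
  se3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_lt(max(abs(freq - 0.25)), se3)

  sim <- simulate_dimer_poses(n_clusters = 2, poses_per_cluster = 5,
                              seed = 1)
  cl2 <- find_clusters(similarity_matrix(superpose_poses(sim$poses)))
  withrep <- pick_representatives(cl2, seed = 3)
  expect_length(withrep$representatives, 2)
  expect_true(all(mapply(`%in%`, withrep$representatives,
                         withrep$clusters)))
  expect_identical(withrep$representatives,
                   pick_representatives(cl2, seed = 3)$representatives)
})

test_that("cluster reports are written as TSV", {
  d <- withr::local_tempdir()
  sim <- simulate_dimer_poses(n_clusters = 1, poses_per_cluster = 4,
                              n_singletons = 1, seed = 6)
  sup <- superpose_poses(sim$poses)
  s <- similarity_matrix(sup)
  cl <- pick_representatives(find_clusters(s), seed = 2)
  paths <- write_cluster_report(s, cl, d)
  expect_true(all(file.exists(paths)))
  meas <- read.delim(file.path(d, "pose_measures.tsv"))
  expect_equal(nrow(meas), choose(5, 2))
  expect_true(all(c("angle_deg", "min_axis_corr", "similar") %in%
                  names(meas)))
  assign_df <- read.delim(file.path(d, "clusters.tsv"))
  expect_setequal(assign_df$pose_id, names(sim$poses))
})
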