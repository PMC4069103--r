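test_that("trajectory constructor enforces its invariants", {
  top <- toy_topology()
  xyz <- matrix(rnorm(nrow(top) * 3), nrow(top), 3)
  tr <- trajectory(top, list(xyz, xyz + 1), frame_interval = 5)
  expect_s3_class(tr, "phstab_traj")
  expect_length(tr, 2)
  expect_equal(frame_times(tr), c(0, 5))

  expect_error(trajectory(top, list(xyz[-1, ])), "frame 1")
  expect_error(trajectory(top, list(), frame_interval = 5), "no frames")
  expect_error(trajectory(top, list(xyz), frame_interval = 0), "frame_interval")
  bad <- dplyr::mutate(top, resno = resno - 1L)
  expect_error(trajectory(bad, list(xyz)), "residue numbers")
})

test_that("tidy() gives the long per-atom per-frame view", {
  top <- toy_topology()
  xyz <- matrix(seq_len(nrow(top) * 3), nrow(top), 3)
  tr <- trajectory(top, list(xyz, xyz), frame_interval = 2)
  td <- tidy(tr)
  expect_equal(nrow(td), 2 * nrow(top))
  expect_equal(unique(td$time_ps), c(0, 2))
  expect_equal(td$x[td$frame == 2], xyz[, 1])
})

test_that("domain residue counts match the published partition", {
  part <- ecpa_domains()
  expect_identical(domain_residue_count(part, "Total"), 766L)
  expect_identical(domain_residue_count(part, "A1"), 147L)
  expect_identical(domain_residue_count(part, "A2"), 30L)
  expect_identical(domain_residue_count(part, "B1"), 302L)
  expect_identical(domain_residue_count(part, "B2"), 73L)
  expect_identical(domain_residue_count(part, "B3"), 161L)
  expect_error(domain_residue_count(part, "B9"), "unknown domain")

  single <- domain_partition(one = list(list("B", 5, 5)))
  expect_identical(domain_residue_count(single, "one"), 1L)
  expect_error(
    domain_partition(bad = list(list("B", 10, 5))),
    "start must be <= end"
  )
  expect_error(
    domain_partition(bad = list(list("B", 1, 10), list("B", 5, 20))),
    "overlapping"
  )
})

test_that("superpose recovers rigid motions and matches the quaternion oracle", {
  set.seed(11)
  pts <- matrix(rnorm(18), 6, 3)

  ident <- superpose(pts, pts)
  expect_equal(ident$rmsd, 0, tolerance = 1e-10)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-8)

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3) # 90 deg about z
  moved <- rigid_move(pts, rot90, c(1, 2, 3))
  sp <- superpose(moved, pts)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)

  for (rep in 1:25) {
    n <- sample(4:10, 1)
    a <- matrix(rnorm(3 * n), n, 3)
    b <- matrix(rnorm(3 * n), n, 3)
    expect_equal(superpose(a, b)$rmsd, quaternion_rmsd(a, b), tolerance = 1e-8)
  }

  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("rmsd_series matches analytic values and a frame-by-frame oracle", {
  top <- toy_topology()
  ref <- matrix(rnorm(nrow(top) * 3, sd = 4), nrow(top), 3)
  static <- trajectory(top, replicate(5, ref, simplify = FALSE))
  all_idx <- seq_len(nrow(top))
  s <- rmsd_series(static, measure = all_idx)
  expect_equal(s$rmsd, rep(0, 5), tolerance = 1e-10)

  # displace one atom by d, fitting on the remaining rigid atoms:
  # RMSD over all N atoms is d / sqrt(N)
  d <- 2.5
  n <- nrow(top)
  fr2 <- ref
  fr2[1, ] <- fr2[1, ] + c(d, 0, 0)
  tr <- trajectory(top, list(ref, fr2))
  s2 <- rmsd_series(tr, measure = all_idx, fit = 2:n)
  expect_equal(s2$rmsd[2], d / sqrt(n), tolerance = 1e-8)

  # random toy trajectory equals the direct per-frame superpose + RMS oracle
  set.seed(21)
  frames <- replicate(10, ref + matrix(rnorm(n * 3, sd = 0.5), n, 3),
    simplify = FALSE
  )
  tr3 <- trajectory(top, frames)
  got <- rmsd_series(tr3, measure = all_idx)$rmsd
  oracle <- vapply(frames, function(fr) quaternion_rmsd(fr, frames[[1]]), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-8)

  expect_error(rmsd_series(tr3, measure = integer(0)), "empty selection")
})

test_that("rmsd_series is invariant under rigid motion of all frames", {
  top <- toy_topology()
  n <- nrow(top)
  set.seed(31)
  frames <- replicate(6, matrix(rnorm(n * 3, sd = 3), n, 3), simplify = FALSE)
  tr <- trajectory(top, frames)
  base <- rmsd_series(tr, measure = seq_len(n))$rmsd
  for (k in 1:3) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 10)
    moved <- trajectory(top, lapply(frames, rigid_move, rot = rot, shift = shift))
    expect_equal(rmsd_series(moved, measure = seq_len(n))$rmsd, base,
      tolerance = 1e-6
    )
  }
})

test_that("rmsf_profile matches the direct definition and analytic cases", {
  top <- toy_topology()
  n <- nrow(top)
  ref <- matrix(rnorm(n * 3, sd = 5), n, 3)
  static <- trajectory(top, replicate(8, ref, simplify = FALSE))
  prof <- rmsf_profile(static, seq_len(n))
  expect_equal(prof$rmsf, rep(0, n), tolerance = 1e-10)

  # one atom alternating +/- d along x about its mean, alignment frozen
  d <- 1.7
  frames <- lapply(1:6, function(k) {
    fr <- ref
    fr[3, 1] <- fr[3, 1] + ifelse(k %% 2 == 0, d, -d)
    fr
  })
  tr <- trajectory(top, frames)
  prof2 <- rmsf_profile(tr, seq_len(n), align = FALSE)
  expect_equal(prof2$rmsf[3], d, tolerance = 1e-10)
  expect_equal(prof2$rmsf[-3], rep(0, n - 1), tolerance = 1e-10)

  # direct-definition oracle on a noisy trajectory (no alignment so the
  # reference computation is a plain mean/spread)
  set.seed(41)
  frames3 <- replicate(12, ref + matrix(rnorm(n * 3, sd = 0.3), n, 3),
    simplify = FALSE
  )
  tr3 <- trajectory(top, frames3)
  got <- rmsf_profile(tr3, seq_len(n), align = FALSE)$rmsf
  stack <- simplify2array(frames3) # n x 3 x frames
  oracle <- vapply(seq_len(n), function(i) {
    xs <- t(stack[i, , ])
    mu <- colMeans(xs)
    sqrt(mean(rowSums(sweep(xs, 2, mu)^2)))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)

  # translation of every frame leaves aligned RMSF unchanged; window errors
  base <- rmsf_profile(tr3, seq_len(n))$rmsf
  shifted <- trajectory(top, lapply(frames3, function(fr) fr + 100))
  expect_equal(rmsf_profile(shifted, seq_len(n))$rmsf, base, tolerance = 1e-6)
  expect_error(rmsf_profile(tr3, seq_len(n), window_frames = 99), "window larger")
})

test_that("atom_distance measures named atom pairs", {
  top <- tibble::tibble(
    chain = "B", resno = c(482L, 484L), resname = c("GLU", "ASP"),
    atom = c("OE1", "OD1"), element = "O"
  )
  fr <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  tr <- trajectory(top, list(fr))
  expect_equal(
    atom_distance(tr,
      list(chain = "B", resno = 482, atom = "OE1"),
      list(chain = "B", resno = 484, atom = "OD1")
    ),
    2.5
  )
})
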