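test_that("the designed hydrogen-bond ladder is found, and only it", {
  g <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
  hb <- backbone_hbonds(g$model)
  # two bonds per designed pair (N->O in each direction)
  expect_equal(nrow(hb), 4)
  expect_true(all(hb$distance_no <= 3.5))
  expect_true(all(hb$donor_chain != hb$acceptor_chain))
  expect_equal(register_map(hb), g$truth)
  # count is invariant under a global rigid motion
  moved <- move_model(g$model, theta = 1.1, shift = c(3, -7, 12))
  expect_equal(nrow(backbone_hbonds(moved)), 4)
})

test_that("separated chains and degenerate cutoffs give empty bond lists", {
  g <- gen_beta_dimer(list(c(10, 10)))
  far <- g$model
  bsel <- far$atoms$chain == "B"
  far$atoms$y[bsel] <- far$atoms$y[bsel] + 20
  expect_equal(nrow(backbone_hbonds(far)), 0)
  expect_equal(nrow(backbone_hbonds(g$model, d_max = 0)), 0)
  expect_equal(nrow(register_map(backbone_hbonds(far))), 0)
})

test_that("register maps and shifts recover designed pairings", {
  native <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
  mutant <- gen_beta_dimer(list(c(10, 10)))
  m_nat <- register_map(native$model)
  m_mut <- register_map(mutant$model)
  expect_equal(m_nat, native$truth)
  expect_equal(m_mut, mutant$truth)
  expect_equal(register_shift(m_nat, m_mut), 1L)
  expect_equal(register_shift(m_nat, m_nat), 0L)
  # designed offsets -2..+2 are recovered exactly
  base_pairs <- list(c(8, 10), c(9, 9), c(10, 8))
  base <- register_map(gen_beta_dimer(base_pairs)$model)
  for (off in -2:2) {
    shifted <- lapply(base_pairs, function(p) p + off)
    m <- register_map(gen_beta_dimer(shifted)$model)
    expect_equal(register_shift(base, m), off)
  }
  expect_error(register_shift(m_nat, m_mut, window = c(30, 40)),
               "window")
})

test_that("sphere SASA matches the analytic area and converges", {
  s <- gen_sphere_fixture(1.7, matrix(c(0, 0, 0), 1))
  a <- sum(sasa(s, probe = 1.4, n_points = 960))
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 0.01)
  # far-apart spheres add independently
  two <- gen_sphere_fixture(c(1.7, 1.7), rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sum(sasa(two)), 2 * a, tolerance = 1e-6)
  # an atom enclosed in a tight cage is fully buried
  cage_centers <- rbind(expand.grid(x = c(-1.2, 1.2), y = c(-1.2, 1.2),
                                    z = c(-1.2, 1.2)),
                        c(0, 0, 0))
  cage <- gen_sphere_fixture(c(rep(3, 8), 0.5), as.matrix(cage_centers))
  expect_equal(sasa(cage, probe = 1.4, n_points = 960)[9], 0)
  # quadrature convergence: doubling n_points moves totals < 0.5%
  g <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
  t1 <- sum(sasa(g$model, n_points = 480))
  t2 <- sum(sasa(g$model, n_points = 960))
  expect_lt(abs(t2 - t1) / t2, 0.005)
  expect_error(sasa(g$model, n_points = 32), ">= 64")
})

test_that("unknown elements are reported by atom", {
  m <- gen_beta_dimer(list(c(10, 10)))$model
  m$atoms$element[1] <- "ZZ"
  expect_error(sasa(m), "unknown element")
})

test_that("two-sphere buried area matches the spherical-cap closed form", {
  two <- gen_sphere_fixture(c(2, 2), rbind(c(0, 0, 0), c(2, 0, 0)),
                            chains = c("A", "B"))
  # expanded radius R = 3.4, cap height h = R - d/2 = 2.4
  expect_equal(interface_area(two), 2 * pi * 3.4 * 2.4, tolerance = 0.02)
  far <- gen_sphere_fixture(c(2, 2), rbind(c(0, 0, 0), c(100, 0, 0)),
                            chains = c("A", "B"))
  expect_equal(interface_area(far), 0)
})

test_that("interface area is chain-symmetric and decays with separation", {
  g <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
  a0 <- interface_area(g$model, n_points = 480)
  expect_gt(a0, 0)
  swapped <- g$model
  swapped$atoms$chain <- ifelse(swapped$atoms$chain == "A", "B", "A")
  expect_equal(interface_area(swapped, n_points = 480), a0)
  prev <- a0
  for (pull in c(3, 8, 30)) {
    m <- g$model
    bsel <- m$atoms$chain == "B"
    m$atoms$y[bsel] <- m$atoms$y[bsel] + pull
    cur <- interface_area(m, n_points = 480)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
  expect_equal(prev, 0)
  one_chain <- structure_model(g$model$atoms[g$model$atoms$chain == "A", ])
  expect_error(interface_area(one_chain), "exactly 2 chains")
})

test_that("superposition is exact for rigid motions and symmetric in its inputs", {
  g <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
  mono <- structure_model(g$model$atoms[g$model$atoms$chain == "A", ])
  expect_equal(superpose(mono, mono)$rmsd, 0)
  moved <- move_model(mono, theta = pi / 2, shift = c(5, 5, 5))
  expect_equal(superpose(moved, mono)$rmsd, 0, tolerance = 1e-9)
  # RMSD(A,B) == RMSD(B,A), invariant to rigid pre-transformations
  pert <- mono
  pert$atoms$x <- pert$atoms$x + rnorm(nrow(pert$atoms), 0, 0.3)
  ab <- superpose(pert, mono)$rmsd
  expect_equal(superpose(mono, pert)$rmsd, ab, tolerance = 1e-9)
  expect_equal(superpose(move_model(pert, 0.7, c(1, 2, 3)), mono)$rmsd, ab,
               tolerance = 1e-9)
  # transform_structure reproduces the fit
  fitted <- transform_structure(moved, superpose(moved, mono))
  expect_equal(as.matrix(fitted$atoms[, c("x", "y", "z")]),
               as.matrix(mono$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("SVD superposition matches a brute-force rotation-grid oracle", {
  # 4-point toy set vs a copy with one point displaced
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P
  Q[4, ] <- Q[4, ] + c(0.3, -0.2, 0.4)
  mk <- function(X) structure_model(data.frame(
    chain = "A", resno = 1:4, resid = "ALA", elety = "CA", element = "C",
    x = X[, 1], y = X[, 2], z = X[, 3]))
  got <- superpose(mk(P), mk(Q))$rmsd
  # oracle: Euler-angle grid search over centred clouds, refined locally
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  euler_rmsd <- function(ang) {
    a <- ang[1]; b <- ang[2]; cang <- ang[3]
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(cang), -sin(cang), 0, sin(cang),
                   cos(cang)), 3, byrow = TRUE)
    sqrt(mean(rowSums((Pc %*% t(Rz %*% Ry %*% Rx) - Qc)^2)))
  }
  coarse <- as.matrix(expand.grid(a = seq(-pi, pi, by = 0.2),
                                  b = seq(-pi / 2, pi / 2, by = 0.2),
                                  c = seq(-pi, pi, by = 0.2)))
  vals <- apply(coarse, 1, euler_rmsd)
  start <- coarse[which.min(vals), ]
  best <- stats::optim(start, euler_rmsd)$value
  expect_lte(got, best + 1e-9)   # the closed form can only do better
  expect_equal(got, best, tolerance = 1e-3)
})

test_that("selection mismatches are reported with the unpaired atoms", {
  g <- gen_beta_dimer(list(c(10, 10)))
  mono <- structure_model(g$model$atoms[g$model$atoms$chain == "A", ])
  shorter <- structure_model(mono$atoms[mono$atoms$resno > 8, ])
  expect_error(superpose(mono, shorter), "unpaired")
  sp <- superpose(mono, shorter, on_mismatch = "intersect")
  expect_equal(sp$n_pairs, sum(mono$atoms$resno > 8 &
                                 mono$atoms$elety == "CA"))
  tiny <- structure_model(mono$atoms[mono$atoms$resno %in% 9:10, ])
  expect_error(superpose(tiny, tiny, elety = c("N", "CA", "C", "O"),
                         resno = 9:10), NA)
  expect_error(superpose(tiny, tiny, resno = 9:10), "at least 3")
})
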