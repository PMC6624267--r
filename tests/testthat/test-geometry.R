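test_that("kabsch superposition recovers constructed rigid motions", {
  set.seed(21)
  X <- matrix(rnorm(90, sd = 8), 30, 3)

  f0 <- kabsch_superpose(X, X)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$transform$rotation, diag(3), tolerance = 1e-9)

  ft <- kabsch_superpose(X + matrix(c(5, 0, 0), 30, 3, byrow = TRUE), X)
  expect_equal(ft$transform$translation, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(ft$rmsd, 0, tolerance = 1e-9)

  for (k in 1:20) {
    R0 <- random_rotation()
    t0 <- rnorm(3, sd = 10)
    Y <- X %*% R0 + matrix(t0, 30, 3, byrow = TRUE)
    fit <- kabsch_superpose(Y, X)           # should invert the motion
    expect_lt(max(abs(fit$transform$rotation - t(R0))), 1e-9)
    expect_lt(fit$rmsd, 1e-9)
  }
  # independent cross-check on noisy data: the minimized RMSD must agree
  # with bio3d's least-squares superposition of the same point sets
  for (k in 1:5) {
    Y <- X %*% random_rotation() + matrix(rnorm(3, sd = 5), 30, 3,
                                          byrow = TRUE) +
         matrix(rnorm(90, sd = 0.4), 30, 3)
    mine <- kabsch_superpose(Y, X)
    fitted <- matrix(bio3d::fit.xyz(fixed = as.vector(t(X)),
                                    mobile = as.vector(t(Y)),
                                    fixed.inds = 1:90, mobile.inds = 1:90),
                     ncol = 3, byrow = TRUE)
    rms_b <- sqrt(mean(rowSums((fitted - X)^2)))
    expect_equal(mine$rmsd, rms_b, tolerance = 1e-6)
    expect_lt(max(abs(apply_transform(Y, mine$transform) - fitted)), 1e-4)
  }
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "3 points")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("rmsd is invariant under common rigid motion of both point sets", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3)
  Y <- X + matrix(rnorm(60, sd = 0.8), 20, 3)
  base <- kabsch_superpose(X, Y)$rmsd
  for (k in 1:10) {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 20)
    Xr <- X %*% R0 + matrix(t0, 20, 3, byrow = TRUE)
    Yr <- Y %*% R0 + matrix(t0, 20, 3, byrow = TRUE)
    expect_equal(kabsch_superpose(Xr, Yr)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("ensemble RMSD matches closed forms and mode ordering", {
  p <- make_toy_protomer(n_core = 200, core_radius = 8, rng_seed = 3)

  e0 <- as_ensemble(list(p, p, p))
  expect_equal(ensemble_rmsd(e0, mode = "to_mean")$mean_rmsd, 0,
               tolerance = 1e-9)
  expect_equal(ensemble_rmsd(e0, mode = "mean_pairwise")$mean_rmsd, 0,
               tolerance = 1e-9)

  # one atom displaced by d: pairwise rmsd ~ d/sqrt(N) (superposition absorbs
  # a small O(1/N) part of the displacement)
  N <- nrow(p); d <- 0.5
  p2 <- p
  p2$x[100] <- p2$x[100] + d
  mp <- ensemble_rmsd(as_ensemble(list(p, p2)), mode = "mean_pairwise")$mean_rmsd
  expect_equal(mp, d / sqrt(N), tolerance = 0.02)

  en <- perturb_ensemble(p, sigma = 0.4, n_models = 10, rng_seed = 5)
  tm <- ensemble_rmsd(en, mode = "to_mean")$mean_rmsd
  pw <- ensemble_rmsd(en, mode = "mean_pairwise")$mean_rmsd
  expect_lte(tm, pw)

  expect_error(ensemble_rmsd(as_ensemble(list(p)), mode = "to_mean"),
               "2 models")
  expect_error(ensemble_rmsd(en, res_seq = 99999L), "empty")
})

test_that("screw decomposition recovers canonical and random screws", {
  sp <- screw_transform_params(screw_transform(90, 5))
  expect_equal(sp$twist, 90)
  expect_equal(sp$rise, 5)
  expect_equal(sp$axis_dir, c(0, 0, 1), tolerance = 1e-12)

  sp2 <- screw_transform_params(rigid_transform(diag(3), c(0, 0, 5)))
  expect_equal(sp2$twist, 0)
  expect_equal(sp2$rise, 5)
  expect_equal(sp2$axis_dir, c(0, 0, 1))

  expect_error(screw_transform_params(rigid_transform(diag(3), c(0, 0, 0))),
               "undefined")

  set.seed(23)
  for (k in 1:50) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    pt <- rnorm(3, sd = 10)
    tw <- runif(1, -179, 179); ri <- runif(1, 0.5, 10)
    tf <- screw_transform(tw, ri, ax, pt)
    sp <- screw_transform_params(tf)
    expect_equal(sp$twist, tw, tolerance = 1e-6)
    expect_equal(sp$rise, ri, tolerance = 1e-6)
    expect_lt(max(abs(sp$axis_dir - ax)), 1e-6)
    # reconstruction reproduces the transform (axis point included)
    tf2 <- screw_transform(sp$twist, sp$rise, sp$axis_dir, sp$axis_point)
    expect_lt(max(abs(tf2$rotation - tf$rotation)), 1e-9)
    expect_lt(max(abs(tf2$translation - tf$translation)), 1e-6)
  }
})

test_that("backbone dihedrals recover construction targets and match bio3d", {
  set.seed(24)
  nres <- 12
  phi <- runif(nres, -150, 150)
  psi <- runif(nres, -150, 150)
  m <- build_backbone(phi, psi)
  dh <- backbone_dihedrals(m)
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[nres]))
  expect_equal(dh$phi[-1], phi[-1], tolerance = 1e-3)
  expect_equal(dh$psi[-nres], psi[-nres], tolerance = 1e-3)

  # independent oracle: bio3d torsions on the same written structure
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
  expect_equal(unname(tor$phi[-1]), phi[-1], tolerance = 1e-2)
  expect_equal(unname(tor$psi[-nres]), psi[-nres], tolerance = 1e-2)

  single <- select_atoms(m, res_seq = 5L)
  dh1 <- backbone_dihedrals(new_model(single))
  expect_true(is.na(dh1$phi) && is.na(dh1$psi))
})
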