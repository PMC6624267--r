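test_that("contact detection brackets the cutoff and is symmetric", {
  two <- function(d) point_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  a <- function(d) new_model(two(d)[1, , drop = FALSE])
  b <- function(d) { m <- two(d)[2, , drop = FALSE]; m$chain <- "B"; new_model(m) }

  hit <- contact_residues(a(2.4), b(2.4), cutoff = 2.5)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$min_distance, 2.4, tolerance = 1e-12)
  expect_equal(nrow(contact_residues(a(2.6), b(2.6), cutoff = 2.5)), 0L)

  # A/B symmetry with roles swapped
  set.seed(41)
  ga <- random_point_model(80, chain = "A")
  gb <- random_point_model(80, chain = "B")
  ab <- contact_residues(ga, gb, cutoff = 4)
  ba <- contact_residues(gb, ga, cutoff = 4)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$res_a, ab$res_b), paste(ba$res_b, ba$res_a))

  expect_error(contact_residues(ga, ga, cutoff = 4), "overlap")
})

test_that("grid contacts equal brute-force contacts exactly on random fixtures", {
  set.seed(42)
  for (rep in 1:3) {
    ga <- random_point_model(500, spread = 40, chain = "A")
    gb <- random_point_model(500, spread = 40, chain = "B")
    g <- contact_residues(ga, gb, cutoff = 3.5, method = "grid")
    b <- contact_residues(ga, gb, cutoff = 3.5, method = "brute")
    expect_identical(as.data.frame(g)[names(g)], as.data.frame(b)[names(b)])
    expect_gt(nrow(g), 0L)
  }
})

test_that("hydrogens are excluded from heavy-atom contacts", {
  ga <- new_model(data.frame(atom = c("CA", "HA"), element = c("C", "H"),
                             res_name = "ALA", res_seq = 1L, chain = "A",
                             x = c(0, 2.0), y = 0, z = 0))
  gb <- new_model(data.frame(atom = "CA", element = "C", res_name = "ALA",
                             res_seq = 1L, chain = "B",
                             x = 4.0, y = 0, z = 0))
  # hydrogen at 2.0 A from B would be a contact, heavy CA at 4.0 A is not
  expect_equal(nrow(contact_residues(ga, gb, cutoff = 2.5)), 0L)
  expect_equal(nrow(contact_residues(ga, gb, cutoff = 2.5,
                                     heavy_only = FALSE)), 1L)
})

test_that("ensemble contacts honor the any-model rule", {
  base <- point_model(rbind(c(0, 0, 0)))
  far <- point_model(rbind(c(10, 0, 0)))
  near <- point_model(rbind(c(2, 0, 0)))
  mk <- function(other) {
    o <- other; o$chain <- "B"
    new_model(rbind(base, o))
  }
  ens <- as_ensemble(list(mk(far), mk(near)))   # contact only in model 2
  tab <- contact_residues_ensemble(
    ens,
    function(m) select_atoms(m, chain = "A"),
    function(m) select_atoms(m, chain = "B"),
    cutoff = 2.5)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$min_distance, 2.0, tolerance = 1e-12)
  per_model <- contact_residues_ensemble(
    ens, function(m) select_atoms(m, chain = "A"),
    function(m) select_atoms(m, chain = "B"),
    cutoff = 2.5, any_model = FALSE)
  expect_equal(nrow(per_model[[1]]), 0L)
  expect_equal(nrow(per_model[[2]]), 1L)
})

test_that("SASA matches the closed form for one, two, and coincident spheres", {
  one <- point_model(rbind(c(0, 0, 0)))
  s1 <- sasa(one)
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(s1$total - exact) / exact, 0.01)

  sep <- point_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(sasa(sep)$total, 2 * s1$total, tolerance = 1e-9)

  coincident <- point_model(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(sasa(coincident)$total, s1$total, tolerance = 1e-9)

  expect_error(sasa(one, n_points = 50), ">= 92")
  weird <- point_model(rbind(c(0, 0, 0)), element = "XX")
  expect_error(sasa(weird), "radius")
  expect_equal(sasa(weird, radii = c(XX = 2.0))$total, 4 * pi * 3.4^2,
               tolerance = 0.01 * 4 * pi * 3.4^2)
})

test_that("SASA is invariant under rigid motion at fixed point set", {
  set.seed(43)
  m <- random_point_model(60, spread = 12)
  ref <- sasa(m)$total
  for (k in 1:5) {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 50)
    mr <- m
    coords(mr) <- coords(m) %*% R0 + matrix(t0, nrow(m), 3, byrow = TRUE)
    expect_lt(abs(sasa(mr)$total - ref) / ref, 0.005)
  }
})

test_that("two-body buried area matches the spherical-cap closed form", {
  # two equal carbon spheres, solvent radius R = 1.70 + 1.4, centers d apart:
  # each buries a cap of area 2*pi*R*h with h = R - d/2
  R <- 1.70 + 1.4
  for (d in c(3.0, 4.0, 5.0)) {
    m <- point_model(rbind(c(0, 0, 0), c(d, 0, 0)))
    ba <- buried_area(m, list(a = 1L, b = 2L), n_points = 3840)
    cap <- 2 * pi * R * (R - d / 2)
    expect_lt(abs(ba$buried[1] - cap) / cap, 0.02)
    expect_lt(abs(ba$buried[2] - cap) / cap, 0.02)
    expect_equal(ba$fraction_buried, ba$buried / ba$sasa_isolated,
                 tolerance = 1e-12)
  }
  # no inter-component contacts: nothing buried
  far <- point_model(rbind(c(0, 0, 0), c(20, 0, 0)))
  ba0 <- buried_area(far, list(a = 1L, b = 2L))
  expect_equal(ba0$buried, c(0, 0), tolerance = 1e-9)

  expect_error(buried_area(far, list(a = integer(0), b = 2L)), "empty")
  expect_error(buried_area(far, list(a = 1:2, b = 2L)), "overlap")
})

test_that("buried area shrinks monotonically as the partner is deleted", {
  set.seed(44)
  cl1 <- matrix(rnorm(30, sd = 2), 10, 3)
  cl2 <- matrix(rnorm(30, sd = 2), 10, 3) + matrix(c(6, 0, 0), 10, 3,
                                                   byrow = TRUE)
  m <- point_model(rbind(cl1, cl2))
  partner <- 11:20
  prev <- Inf
  for (keep in c(10, 6, 3, 0)) {
    sub <- m[c(1:10, partner[seq_len(keep)]), , drop = FALSE]
    ba <- buried_area(new_model(sub), list(a = 1:10))
    expect_lte(ba$buried[1], prev + 1e-6)
    prev <- ba$buried[1]
  }
  expect_equal(prev, 0, tolerance = 1e-9)
})

test_that("typed interface reports label every pair and find engineered contacts", {
  fl <- default_toy_filament(8L)
  rep <- interface_report(fl, "filament_typed")
  expect_gt(nrow(rep), 0L)
  expect_true(all(rep$interface %in% c("TypeI", "TypeII", "TypeIII")))
  # patch residues dominate the contacts: the b-face patch of start k meets
  # the a-face patch of the +k neighbor
  t3 <- rep[rep$interface == "TypeIII", ]
  expect_true(all(grepl("^PB1", t3$res_name_a)))
  expect_true(all(grepl("^PA1", t3$res_name_b)))

  # dimer scheme: engineered cross-subdomain contact is the only report
  dimer <- new_model(data.frame(
    atom = "CA", element = "C", res_name = "ALA",
    res_seq = c(50, 105, 120),          # CARD, linker, coiled-coil
    chain = "A",
    x = c(0, 2.2, 50), y = 0, z = 0))   # CARD-linker pair within 2.5 A
  drep <- interface_report(dimer, "dimer_subdomain")
  expect_equal(nrow(drep), 1L)
  expect_identical(drep$interface, "CARD-linker")
  expect_identical(c(drep$res_a, drep$res_b), c(50L, 105L))
})
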