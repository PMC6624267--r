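test_that("write then read round-trips coordinates and topology", {
  set.seed(11)
  m1 <- random_point_model(40)
  m2 <- m1
  coords(m2) <- coords(m1) + matrix(rnorm(120, sd = 0.5), 40, 3)
  ens <- as_ensemble(list(m1, m2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, path)
  back <- read_structure(path)
  expect_equal(n_models(back), 2L)
  expect_identical(back$atoms$res_seq, ens$atoms$res_seq)
  expect_identical(back$atoms$chain, ens$atoms$chain)
  for (i in 1:2)
    expect_lt(max(abs(back$xyz[[i]] - ens$xyz[[i]])), 1e-3)
  # idempotence: a second write/read changes nothing further
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(back, path2)
  back2 <- read_structure(path2)
  expect_identical(back2$xyz, back$xyz)
})

test_that("multi-model framing matches model count and single-model files omit it", {
  m <- random_point_model(5)
  ens20 <- as_ensemble(replicate(20, m, simplify = FALSE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens20, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 20L)
  expect_equal(sum(grepl("^ENDMDL", lines)), 20L)
  expect_equal(n_models(read_structure(path)), 20L)

  write_structure(m, path)
  expect_false(any(grepl("^MODEL", readLines(path))))
  expect_equal(n_models(read_structure(path)), 1L)
})

test_that("long atom names are written column-correct for an independent reader", {
  m <- new_model(data.frame(
    atom = c("N", "CA", "HG12"), element = c("N", "C", "H"),
    res_name = "ILE", res_seq = 1L, chain = "A",
    x = c(0, 1.4, 2.2), y = 0, z = 0))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)     # independent reader
  expect_identical(pdb$atom$elety, c("N", "CA", "HG12"))
  expect_identical(pdb$atom$resid, rep("ILE", 3))
  expect_equal(pdb$atom$x, c(0, 1.4, 2.2), tolerance = 1e-6)
})

test_that("reading rejects empty and malformed files, and enforces topology", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER test", "END"), empty)
  expect_error(read_structure(empty), "no ATOM")

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1      bogus.   0.000   0.000  1.00  0.00           C"),
    bad)
  expect_error(read_structure(bad), "line 2")

  expect_error(read_structure(file.path(tempdir(), "does-not-exist.pdb")),
               "not found")

  # models with different atom counts cannot form an ensemble
  m1 <- random_point_model(5)
  m2 <- random_point_model(6)
  expect_error(as_ensemble(list(m1, m2)), "topology")
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50 10.00           C",
    "END"), path)
  ens <- read_structure(path)
  m <- get_model(ens, 1L)
  expect_equal(nrow(m), 2L)
  expect_equal(m$x[m$atom == "CA"], 2.0)   # higher occupancy wins
  expect_equal(m$x[m$atom == "CB"], 3.0)   # tie: first occurrence wins
})

test_that("selection arithmetic, empty selections, and heavy-atom filtering", {
  # two chains, residues 10-142, backbone N/CA/C/O plus one hydrogen each
  res <- 10:142
  per_chain <- do.call(rbind, lapply(res, function(r)
    data.frame(atom = c("N", "CA", "C", "O", "H"),
               element = c("N", "C", "C", "O", "H"),
               res_name = "GLY", res_seq = r,
               x = rnorm(5), y = rnorm(5), z = rnorm(5))))
  both <- rbind(cbind(per_chain, chain = "A"), cbind(per_chain, chain = "B"))
  m <- new_model(both)

  sel <- select_atoms(m, res_range = c(10, 142),
                      atoms = c("N", "CA", "C", "O"))
  expect_equal(nrow(sel), 2 * 4 * 133)
  selA <- select_atoms(m, chain = "A", res_range = c(10, 142),
                       atoms = c("N", "CA", "C", "O"))
  expect_equal(nrow(selA), 4 * 133)

  expect_equal(nrow(select_atoms(m, res_seq = 999L)), 0L)
  expect_error(select_atoms(m, chain = "Z"), "unknown chain")

  heavy <- select_atoms(m, heavy_only = TRUE)
  expect_false(any(heavy$hydrogen))
  expect_equal(nrow(heavy), nrow(m) - 2 * length(res))
})

test_that("models reject duplicate atom keys and non-finite coordinates", {
  d <- data.frame(atom = "CA", element = "C", res_name = "ALA", res_seq = 1L,
                  chain = "A", x = 0, y = 0, z = 0)
  expect_error(new_model(rbind(d, d)), "duplicate")
  d$x <- NaN
  expect_error(new_model(d), "finite")
  expect_error(write_structure(
    new_model(data.frame(atom = "CA", element = "C", res_name = "ALA",
                         res_seq = 10000L, chain = "A", x = 0, y = 0, z = 0)),
    withr::local_tempfile(fileext = ".pdb")), "9999")
})
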