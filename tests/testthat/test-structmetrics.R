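test_that("kabsch superposition is exact on identity and rigid motions", {
  set.seed(8)
  X <- random_cloud(10)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  for (i in 1:20) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 10)
    Y <- sweep(X %*% t(R), 2, t, "+")
    fit <- kabsch_superpose(X, Y)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("kabsch RMSD matches the quaternion oracle on random clouds", {
  set.seed(9)
  for (i in 1:50) {
    A <- random_cloud(sample(4:20, 1))
    B <- A + matrix(stats::rnorm(length(A)), ncol = 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch_superpose(random_cloud(2), random_cloud(2)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "rank-deficient")
})

test_that("ensemble RMSD is zero for identical or rigidly moved models", {
  base <- random_cloud(30)
  atoms <- data.frame(resno = rep(1:10, each = 3),
                      elety = rep(c("N", "CA", "C"), 10))
  coords <- array(rep(base, 4), c(30, 3, 4))
  ens <- structure_ensemble(coords, atoms)
  r <- ensemble_rmsd(ens, c(1, 10))
  expect_equal(r$mean, 0, tolerance = 1e-10)
  expect_equal(r$sd, 0, tolerance = 1e-10)

  set.seed(10)
  for (m in 2:4) {
    R <- random_rotation()
    coords[, , m] <- sweep(base %*% t(R), 2, stats::rnorm(3, sd = 8), "+")
  }
  r2 <- ensemble_rmsd(structure_ensemble(coords, atoms), c(1, 10))
  expect_lt(r2$mean, 1e-8)

  expect_error(ensemble_rmsd(ens, c(1, 40)), "outside")
})

test_that("ensemble RMSD is invariant to one rigid motion applied everywhere", {
  ens <- generate_synthetic_ensemble(n_res = 20, n_models = 6, seed = 11)
  r0 <- ensemble_rmsd(ens, c(5, 15))
  R <- random_rotation()
  moved <- ens$coords
  for (m in seq_len(dim(moved)[3]))
    moved[, , m] <- sweep(moved[, , m] %*% t(R), 2, c(3, -7, 2), "+")
  r1 <- ensemble_rmsd(structure_ensemble(moved, ens$atoms), c(5, 15))
  expect_equal(r1$mean, r0$mean, tolerance = 1e-6)
  expect_equal(r1$sd, r0$sd, tolerance = 1e-6)
})

test_that("multi-model PDB writing and reading round-trip the ensemble", {
  ens <- generate_synthetic_ensemble(n_res = 12, n_models = 3, seed = 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble(f)
  expect_equal(back$n_models, 3L)
  expect_equal(back$atoms$resno, ens$atoms$resno)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_equal(back$coords, ens$coords, tolerance = 1e-3)  # 3-decimal PDB
  r_ens <- ensemble_rmsd(ens, c(3, 10))
  r_back <- ensemble_rmsd(back, c(3, 10))
  expect_equal(r_back$mean, r_ens$mean, tolerance = 1e-3)
})

test_that("restraint tally partitions by residue separation", {
  tally <- tally_restraints(data.frame(i = c(3, 3, 3, 3), j = c(3, 4, 6, 9)))
  expect_equal(unname(tally),
               c(1L, 1L, 1L, 1L, 4L))
  expect_equal(unname(tally_restraints(data.frame(i = integer(0),
                                                  j = integer(0)))),
               rep(0L, 5))
  # disjoint and exhaustive over random pairs
  set.seed(13)
  df <- data.frame(i = sample(1:44, 500, TRUE), j = sample(1:44, 500, TRUE))
  t2 <- tally_restraints(df)
  expect_equal(sum(t2[1:4]), t2[["total"]])
  expect_equal(t2[["total"]], 500L)
})

test_that("restraint readers handle TSV, CYANA upl and NMR-STAR blocks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("i\tj", "3\t3", "3\t4", "3\t9"), f)
  expect_equal(read_restraints(f)$j, c(3L, 4L, 9L))

  fu <- withr::local_tempfile(fileext = ".upl")
  writeLines(c("  1 ALA HA   5 CYS HB2  4.50",
               " 12 GLY HN  12 GLY HA   3.10"), fu)
  up <- read_restraints(fu)
  expect_equal(up$i, c(1L, 12L))
  expect_equal(up$j, c(5L, 12L))

  fs <- withr::local_tempfile(fileext = ".str")
  writeLines(c("loop_",
               "_Gen_dist_constraint.ID",
               "_Gen_dist_constraint.Comp_index_ID_1",
               "_Gen_dist_constraint.Comp_index_ID_2",
               "_Gen_dist_constraint.Distance_val",
               "1 2 6 3.2",
               "2 7 7 2.8",
               "stop_"), fs)
  st <- read_restraints(fs)
  expect_equal(st$i, c(2L, 7L))
  expect_equal(st$j, c(6L, 7L))
  expect_equal(unname(tally_restraints(st)),
               c(1L, 0L, 1L, 0L, 2L))
})

test_that("in-silico PCR finds exact products and degrades to NO_PRODUCT", {
  fwd <- "GTCACGCGATGAAGAAGAAT"
  rev <- "GAAGTGGTCACAGTCCGAGT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  set.seed(14)
  mid <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  template <- paste0(fwd, mid, rc)
  pr <- insilico_pcr(template, fwd, rev)
  expect_equal(pr$length, nchar(template))
  expect_equal(pr$start, 1L)

  none <- insilico_pcr(strrep("A", 200), fwd, rev)
  expect_equal(nrow(none), 0L)
  expect_true(attr(none, "no_product"))

  # flanking the template with primer-free sequence leaves the product alone
  flank <- paste0(strrep("T", 40), template, strrep("A", 40))
  pr2 <- insilico_pcr(flank, fwd, rev)
  expect_equal(pr2$length, nchar(template))

  expect_error(insilico_pcr(template, "ACGT", rev), "15 nt")
})
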