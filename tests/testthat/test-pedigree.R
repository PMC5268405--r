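test_that("trio pedigree validates with correct link counts and depth", {
  ped <- validate_pedigree(trio_table())
  expect_s3_class(ped, "qg_pedigree")
  expect_equal(attr(ped, "n_maternities"), 1L)
  expect_equal(attr(ped, "n_paternities"), 1L)
  expect_equal(max(attr(ped, "depth")), 2L)
  # parents precede offspring
  expect_true(match("o1", ped$id) > max(match(c("s1", "d1"), ped$id)))
})

test_that("structural defects are rejected with informative errors", {
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), sex = c("M", "M"),
                    cohort = c(2000, 2000))
  expect_error(validate_pedigree(cyc), "cycle")

  bad_sex <- trio_table()
  bad_sex$sire[3] <- "d1"  # a female listed as sire
  bad_sex$dam[3] <- "s1"
  expect_error(validate_pedigree(bad_sex), "sex-inconsistent")

  orphan_ref <- trio_table()
  orphan_ref$sire[3] <- "ghost"
  expect_error(validate_pedigree(orphan_ref), "ghost")

  late <- trio_table()
  late$cohort[3] <- 1999  # born before its parents
  expect_error(validate_pedigree(late), "born after")

  # same-cohort parentage is allowed (early-maturing females)
  same <- trio_table()
  same$cohort[3] <- 2000
  expect_s3_class(validate_pedigree(same), "qg_pedigree")
})

test_that("A matrix has textbook values on small pedigrees", {
  founders <- data.frame(id = c("x", "y"), sire = NA, dam = NA,
                         sex = c("M", "F"), cohort = 2000)
  expect_equal(unname(additive_relationship(validate_pedigree(founders))),
               diag(2))

  ped <- validate_pedigree(trio_table())
  A <- additive_relationship(ped)
  expect_equal(A["s1", "o1"], 0.5)
  expect_equal(A["o1", "o1"], 1)

  # offspring of two full sibs: F = 0.25
  fs <- data.frame(
    id = c("s", "d", "b1", "b2", "inb"),
    sire = c(NA, NA, "s", "s", "b1"),
    dam = c(NA, NA, "d", "d", "b2"),
    sex = c("M", "F", "M", "F", "F"),
    cohort = c(2000, 2000, 2001, 2001, 2002))
  A2 <- additive_relationship(validate_pedigree(fs))
  expect_equal(A2["inb", "inb"], 1.25)
  expect_equal(unname(inbreeding(validate_pedigree(fs))["inb"]), 0.25)
})

test_that("A matches gene-dropping allele-sharing within Monte Carlo error", {
  ped <- random_pedigree(n_founders = 10, n_gen = 4, per_gen = 10, seed = 3)
  A <- additive_relationship(ped)
  n_rep <- 50000
  Ahat <- gene_drop_relatedness(ped, n_rep = n_rep, seed = 99)
  # binomial-scale Monte Carlo SE for a sharing probability
  se <- 2 * sqrt(0.25 / n_rep) * 3
  expect_lt(max(abs(A - Ahat)), max(3 * se, 0.02))
})

test_that("inbreeding matches the recursive kinship oracle", {
  ped <- random_pedigree(n_founders = 8, n_gen = 4, per_gen = 10, seed = 5)
  f_kin <- kinship_recursive(ped)
  expect_equal(unname(inbreeding(ped)), 2 * diag(f_kin) - 1, tolerance = 1e-12)
  expect_equal(unname(additive_relationship(ped)), unname(2 * f_kin),
               tolerance = 1e-12)
})

test_that("sparse A-inverse inverts A", {
  ped <- validate_pedigree(trio_table())
  A <- additive_relationship(ped)
  Ainv <- as.matrix(a_inverse(ped))
  expect_lt(max(abs(Ainv %*% A - diag(3))), 1e-10)

  # founders only
  fo <- validate_pedigree(data.frame(
    id = letters[1:4], sire = NA, dam = NA,
    sex = c("M", "F", "M", "F"), cohort = 2000))
  expect_equal(unname(as.matrix(a_inverse(fo))), diag(4))

  # larger pedigree with inbreeding: compare with dense inversion
  ped2 <- random_pedigree(n_founders = 12, n_gen = 5, per_gen = 20, seed = 7)
  A2 <- additive_relationship(ped2)
  Ainv2 <- as.matrix(a_inverse(ped2))
  expect_lt(max(abs(Ainv2 - solve(A2))), 1e-8)
})

test_that("A is symmetric positive semi-definite on generated pedigrees", {
  for (s in 1:3) {
    ped <- random_pedigree(n_founders = 10, n_gen = 4, per_gen = 15, seed = s)
    A <- additive_relationship(ped)
    expect_true(isSymmetric(A))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_true(all(A >= -1e-12 & A <= 2 + 1e-12))
    expect_true(all(diag(A) >= 1 - 1e-12))
  }
})

test_that("generation time averages parental ages over links", {
  ped <- validate_pedigree(trio_table())
  expect_equal(generation_time(ped), 1)

  two <- data.frame(
    id = c("s", "d", "o1", "o2"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"),
    sex = c("M", "F", "F", "F"),
    cohort = c(2000, 2000, 2001, 2002))
  expect_equal(generation_time(validate_pedigree(two)), 1.5)

  fo <- validate_pedigree(data.frame(id = c("a", "b"), sire = NA, dam = NA,
                                     sex = c("M", "F"), cohort = 2000))
  expect_error(generation_time(fo), "no parent-offspring links")
})

test_that("pedigree round-trips through CSV", {
  ped <- random_pedigree(n_founders = 6, n_gen = 2, per_gen = 8, seed = 2)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(ped)[, c("id", "sire", "dam", "sex",
                                          "cohort")],
                   tmp, row.names = FALSE, na = "")
  ped2 <- read_pedigree(tmp)
  expect_equal(ped2$id, ped$id)
  expect_equal(additive_relationship(ped2), additive_relationship(ped))
})
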