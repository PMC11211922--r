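test_that("partial diallel enumerates all ordered non-self pairs", {
  cr5 <- build_partial_diallel(letters[1:5])
  expect_equal(nrow(cr5), 20)
  expect_true(all(cr5$dam != cr5$sire))
  expect_equal(as.vector(table(cr5$dam)), rep(4L, 5))
  expect_equal(as.vector(table(cr5$sire)), rep(4L, 5))

  expect_equal(nrow(build_partial_diallel(c("A", "B"))), 2)
  expect_equal(nrow(build_partial_diallel(paste0("p", 1:7))), 7 * 6)
  # without reciprocals: one cross per unordered pair
  expect_equal(nrow(build_partial_diallel(letters[1:5], reciprocals = FALSE)), 10)

  expect_error(build_partial_diallel("a"), "at least 2")
  expect_error(build_partial_diallel(c("a", "a", "b")), "duplicate")
})

test_that("family assignment pools reciprocal crosses", {
  cr <- assign_families(build_partial_diallel(letters[1:5]))
  expect_equal(length(unique(cr$family)), 10)
  ab <- cr[(cr$dam == "a" & cr$sire == "b") | (cr$dam == "b" & cr$sire == "a"), ]
  expect_equal(unique(ab$family), "axb")
  # a lone non-reciprocated cross still gets its unordered-pair family
  lone <- assign_families(data.frame(dam = "a", sire = "b"))
  expect_equal(lone$family, "axb")
})

test_that("pedigree construction places founders first and counts records", {
  cr <- assign_families(build_partial_diallel(letters[1:5]))
  ped <- build_pedigree(letters[1:5], cr, 1L)
  expect_equal(nrow(ped), 25)
  expect_equal(ped$generation, rep(c("P1", "F1"), c(5, 20)))
  expect_true(all(is.na(ped$dam[1:5])))

  ped0 <- build_pedigree(letters[1:5], cr, 0L)
  expect_equal(nrow(ped0), 5)

  # a 38-group design at 2 offspring per cross gives 1520 F1 records
  n_f1 <- 38 * 20 * 2
  expect_equal(n_f1, 1520)
  expect_error(build_pedigree(letters[1:3], cr, 1L), "unknown parents")
})

test_that("additive relationship reproduces textbook path coefficients", {
  cr <- assign_families(build_partial_diallel(letters[1:3]))
  ped <- build_pedigree(letters[1:3], cr, 2L)
  A <- additive_relationship(ped)
  expect_equal(unname(A["a", "axb_1"]), 0.5)          # parent-offspring
  expect_equal(unname(A["axb_1", "axb_2"]), 0.5)      # full sibs, same cross
  expect_equal(unname(A["axb_1", "bxa_1"]), 0.5)      # reciprocal-cross sibs
  expect_equal(unname(A["axb_1", "axc_1"]), 0.25)     # half sibs
  expect_equal(unname(A["a", "b"]), 0)                # founders unrelated
  expect_equal(unname(diag(A)), rep(1, nrow(A)))      # non-inbred

  # founders only -> identity
  expect_equal(additive_relationship(build_pedigree(letters[1:4], cr[0, ], 0L)),
               diag(4), ignore_attr = TRUE)

  # individuals from different groups are unrelated
  cr2 <- assign_families(build_partial_diallel(c("x", "y"), group = "G2"))
  ped2 <- build_pedigree(c(letters[1:3], "x", "y"), rbind(cr, cr2), 1L)
  A2 <- additive_relationship(ped2)
  expect_equal(unname(A2["axb_1", "xxy_1"]), 0)
})

test_that("A is symmetric PSD with unit diagonal on generated pedigrees", {
  set.seed(42)
  for (k in 1:10) {
    ped <- random_two_gen_pedigree()
    A <- additive_relationship(ped)
    expect_equal(A, t(A))
    expect_equal(unname(diag(A)), rep(1, nrow(A)))
    expect_true(all(A >= 0 & A <= 1.5))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("reciprocal-cross full sibs have identical relationship rows", {
  cr <- assign_families(build_partial_diallel(letters[1:5]))
  ped <- build_pedigree(letters[1:5], cr, 1L)
  A <- additive_relationship(ped)
  i <- which(ped$id == "axb_1"); j <- which(ped$id == "bxa_1")
  expect_equal(A[i, -c(i, j)], A[j, -c(i, j)], ignore_attr = TRUE)
})

test_that("sparse A-inverse matches the dense inverse", {
  set.seed(7)
  for (k in 1:5) {
    ped <- random_two_gen_pedigree()
    A <- additive_relationship(ped)
    Ai <- as.matrix(additive_relationship_inverse(ped))
    expect_equal(Ai %*% A, diag(nrow(A)), ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("unsorted or cyclic pedigrees are rejected", {
  bad <- data.frame(id = c("o", "p"), dam = c("p", NA), sire = c(NA, NA))
  expect_error(additive_relationship(bad), "sorted|cycle")
  cyc <- data.frame(id = c("x", "y"), dam = c("y", "x"), sire = c(NA, NA))
  expect_error(additive_relationship(cyc), "sorted|cycle")
})

test_that("design validation flags selfing, missing reciprocals and imbalance", {
  cr <- assign_families(build_partial_diallel(letters[1:5], group = "G1"))
  ok <- validate_design(cr)
  expect_true(ok$ok)
  expect_true(all(ok$counts$as_dam == 4 & ok$counts$as_sire == 4))

  selfed <- rbind(cr, data.frame(dam = "a", sire = "a", group = "G1",
                                 family = "axa"))
  rep_self <- validate_design(selfed)
  expect_false(rep_self$ok)
  expect_equal(nrow(rep_self$selfings), 1)

  broken <- validate_design(cr[!(cr$dam == "b" & cr$sire == "a"), ])
  expect_false(broken$ok)
  expect_equal(nrow(broken$missing_reciprocals), 1)
  expect_true(any(!broken$counts$ok))
})

test_that("pedigree text round-trips through the 3-column dialect", {
  cr <- assign_families(build_partial_diallel(letters[1:3]))
  ped <- build_pedigree(letters[1:3], cr, 1L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_equal(back$id, ped$id)
  expect_equal(back$dam, ped$dam)
  expect_equal(back$sire, ped$sire)
  expect_equal(readLines(f)[1], "id sire dam")
})
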