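# Long-table assembly and the normalization chain. Masks must be invariant
# under every operation except assembly.

makeLongTable <- function(nS = 3, nT = 2, nC = 2, nM = 2, seed = 1) {
  df <- expand.grid(subject = sprintf("s%d", seq_len(nS)),
                    treatment = sprintf("t%d", seq_len(nT)),
                    cell_type = sprintf("c%d", seq_len(nC)),
                    marker = sprintf("m%d", seq_len(nM)),
                    stringsAsFactors = FALSE)
  df$cohort <- ifelse(df$subject == "s1", "bc", "healthy")
  df$mfi <- withr::with_seed(seed, runif(nrow(df), 1, 10))
  df
}

test_that("assembly produces the full labeled shape and masks absent keys", {
  df <- makeLongTable()
  lt <- assembleTensor(df)
  expect_equal(dim(lt), c(3L, 2L, 2L, 2L))
  expect_equal(axisNames(lt), c("subject", "treatment", "cell_type", "marker"))
  expect_true(all(tensorMask(lt)))

  # dropping one (subject, treatment) pair masks the whole 2x2 fiber
  df2 <- df[!(df$subject == "s2" & df$treatment == "t1"), ]
  lt2 <- assembleTensor(df2)
  expect_false(any(tensorMask(lt2)["s2", "t1", , ]))
  expect_equal(sum(!tensorMask(lt2)), 4L)
})

test_that("assembly rejects duplicates (naming the key) and empty tables", {
  df <- makeLongTable()
  expect_error(assembleTensor(rbind(df, df[3, ])), "duplicate key.*s3",
               ignore.case = TRUE)
  expect_error(assembleTensor(df[0, ]), "empty")
})

test_that("background subtraction is exact per-triple arithmetic, keeps negatives, keeps the mask", {
  df <- makeLongTable()
  lt <- assembleTensor(df)
  bg <- expand.grid(subject = sprintf("s%d", 1:3),
                    cell_type = sprintf("c%d", 1:2),
                    marker = sprintf("m%d", 1:2), stringsAsFactors = FALSE)
  bg$mfi <- 0
  expect_equal(tensorValues(subtractBackground(lt, bg)), tensorValues(lt))

  bg$mfi <- 4
  out <- subtractBackground(lt, bg)
  expect_equal(tensorValues(out), tensorValues(lt) - 4)
  expect_identical(tensorMask(out), tensorMask(lt))
  # 3.0 - 5.0 = -2.0 retained
  v <- tensorValues(lt); v["s1", "t1", "c1", "m1"] <- 3
  lt2 <- LabeledTensor(v)
  bg$mfi <- 5
  expect_equal(tensorValues(subtractBackground(lt2, bg))["s1", "t1", "c1", "m1"],
               -2)
  # missing background for an observed entry names the triple
  expect_error(subtractBackground(lt, bg[-1, ]), "s1/c1/m1")
})

test_that("marker-max normalization rescales each marker slab to observed max 1", {
  x <- array(NA_real_, dim = c(1, 3, 2),
             dimnames = list(subject = "s1", treatment = c("a", "b", "c"),
                             marker = c("m1", "m2")))
  x[1, , 1] <- c(2, 4, 8)
  x[1, , 2] <- c(10, 20, 5)
  lt <- LabeledTensor(x)
  out <- tensorValues(normalizeMarkerMax(lt))
  expect_equal(out[1, , 1], c(a = 0.25, b = 0.5, c = 1))
  expect_equal(out[1, , 2], c(a = 0.5, b = 1, c = 0.25))

  # masked large value is ignored by the slab maximum
  x[1, 1, 1] <- 100
  m <- !is.na(x); m[1, 1, 1] <- FALSE
  lt2 <- LabeledTensor(x, mask = m)
  out2 <- tensorValues(normalizeMarkerMax(lt2))
  bruteMax <- max(x[1, 2:3, 1])  # observed entries only
  expect_equal(out2[1, 2:3, 1], x[1, 2:3, 1] / bruteMax)
  expect_equal(max(out2[1, , 1], na.rm = TRUE), 1)

  # non-positive slab max is an error
  x[] <- -1
  expect_error(normalizeMarkerMax(LabeledTensor(x)), "non-positive")
})

test_that("marker-max normalization is scale-equivariant per slab", {
  s <- smallStudy(mode_sizes = c(treatment = 4, marker = 3), seed = 31,
                  noise_sd = 0.2)
  shifted <- tensorValues(s$tensor) + 10  # make positive
  lt <- LabeledTensor(shifted, mask = tensorMask(s$tensor))
  ref <- tensorValues(normalizeMarkerMax(lt))
  v2 <- shifted
  v2[, , 2] <- v2[, , 2] * 7.3  # rescale one marker slab
  out <- tensorValues(normalizeMarkerMax(LabeledTensor(v2, mask = tensorMask(lt))))
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("receptor z-scoring gives observed mean 0 and sample SD 1 per slab", {
  x <- array(NA_real_, dim = c(2, 1, 2),
             dimnames = list(subject = c("s1", "s2"), cell_type = "c1",
                             receptor = c("r1", "r2")))
  x[, 1, 1] <- c(1, 3)
  x[, 1, 2] <- c(5, 9)
  out <- tensorValues(zscoreReceptors(LabeledTensor(x)))
  expect_equal(out[, 1, 1], c(s1 = -1, s2 = 1) / sqrt(2), tolerance = 1e-12)

  # idempotence and independent two-pass moments on a random slab
  s <- withr::with_seed(5, array(rnorm(60, 4, 3), dim = c(5, 4, 3)))
  lt <- LabeledTensor(s, axes = c("subject", "cell_type", "receptor"))
  z1 <- zscoreReceptors(lt)
  for (r in 1:3) {
    slab <- tensorValues(z1)[, , r]
    expect_lt(abs(mean(slab)), 1e-10)
    expect_equal(sd(as.vector(slab)), 1, tolerance = 1e-10)
  }
  z2 <- zscoreReceptors(z1)
  expect_equal(tensorValues(z2), tensorValues(z1), tolerance = 1e-10)

  # zero-variance slab names the receptor
  s[, , 2] <- 7
  expect_error(zscoreReceptors(LabeledTensor(s, axes = c("subject", "cell_type", "receptor"))),
               "receptor_02")
})

test_that("fold-change transform divides by the matched baseline and sets the baseline slice to 1", {
  x <- array(2, dim = c(2, 3, 2, 2),
             dimnames = list(subject = c("s1", "s2"),
                             treatment = c("Untreated", "t1", "t2"),
                             cell_type = c("c1", "c2"),
                             marker = c("m1", "m2")))
  x["s1", "t1", "c1", "m1"] <- 8
  x["s1", "Untreated", "c1", "m1"] <- 2
  lt <- LabeledTensor(x)
  out <- foldChangeTransform(lt, "Untreated")
  expect_equal(tensorValues(out)["s1", "t1", "c1", "m1"], 4)
  expect_true(all(tensorValues(out)[, "Untreated", , ] == 1))

  # masked treated entries stay masked
  m <- tensorMask(lt); m["s2", "t2", "c2", "m2"] <- FALSE
  v <- x; v["s2", "t2", "c2", "m2"] <- NA
  out2 <- foldChangeTransform(LabeledTensor(v, mask = m), "Untreated")
  expect_false(tensorMask(out2)["s2", "t2", "c2", "m2"])

  # non-positive baseline is an error
  v2 <- x; v2["s1", "Untreated", "c2", "m1"] <- 0
  expect_error(foldChangeTransform(LabeledTensor(v2), "Untreated"),
               "baseline")
})

test_that("assemble -> write -> assemble is the identity on observed entries", {
  df <- makeLongTable(seed = 9)
  df <- df[-c(5, 12), ]  # knock out two entries
  lt <- assembleTensor(df)
  f <- tempfile(fileext = ".csv")
  writeCohortTables(lt, cohortLabelsFromTable(df), f)
  back <- assembleTensor(readCohortTable(f))
  expect_identical(dim(back), dim(lt))
  expect_identical(tensorMask(back), tensorMask(lt))
  expect_equal(tensorValues(back), tensorValues(lt), tolerance = 1e-15)
})
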