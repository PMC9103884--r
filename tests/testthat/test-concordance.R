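test_that("Lin's coefficient on analytic cases and degenerate inputs", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(linsCCC(x, x), 1)
  expect_equal(linsCCC(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_equal(linsCCC(c(1, 2, 3), c(2, 2, 4)),
               oracleCCC(c(1, 2, 3), c(2, 2, 4)), tolerance = 1e-12)

  # both constant -> undefined; one constant -> 0
  expect_true(is.na(linsCCC(c(2, 2, 2), c(5, 5, 5))))
  expect_equal(linsCCC(c(2, 2, 2), c(1, 2, 3)), 0)

  expect_error(linsCCC(1:4, 1:5), "equal length")
  expect_error(linsCCC(1:2, 2:3), "at least 3")
  expect_error(linsCCC(c(1, NA, 3), c(1, 2, 3)), "finite")

  # sample-moment variant agrees with the direct formula
  x <- rnorm(10); y <- rnorm(10)
  num <- 2 * cov(x, y)
  den <- var(x) + var(y) + (mean(x) - mean(y))^2 * 1
  # note: the mean-shift term is not rescaled by n/(n-1) in the sample form
  expect_equal(linsCCC(x, y, sample = TRUE), num / den, tolerance = 1e-12)
})

test_that("Lin's coefficient properties hold on random pairs", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    x <- rnorm(n, sample(0:5, 1), runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(n, 0, 1)
    cc <- linsCCC(x, y)
    rho <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lte(abs(cc), abs(rho) + 1e-12)   # Lin's inequality
    expect_lte(abs(cc), 1 + 1e-12)
    expect_equal(cc, linsCCC(y, x), tolerance = 1e-12)        # symmetry
    cl <- runif(1, 0.5, 2) * sample(c(-1, 1), 1)
    d <- rnorm(1)
    expect_equal(linsCCC(cl * x + d, cl * y + d), cc, tolerance = 1e-9)
  }
})

makeFS <- function(values, m, tissue = "bone", norm = "raw") {
  nm <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- nm
  rownames(values) <- paste0("S", seq_len(nrow(values)))
  TextureFeatureSet(values, m, tissue, "2D", norm,
                    families = rep(c("GLCM", "HIST"),
                                   length.out = ncol(values)))
}

test_that("per-feature concordance between tables and its edge cases", {
  set.seed(7)
  X <- cbind(rnorm(8), rnorm(8, 5), rep(3, 8), rnorm(8))
  Y <- cbind(rnorm(8), rnorm(8, 5), rep(3, 8), rnorm(8))
  a <- makeFS(X, 256); b <- makeFS(Y, 320)
  res <- cccBetweenMatrices(a, b)
  tab <- cccTable(res)
  # column-by-column oracle
  for (k in c(1, 2, 4)) {
    expect_equal(tab$rho_c[k], oracleCCC(X[, k], Y[, k]), tolerance = 1e-12)
    expect_true(tab$defined[k])
  }
  # feature constant in both tables: flagged undefined
  expect_false(tab$defined[3])
  expect_true(is.na(tab$rho_c[3]))

  # self-pairing: every defined coefficient is exactly 1
  expect_warning(selfres <- cccBetweenMatrices(a, makeFS(X, 256)),
                 "self-pairing")
  st <- cccTable(selfres)
  expect_true(all(st$rho_c[st$defined] == 1))

  bad <- makeFS(Y, 320)
  colnames(bad) <- paste0("Z", 1:8)
  expect_error(cccBetweenMatrices(a, bad), "subject sets differ")
  expect_error(cccBetweenMatrices(a, makeFS(Y, 320, tissue = "fat")),
               "strata")
})

test_that("transition aggregation: scopes, weighting and mean change", {
  sizes <- c(256L, 320L, 384L, 448L, 512L)
  mk <- function(i, j, glcmVal, histVal) {
    tab <- data.frame(
      feature = paste0("f", 1:5),
      family = c("GLCM", "GLCM", "GLCM", "HIST", "HIST"),
      rho_c = c(rep(glcmVal, 3), histVal, NA),
      rho = NA_real_, mu_i = 0, mu_j = 0, sigma_i = 1, sigma_j = 1,
      defined = c(TRUE, TRUE, TRUE, TRUE, FALSE))
    new("CCCResult", table = tab, pair = c(i, j), tissue = "bone",
        mode = "2D", normalization = "raw")
  }
  prs <- combn(sizes, 2)
  res <- lapply(seq_len(ncol(prs)), function(k) mk(prs[1, k], prs[2, k],
                                                   0.8, 0.4))
  nb <- aggregateTransitions(res, "neighboring", sizes)
  ap <- aggregateTransitions(res, "all_pairs", sizes)
  tnb <- transitionTable(nb); tap <- transitionTable(ap)
  expect_equal(length(unique(tnb$pair)), 4)
  expect_equal(length(unique(tap$pair)), 10)  # C(5, 2)

  # overall mean = defined-count-weighted mean of family means
  row <- tnb[tnb$pair == "256-320", ]
  glcmMean <- row$mean_ccc[row$family == "GLCM"]
  histMean <- row$mean_ccc[row$family == "HIST"]
  allMean <- row$mean_ccc[row$family == "ALL"]
  expect_equal(allMean, (3 * glcmMean + 1 * histMean) / 4, tolerance = 1e-12)
  expect_equal(allMean, (3 * 0.8 + 0.4) / 4, tolerance = 1e-12)
  expect_equal(row$n_excluded[row$family == "ALL"], 1)

  # identical coefficients across transitions: zero mean change
  expect_equal(meanChange(nb)$mean_abs_change, 0)

  # all-ones result: every family mean is 1
  res1 <- lapply(seq_len(ncol(prs)), function(k) mk(prs[1, k], prs[2, k],
                                                    1, 1))
  t1 <- transitionTable(aggregateTransitions(res1, "neighboring", sizes))
  expect_true(all(t1$mean_ccc == 1))

  expect_error(aggregateTransitions(res[1:3], "neighboring", sizes),
               "missing CCC result")
})
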