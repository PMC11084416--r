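test_that("percent agreement is the exact-match fraction", {
  expect_equal(percent_agreement(1:5, 1:5), 1)
  expect_equal(percent_agreement(c(1, 2, 3), c(1, 2, 4)), 2 / 3)
  a <- c(rep(1, 32), rep(2, 5)); b <- rep(1, 37)
  expect_equal(percent_agreement(a, b), 32 / 37)
  expect_error(percent_agreement(1:3, 1:4), "same length")
  expect_error(percent_agreement(integer(), integer()), "nonempty")
})

test_that("kappa is 1 on identical ratings and 0 at chance agreement", {
  r <- c("a", "b", "a", "c", "b", "a")
  expect_equal(cohen_kappa(r, r)$kappa, 1)
  # margins-product table: counts n * r_i * c_j give exactly chance-level
  # agreement (2x2 with margins (0.5, 0.5) x (0.4, 0.6), n = 20)
  a <- rep(c("x", "x", "y", "y"), c(4, 6, 4, 6))
  b <- rep(c("x", "y", "x", "y"), c(4, 6, 4, 6))
  expect_equal(cohen_kappa(a, b)$kappa, 0)
  # both raters constant on one category: expected agreement 1, undefined
  expect_error(cohen_kappa(rep("a", 5), rep("a", 5)), "undefined")
})

test_that("weighted kappa equals unweighted kappa on binary ratings", {
  withr::with_seed(42, {
    for (i in 1:25) {
      a <- sample(c("neg", "pos"), 30, replace = TRUE)
      b <- ifelse(runif(30) < 0.7, a, sample(c("neg", "pos"), 30,
                                             replace = TRUE))
      if (length(unique(c(a, b))) < 2) next
      ku <- cohen_kappa(a, b, "unweighted", categories = c("neg", "pos"))
      kl <- cohen_kappa(a, b, "linear", categories = c("neg", "pos"))
      kq <- cohen_kappa(a, b, "quadratic", categories = c("neg", "pos"))
      expect_equal(kl$kappa, ku$kappa, tolerance = 1e-12)
      expect_equal(kq$kappa, ku$kappa, tolerance = 1e-12)
      expect_equal(kl$ase, ku$ase, tolerance = 1e-12)
      expect_equal(kq$ase, ku$ase, tolerance = 1e-12)
    }
  })
})

test_that("kappa and its ASE match a loop-based oracle on random tables", {
  withr::with_seed(7, {
    for (i in 1:40) {
      n <- sample(10:50, 1)
      a <- sample(1:3, n, replace = TRUE)
      b <- ifelse(runif(n) < 0.6, a, sample(1:3, n, replace = TRUE))
      tab <- table(factor(a, 1:3), factor(b, 1:3))
      for (wt in c("unweighted", "linear", "quadratic")) {
        got <- cohen_kappa(a, b, wt, categories = 1:3)
        want <- kappa_loop_oracle(tab, wt)
        expect_equal(got$kappa, want$kappa, tolerance = 1e-10)
        expect_equal(got$ase, want$ase, tolerance = 1e-10)
        # z / p / CI are exact functions of kappa and ase
        expect_equal(got$z, got$kappa / got$ase)
        expect_equal(got$p_value, 2 * pnorm(-abs(got$z)))
        expect_equal(got$ci_low, got$kappa - qnorm(0.975) * got$ase)
        expect_equal(got$ci_high, got$kappa + qnorm(0.975) * got$ase)
      }
    }
  })
})

test_that("kappa matches independent reference implementations", {
  # fixed 3x3 table; reference values computed with an independent
  # implementation of the large-sample (alternative) variance
  tab_a <- rep(1:3, times = c(15, 15, 10))
  tab_b <- c(rep(1, 11), rep(2, 3), 3,
             rep(1, 2), rep(2, 9), rep(3, 4),
             rep(2, 2), rep(3, 8))
  ku <- cohen_kappa(tab_a, tab_b, "unweighted", categories = 1:3)
  expect_equal(ku$kappa, 0.5492957746, tolerance = 1e-9)
  expect_equal(ku$ase, 0.1084660235, tolerance = 1e-9)
  kl <- cohen_kappa(tab_a, tab_b, "linear", categories = 1:3)
  expect_equal(kl$kappa, 0.6258992806, tolerance = 1e-9)
  expect_equal(kl$ase, 0.0968708082, tolerance = 1e-9)
  kq <- cohen_kappa(tab_a, tab_b, "quadratic", categories = 1:3)
  expect_equal(kq$kappa, 0.7058823529, tolerance = 1e-9)
  expect_equal(kq$ase, 0.0937640714, tolerance = 1e-9)
  tab <- table(factor(tab_a, 1:3), factor(tab_b, 1:3))
  expect_equal(ku$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("kappa is invariant under subject permutation and relabeling", {
  withr::with_seed(99, {
    a <- sample(1:3, 40, replace = TRUE)
    b <- ifelse(runif(40) < 0.6, a, sample(1:3, 40, replace = TRUE))
    k0 <- cohen_kappa(a, b, "quadratic", categories = 1:3)
    perm <- sample(40)
    k1 <- cohen_kappa(a[perm], b[perm], "quadratic", categories = 1:3)
    expect_equal(k0$kappa, k1$kappa)
    expect_equal(k0$ase, k1$ase)
    # unweighted kappa survives arbitrary relabeling; weighted kappa only
    # order-preserving relabeling
    swap <- c(2, 3, 1) # arbitrary bijection 1:3 -> 1:3
    ku0 <- cohen_kappa(a, b, "unweighted", categories = 1:3)
    ku1 <- cohen_kappa(swap[a], swap[b], "unweighted", categories = 1:3)
    expect_equal(ku0$kappa, ku1$kappa, tolerance = 1e-12)
    shift <- a + 10; shiftb <- b + 10 # order-preserving relabeling
    kq1 <- cohen_kappa(shift, shiftb, "quadratic", categories = 11:13)
    expect_equal(k0$kappa, kq1$kappa, tolerance = 1e-12)
  })
})

test_that("Landis-Koch bands interpret kappa as published", {
  expect_equal(interpret_kappa(0.5761), "moderate")
  expect_equal(interpret_kappa(0.88), "near_perfect")
  expect_equal(interpret_kappa(0.05), "none")
  expect_equal(interpret_kappa(0.15), "slight")
  expect_equal(interpret_kappa(0.30), "fair")
  expect_equal(interpret_kappa(0.75), "substantial")
  expect_equal(interpret_kappa(0.81), "near_perfect")
  expect_equal(interpret_kappa(-0.4), "none")
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})
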