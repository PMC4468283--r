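test_that("alpha is 1 for perfect agreement and matches the hand example", {
  m <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  expect_equal(voqual:::alpha_from_matrix(m), 1)
  # 2 raters, 4 items, ((0,0),(1,1),(2,3),(3,2)): compare with the oracle
  m2 <- matrix(c(0, 0, 1, 1, 2, 3, 3, 2), ncol = 2, byrow = TRUE)
  expect_equal(voqual:::alpha_from_matrix(m2), alpha_oracle(m2),
               tolerance = 1e-12)
})

test_that("alpha equals the brute-force coincidence oracle on random panels", {
  set.seed(77)
  for (k in 1:60) {
    m <- random_small_panel()
    for (metric in c("interval", "ordinal")) {
      got <- tryCatch(voqual:::alpha_from_matrix(m, metric),
                      voq_undefined = function(e) NA_real_)
      want <- alpha_oracle(m, metric)
      if (is.na(want)) next
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("panel %d (%s)", k, metric))
    }
  }
})

test_that("alpha is permutation-invariant in raters and items", {
  set.seed(13)
  m <- matrix(sample(0:3, 40, replace = TRUE), 10, 4)
  base <- voqual:::alpha_from_matrix(m)
  for (k in 1:10) {
    m2 <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(voqual:::alpha_from_matrix(m2), base, tolerance = 1e-12)
  }
})

test_that("an item-independent rater drives alpha toward zero", {
  set.seed(31)
  true <- sample(0:3, 30, replace = TRUE)
  m <- cbind(true, true, sample(true))
  got <- voqual:::alpha_from_matrix(m)
  expect_equal(got, alpha_oracle(m), tolerance = 1e-12)
})

test_that("correlation functions match known values and invariances", {
  pe <- pearson(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pe$r, 1)
  sp <- spearman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sp$rho, 1)
  # rho = -1 under any strictly decreasing transform
  x <- c(0.3, 1.2, 2.5, 4.1, 5)
  expect_equal(spearman(x, exp(-x))$rho, -1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  # hand-ranked example: d = (-1, 1, -1, 1, 0), sum d^2 = 4
  expect_equal(spearman(1:5, c(2, 1, 4, 3, 5))$rho, 1 - 6 * 4 / (5 * 24))
  # Pearson r invariant under positive affine maps
  set.seed(8)
  a <- rnorm(20); b <- a + rnorm(20)
  expect_equal(pearson(2.5 * a + 3, b)$r, pearson(a, b)$r, tolerance = 1e-12)
  expect_equal(pearson(a, 0.1 * b - 7)$r, pearson(a, b)$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), class = "voq_undefined")
})

test_that("t-approximation p-values agree with the reference implementation", {
  set.seed(14)
  x <- rnorm(25); y <- x + rnorm(25)
  pe <- pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(pe$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pe$p, ct$p.value, tolerance = 1e-12)
})

test_that("exact permutation p-values are valid for small n", {
  set.seed(15)
  x <- rnorm(6); y <- x + 0.3 * rnorm(6)
  pe <- pearson(x, y)
  expect_gte(pe$p, 0); expect_lte(pe$p, 1)
  # p is the tail mass of |r| under permutations: perfect monotone data in
  # n = 5 has p = 2/5! * ... at least 1/|perms| and at most 1
  pe2 <- pearson(1:5, (1:5)^2)
  expect_equal(pe2$p, 2 / factorial(5))  # only identity and reverse tie it
})

test_that("rater-vs-rest agreement behaves under identity and duplication", {
  true <- matrix(rep(rep(0:3, 3), 4), ncol = 4)
  arr <- array(rep(true, 3), c(12, 4, 3),
               dimnames = list(NULL, NULL, c("R", "B", "H")))
  panel <- new_panel(arr)
  rr <- rater_vs_rest(panel, "R")
  expect_equal(rr$mean_r, 1, tolerance = 1e-12)
  # duplicated rater gets the same r as the original
  set.seed(16)
  m <- matrix(sample(0:3, 36, TRUE), 12, 3)
  m[, 3] <- m[, 1]
  arr2 <- array(rep(m, 3), c(12, 3, 3),
                dimnames = list(NULL, NULL, c("R", "B", "H")))
  rr2 <- rater_vs_rest(new_panel(arr2), "R")
  expect_equal(rr2$per_rater$r[3], rr2$per_rater$r[1], tolerance = 1e-12)
})

test_that("rater-vs-rest matches an independent recomputation on noisy panels", {
  panel <- synth_panel(seq(0, 3, length.out = 30), n_raters = 6,
                       rater_noise_sd = 0.7, seed = 99)
  rr <- rater_vs_rest(panel, "R")
  m <- unclass(panel)[, , "R"]
  direct <- mean(sapply(seq_len(ncol(m)), function(j)
    cor(m[, j], rowMeans(m[, -j]))))
  expect_equal(rr$mean_r, direct, tolerance = 0.05)
})

test_that("panel summary averages items first, then summarizes", {
  arr <- array(NA_real_, c(2, 3, 3), dimnames = list(NULL, NULL, c("R", "B", "H")))
  arr[1, , ] <- 1                   # item 1 rated 1 by everyone
  arr[2, , 1] <- c(1, 2, 2)
  arr[2, , 2] <- c(2, 1, 2)
  arr[2, , 3] <- c(1, 1, 1)
  ps <- panel_summary(new_panel(arr))
  expect_equal(ps$stats$min[ps$stats$criterion == "R"], 1)
  expect_equal(ps$stats$max[ps$stats$criterion == "R"], 5 / 3)
  # identical R and B columns give inter-criterion r = 1
  arr2 <- array(sample(0:3, 24, TRUE), c(4, 2, 3),
                dimnames = list(NULL, NULL, c("R", "B", "H")))
  arr2[, , "B"] <- arr2[, , "R"]
  ps2 <- panel_summary(new_panel(arr2))
  rb <- ps2$cross[ps2$cross$a == "R" & ps2$cross$b == "B", ]
  expect_equal(rb$r, 1, tolerance = 1e-12)
})

test_that("the agreement report carries alpha per criterion", {
  panel <- synth_panel(seq(0, 2.5, length.out = 20), n_raters = 5,
                       rater_noise_sd = 0.5, seed = 7)
  rep <- agreement_report(panel)
  expect_s3_class(rep, "voq_agreement")
  expect_equal(rep$per_criterion$criterion, c("R", "B", "H"))
  expect_true(all(rep$per_criterion$alpha <= 1))
  expect_true(all(rep$stats$mean >= 0 & rep$stats$mean <= 3))
})
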