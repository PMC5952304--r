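# brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum the probabilities (from binomial coefficients) of
# tables no more probable than the observed one
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n <- m1 + m2
  ks <- max(0, n1 - m2):min(n1, m1)
  logp <- lchoose(m1, ks) + lchoose(m2, n1 - ks) - lchoose(n, n1)
  p <- exp(logp)
  sum(p[p <= p[ks == a] * (1 + 1e-7)])
}

test_that("Fisher exact p-values match hand checks and symmetries", {
  expect_equal(fisher_exact_two_sided(c(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_two_sided(c(2, 0, 0, 2)), 1 / 3, tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(c(-1, 1, 1, 1)), "non-negative")
  expect_error(fisher_exact_two_sided(c(0, 0, 0, 0)), "at least one")

  # invariance to simultaneously swapping both rows and both columns
  set.seed(1)
  for (i in 1:50) {
    tab <- rpois(4, 5)
    if (sum(tab) == 0) next
    p1 <- fisher_exact_two_sided(tab)
    p2 <- fisher_exact_two_sided(tab[c(4, 3, 2, 1)])
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("Fisher implementation agrees with stats::fisher.test", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_two_sided(as.vector(t(tab))),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher matches brute-force enumeration on random small tables", {
  set.seed(19)
  for (i in 1:300) {
    t4 <- sample(0:12, 4, replace = TRUE)
    if (sum(t4) == 0) next
    expect_equal(fisher_exact_two_sided(t4),
                 fisher_oracle(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U and p follow the exact and approximate paths", {
  ident <- mann_whitney(1:6, 1:6)
  expect_equal(ident$U, 18)           # n1 n2 / 2
  expect_equal(ident$p.value, 1)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p.value, 0.1)      # 2 / C(6,3)

  # rank invariance under common shift/scale
  x <- c(3, 9, 4.5, 8)
  y <- c(2, 7, 7, 12, 1)
  a <- mann_whitney(x, y)
  b <- mann_whitney(10 + 2 * x, 10 + 2 * y)
  expect_equal(a$U, b$U)
  expect_equal(a$p.value, b$p.value)

  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with full permutation enumeration", {
  perm_oracle <- function(x, y) {
    n1 <- length(x)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(combn(length(r), n1), 2,
                function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  set.seed(11)
  for (i in 1:20) {
    x <- sample(1:6, 4, replace = TRUE)      # ties guaranteed sometimes
    y <- sample(1:6, 4, replace = TRUE)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p.value, perm_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney cross-checks against stats::wilcox.test", {
  set.seed(3)
  # exact path, no ties
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6)
    got <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
  # approximate path with ties
  for (i in 1:10) {
    x <- sample(1:10, 15, replace = TRUE)
    y <- sample(1:10, 15, replace = TRUE)
    got <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  }
})

make_plate <- function(dcts_by_group, hk = c(18, 17, 21)) {
  rows <- list()
  i <- 0
  for (g in names(dcts_by_group)) {
    for (dct in dcts_by_group[[g]]) {
      i <- i + 1
      s <- paste0("s", i)
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, group = g,
        gene = c("ACTB", "GAPDH", "HPRT1", "CCL2"),
        ct = c(hk, geometric_mean(hk) + dct))
    }
  }
  do.call(rbind, rows)
}

test_that("ddCt fold changes reference the control geometric-mean baseline", {
  plate <- make_plate(list(control = c(5, 5, 5), treated = c(3, 5, 7)))
  res <- ddct_fold_change(plate, "CCL2")
  ctrl <- res$group_mean$mean_fold[res$group_mean$group == "control"]
  expect_equal(ctrl, 1)                       # control group mean fold = 1
  per <- res$per_sample
  expect_equal(per$fold[per$dct == 3][1], 4)  # two cycles below -> 2^2
  expect_equal(per$fold[per$dct == 5][1], 1)

  missing_hk <- plate[!(plate$sample == "s1" & plate$gene == "GAPDH"), ]
  expect_error(ddct_fold_change(missing_hk, "CCL2"), "housekeeping")
  expect_error(ddct_fold_change(plate, "CCL2", control_group = "nope"),
               "control group")
})

test_that("FJB classification splits strictly above 10 cells", {
  expect_equal(fjb_protection_class(10), "protected")
  expect_equal(fjb_protection_class(11), "degenerating")
  expect_equal(fjb_protection_class(254), "degenerating")
  expect_equal(fjb_protection_class(0), "protected")
  expect_error(fjb_protection_class(-1), "non-negative")
})

test_that("incidence and frequency reductions reproduce the group arithmetic", {
  urethane <- group_outcome("urethane", 11, n_positive = 3, events_total = 7)
  diazepam <- group_outcome("diazepam", 10, n_positive = 10, events_total = 76)

  expect_equal(incidence_reduction(urethane, diazepam), 73)
  expect_equal(incidence_reduction(diazepam, diazepam), 0)
  zero <- group_outcome("none", 8, n_positive = 0)
  expect_equal(incidence_reduction(zero, diazepam), 100)
  expect_error(incidence_reduction(urethane, zero), "reference incidence")

  expect_equal(frequency_reduction(urethane, diazepam),
               100 * (1 - (7 / 11) / (76 / 10)), tolerance = 1e-12)
  expect_equal(frequency_reduction(diazepam, diazepam), 0)
  expect_equal(frequency_reduction(zero, diazepam), 100)
  expect_equal(frequency_reduction(urethane, diazepam, "total_count"),
               100 * (1 - 7 / 76), tolerance = 1e-12)
})

test_that("weight trajectories are expressed as percent of day 0", {
  expect_equal(percent_of_day0(c(300, 300, 300)), c(100, 100, 100))
  expect_equal(percent_of_day0(c(250, 230, 240, 240, 240))[5], 96)
  expect_equal(percent_of_day0(c(200, 100)), c(100, 50))
  expect_error(percent_of_day0(c(0, 100)), "positive")
})
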