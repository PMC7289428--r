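test_that("median and MAD follow the stated conventions", {
  expect_equal(median_mad(c(1, 2, 3), mad_constant = 1),
               c(median = 2, mad = 1))
  expect_equal(median_mad(rep(7, 5))[["mad"]], 0)
  expect_equal(median_mad(c(1, 2, 3))[["mad"]], 1.4826)
  expect_error(median_mad(numeric(0)), "no finite values")
})

test_that("dichotomisation is strict-greater with ties going low", {
  rec <- data.frame(sugar_ug = c(1, 2, 3, 4))
  expect_equal(as.character(dichotomize(rec, 2.5)$reward_class),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomize(data.frame(sugar_ug = 2), 2)$reward_class),
               "low")
  expect_true(all(dichotomize(data.frame(sugar_ug = rep(5, 4)), 5)$reward_class == "low"))
})

test_that("median split leaves floor(n/2) to ceiling(n/2) species high when values are distinct", {
  set.seed(11)
  for (n in c(5, 6, 27, 58)) {
    rec <- data.frame(sugar_ug = sample(seq_len(1000), n))
    d <- dichotomize(rec, median(rec$sugar_ug))
    nh <- sum(d$reward_class == "high")
    expect_gte(nh, floor(n / 2))
    expect_lte(nh, ceiling(n / 2))
  }
})

test_that("nested subsets reproduce the exclusion cascade", {
  comm <- make_community(community_spec(seed = 2))
  subs <- make_subsets(comm$records)
  expect_equal(vapply(subs, nrow, integer(1)),
               c(complete = 59L, SS1 = 58L, SS2 = 55L, SS3 = 27L,
                 orchids = 28L))
  expect_true(all(subs$SS1$sector != "U"))
  expect_true(all(subs$SS2$family != "Asteraceae"))
  expect_true(all(subs$orchids$family == "Orchidaceae"))
  # no UV species: SS1 equals the complete set
  no_uv <- comm$records[comm$records$sector != "U", ]
  expect_identical(make_subsets(no_uv)$SS1, make_subsets(no_uv)$complete)
  empty <- comm$records[0, ]
  expect_equal(nrow(make_subsets(empty)$SS3), 0L)
})

test_that("contingency tables count reward by sector and drop empty sectors", {
  rec <- data.frame(
    sector = c("B", "B", "BG"),
    reward_class = factor(c("high", "low", "high"), levels = c("high", "low")))
  tab <- suppressMessages(contingency_table(rec))
  expect_equal(unname(tab), matrix(c(1L, 1L, 1L, 0L), nrow = 2))
  expect_equal(colnames(tab), c("B", "BG"))
  one <- data.frame(sector = "G",
                    reward_class = factor("high", levels = c("high", "low")))
  expect_message(t1 <- contingency_table(one), "empty")
  expect_equal(sum(t1), 1L)
  expect_error(contingency_table(data.frame(sector = "B")), "dichotomised")
})

test_that("Pearson chi-square matches longhand computation and is row-symmetric", {
  expect_equal(pearson_chisq(matrix(10, 2, 2)), 0)
  tab <- matrix(c(20, 10, 10, 20), 2, 2)
  expect_equal(pearson_chisq(tab), 20 / 3)
  expect_equal(pearson_chisq(tab), chisq_oracle(tab))
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(10, 8), 2, 5)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(pearson_chisq(m), chisq_oracle(m))
    expect_equal(pearson_chisq(m[2:1, ]), pearson_chisq(m))
  }
  expect_error(pearson_chisq(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("Monte-Carlo p is reproducible, floored, and 1 for a homogeneous table", {
  tab <- matrix(c(5, 5, 5, 5), 2, 2)
  res <- monte_carlo_p(tab, n_sim = 500, seed = 9)
  expect_equal(res$p_mc, 1)  # observed chi-square is 0, no table beats it
  res2 <- monte_carlo_p(tab, n_sim = 500, seed = 9)
  expect_identical(res$p_mc, res2$p_mc)
  skew <- matrix(c(9, 0, 0, 9), 2, 2)
  p <- monte_carlo_p(skew, n_sim = 200, seed = 1)$p_mc
  expect_gte(p, 1 / 201)
})

test_that("Monte-Carlo p agrees with R's simulate.p.value convention", {
  tab <- matrix(c(8, 2, 3, 7, 5, 5), 2, 3)
  ours <- monte_carlo_p(tab, n_sim = 20000, seed = 4)
  ref <- suppressWarnings(
    chisq.test(tab, simulate.p.value = TRUE, B = 20000))
  expect_equal(ours$chisq, unname(ref$statistic))
  expect_equal(ours$p_mc, ref$p.value, tolerance = 0.02)
  # across seeds the estimator scatters no more than binomial noise allows
  ps <- vapply(1:20, function(s) monte_carlo_p(tab, 2000, s)$p_mc, numeric(1))
  pbar <- mean(ps)
  expect_lt(sd(ps), 2 * sqrt(pbar * (1 - pbar) / 2000))
})

test_that("Monte-Carlo null is calibrated on random fixed-margin tables", {
  # draw 2x5 tables from the fixed-margin null itself, test each at alpha=.05
  rs <- c(29, 29); cs <- c(12, 20, 12, 10, 4)
  set.seed(21)
  tabs <- stats::r2dtable(500, rs, cs)
  rej <- vapply(seq_along(tabs), function(i)
    monte_carlo_p(tabs[[i]], n_sim = 2000, seed = i)$p_mc < 0.05, logical(1))
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.01)
})

test_that("Kendall tau-b matches brute-force pair counting and cor.test", {
  expect_equal(kendall_tau(1:3, c(10, 20, 30))$tau, 1)
  expect_equal(kendall_tau(1:3, c(3, 2, 1))$tau, -1)
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4))$tau, 2 / 3)
  set.seed(13)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    res <- kendall_tau(x, y)
    expect_equal(res$tau, kendall_oracle(x, y), tolerance = 1e-12)
    expect_equal(res$tau, unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(1:3, rep(2, 3)), "zero variance")
  expect_error(kendall_tau(1:3, 1:4), "unequal")
})

test_that("Kendall p-values track cor.test on tied and untied data", {
  set.seed(14)
  # tied data, normal approximation path
  for (i in 1:10) {
    n <- sample(15:40, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- x + sample(0:4, n, replace = TRUE)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
    res <- kendall_tau(x, y)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
  # untied small samples, exact permutation path
  for (i in 1:10) {
    x <- sample(1:50, 8); y <- sample(1:50, 8)
    ref <- cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(kendall_tau(x, y)$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("a planted reward excess in the BLUE sector is detected", {
  spec <- community_spec(seed = 31,
                         effect = c(B = 8, BG = 1, G = 1, UG = 1, U = 1, UB = 1))
  comm <- make_community(spec)
  rep <- run_reward_analysis(comm$records, n_sim = 5000, seed = 31)
  expect_lt(rep$subsets$SS1$contingency$p_mc, 0.05)
  # and the per-sector proportions point at the planted sector
  expect_gt(rep$subsets$SS1$prop_high[["B"]],
            rep$subsets$SS1$prop_high[["BG"]])
})

test_that("the reward report carries per-subset thresholds, taus and tables", {
  comm <- make_community(community_spec(seed = 5))
  rep <- run_reward_analysis(comm$records, n_sim = 1000, seed = 5)
  expect_named(rep$subsets, c("complete", "SS1", "SS2", "SS3", "orchids"))
  for (nm in c("SS1", "SS2", "SS3")) {
    s <- rep$subsets[[nm]]
    expect_equal(s$threshold, median(s$median))
    expect_s3_class(s$contingency, "contingency_result")
    expect_equal(sum(s$contingency$table), s$n)
  }
  expect_null(rep$subsets$complete$contingency)
  expect_null(rep$subsets$orchids$contingency)
  expect_s3_class(rep$subsets$orchids$tau, "correlation_result")
  # SS1 drops only the UV species, so its table spans five sectors
  expect_equal(ncol(rep$subsets$SS1$contingency$table), 5L)
})
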