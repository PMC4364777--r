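# The binomial Xi-expression model: estimation, bias correction, calling,
# replicate reconciliation and group classification.

test_that("estimation matches the closed-form Wald interval", {
  # 12 Xi / 210 Xa reads: p-hat ~ 0.0541, 99% lower limit ~ 0.0150 > 0
  est <- estimate_escape(12, 210, r_m = 1, alpha = 0.01)
  expect_equal(est$p_hat, 12 / 222)
  z <- qnorm(1 - 0.01 / 2)
  expect_equal(est$ci_lower_raw,
               12 / 222 - z * sqrt((12 / 222) * (210 / 222) / 222),
               tolerance = 1e-12)
  expect_equal(round(est$ci_lower_raw, 4), 0.0150)
  expect_gt(est$ci_lower_raw, 0)

  # silenced gene: no Xi evidence
  est0 <- estimate_escape(0, 50)
  expect_identical(est0$p_hat, 0)
  expect_lte(est0$ci_lower_raw, 0)

  # bias correction shrinks the estimate when r_m > 1
  est_b <- estimate_escape(10, 90, r_m = 1.2)
  expect_equal(est_b$p_bar, 10 / (10 + 1.2 * 90))
  expect_lt(est_b$p_bar, est_b$p_hat)

  # n = 0 is unassessable, not an error
  expect_true(is.na(estimate_escape(0, 0)$p_hat))
})

test_that("bias-correction map is monotone and the identity at r_m = 1", {
  p <- seq(0, 1, by = 0.01)
  expect_equal(estimate_escape(0:100, 100:0, r_m = 1)$p_bar, p)
  for (rm in c(0.5, 0.9, 1.1, 1.7)) {
    pb <- estimate_escape(0:100, 100:0, r_m = rm)$p_bar
    expect_true(all(diff(pb) > 0))        # strictly increasing
    expect_equal(pb[c(1, 101)], c(0, 1))  # fixes the endpoints
  }
  # corrected CI equals uncorrected CI at r_m = 1
  a <- estimate_escape(25, 75, r_m = 1)
  expect_equal(c(a$ci_lower_raw, a$ci_upper),
               c(a$p_hat - qnorm(0.995) * sqrt(a$p_hat * (1 - a$p_hat) / 100),
                 a$p_hat + qnorm(0.995) * sqrt(a$p_hat * (1 - a$p_hat) / 100)),
               tolerance = 1e-12)
})

test_that("escape decision agrees with an independent oracle at small n", {
  # all (n0, n1) with n <= 50, against the algebraic form of the Wald
  # lower-limit sign using a second quantile source
  grid <- expand.grid(n0 = 0:50, n1 = 0:50)
  grid <- grid[grid$n0 + grid$n1 >= 1 & grid$n0 + grid$n1 <= 50, ]
  est <- estimate_escape(grid$n0, grid$n1, alpha = 0.01)
  expect_identical(est$ci_lower_raw > 0,
                   wald_lower_positive_oracle(grid$n0, grid$n1))
  # and the quantile sources agree numerically
  expect_equal(qnorm(0.995), qt(0.995, df = Inf), tolerance = 1e-12)
})

test_that("all three criteria gate the escape call, with inclusive ties", {
  est <- estimate_escape(12, 210)
  expect_true(call_escape(est, rpkm = 131, xi_srpm = 12)$is_escape)
  expect_false(call_escape(est, rpkm = 0.5, xi_srpm = 12)$is_escape)
  expect_false(call_escape(est, rpkm = 131, xi_srpm = 1.5)$is_escape)
  expect_true(call_escape(est, rpkm = 1, xi_srpm = 2)$is_escape)  # ties pass
  expect_false(call_escape(estimate_escape(0, 12), rpkm = 6,
                           xi_srpm = 0)$is_escape)
})

test_that("increasing n0 never revokes an escape call", {
  for (n1 in c(10, 90, 400)) {
    esc <- vapply(0:60, function(n0)
      call_escape(estimate_escape(n0, n1), rpkm = 10,
                  xi_srpm = 10)$is_escape, TRUE)
    expect_true(all(diff(esc) >= 0))
  }
})

test_that("Wald coverage at n = 500, p = 0.2 reaches the nominal band", {
  set.seed(42)
  n <- 500; p <- 0.2
  n0 <- rbinom(10000, n, p)
  est <- estimate_escape(n0, n - n0, alpha = 0.01)
  coverage <- mean(est$ci_lower <= p & p <= est$ci_upper)
  expect_gte(coverage, 0.98)
})

test_that("replicate reconciliation and tissue status", {
  expect_identical(combine_replicates(c(TRUE, TRUE)), "escape")
  expect_identical(combine_replicates(c(TRUE, FALSE)), "variable")
  expect_identical(combine_replicates(c(FALSE, FALSE)), "subject")
  expect_identical(combine_replicates(TRUE), "escape")   # single replicate
  expect_identical(combine_replicates(FALSE), "subject")
  expect_identical(combine_replicates(c(TRUE, FALSE),
                                      assessable = c(FALSE, FALSE)),
                   "unassessable")
  expect_identical(combine_replicates(c(TRUE, FALSE),
                                      assessable = c(TRUE, FALSE)),
                   "escape")  # the only assessable replicate escapes
  expect_error(combine_replicates(logical(0)), "no replicate")
})

test_that("group classification separates common and tissue-specific escape", {
  st <- function(b, s, o) data.frame(gene = "g",
                                     tissue = c("brain", "spleen", "ovary"),
                                     status = c(b, s, o))
  expect_identical(classify_groups(st("escape", "escape", "escape"))$group,
                   "group1")
  expect_identical(classify_groups(st("escape", "escape", "subject"))$group,
                   "group1")
  g2 <- classify_groups(st("subject", "escape", "subject"))
  expect_identical(g2$group, "group2")
  expect_identical(g2$group2_tissue, "spleen")
  # variable escape elsewhere blocks group 2
  expect_identical(classify_groups(st("variable", "escape",
                                      "subject"))$group, "none")
  expect_identical(classify_groups(st("subject", "subject",
                                      "subject"))$group, "none")
  expect_error(classify_groups(data.frame(gene = "g", tissue = "brain",
                                          status = "escape")),
               "two tissues")
})

test_that("Xi/Xa summary excludes Xist and undefined ratios", {
  one <- data.frame(gene = "g1", is_escape = TRUE, xi_srpm = 20,
                    xa_srpm = 100)
  s <- summarize_xi_xa(one)
  expect_equal(c(s$min, s$median, s$max), c(20, 20, 20))
  expect_equal(summarize_xi_xa(data.frame(
    gene = "Ddx3x", is_escape = TRUE, xi_srpm = 56,
    xa_srpm = 178))$median, 100 * 56 / 178)
  mixed <- rbind(one,
                 data.frame(gene = "Xist", is_escape = TRUE, xi_srpm = 1755,
                            xa_srpm = 4),
                 data.frame(gene = "g2", is_escape = TRUE, xi_srpm = 3,
                            xa_srpm = 0))
  s2 <- summarize_xi_xa(mixed)
  expect_identical(s2$n, 1L)
  expect_identical(s2$n_undefined_ratio, 1L)
  expect_error(summarize_xi_xa(one[0, ]), "no escape calls")
})

test_that("the fitted model object behaves like a classed R model", {
  counts <- data.frame(gene = c("g1", "g2", "g3", "autoA", "autoB"),
                       chrom = c("chrX", "chrX", "chrX", "chr1", "chr1"),
                       n0 = c(120, 0, 3, 6000, 5000),
                       n1 = c(300, 90, 500, 5500, 4500),
                       total_reads = c(2000, 400, 1800, 40000, 35000),
                       exon_length_bp = 3000, library_size = 3e7)
  fit <- xci_fit(counts)
  # r_m estimated from the autosomal rows only
  expect_equal(unname(fit$r_m), 11000 / 10000)
  expect_identical(nrow(fit$calls), 3L)  # X rows only
  expect_named(coef(fit), c("g1", "g2", "g3"))
  expect_equal(unname(coef(fit)["g1"]), 120 / (120 + 1.1 * 300))
  ci <- confint(fit)
  expect_identical(dim(ci), c(3L, 2L))
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_identical(fitted(fit), coef(fit))
  expect_s3_class(as.data.frame(fit), "data.frame")
  expect_output(print(fit), "r_m")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_identical(sims[[1]]$n0 + sims[[1]]$n1, fit$calls$n)
  # supplying r_m directly bypasses estimation
  fit2 <- xci_fit(counts, r_m = 1)
  expect_equal(unname(coef(fit2)["g1"]), 120 / 420)
  expect_error(xci_fit(counts[1:3, ]), "autosomal")
})
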