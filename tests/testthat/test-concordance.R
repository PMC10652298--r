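# Concordance statistics: same-sign flag, exact binomial test,
# correlations, over-representation.

test_that("same_sign follows the strict-sign definition", {
  expect_true(same_sign(-0.2, -1.1))
  expect_false(same_sign(0.2, -0.1))
  expect_true(same_sign(0.3, 0.001))
  expect_identical(same_sign(0, 0.5), NA)
  expect_identical(same_sign(0.5, 0), NA)
  expect_identical(same_sign(c(1, -1, 0), c(1, 1, 1)), c(TRUE, FALSE, NA))
})

test_that("exact binomial p matches hand-enumerated small cases", {
  expect_identical(binom_exact_two_sided(50, 100, 0.5), 1)
  # n = 4: pmf(0) = pmf(4) = 1/16 are the only outcomes as unlikely as k = 0
  expect_equal(binom_exact_two_sided(0, 4, 0.5), 0.125, tolerance = 1e-12)
  expect_error(binom_exact_two_sided(5, 4), "k must be")
  expect_error(binom_exact_two_sided(-1, 4), "k must be")
})

test_that("minimum-likelihood p agrees with the enumeration oracle and binom.test", {
  # independent oracle: explicit enumeration over all outcomes
  oracle <- function(k, n, p0) {
    pmf <- vapply(0:n, function(j) stats::dbinom(j, n, p0), numeric(1))
    sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  }
  for (n in c(4, 17, 100)) {
    for (k in c(0, 1, floor(n / 3), floor(n / 2), n)) {
      expect_equal(binom_exact_two_sided(k, n, 0.5), oracle(k, n, 0.5),
                   tolerance = 1e-12)
      expect_equal(binom_exact_two_sided(k, n, 0.5),
                   stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-10)
    }
  }
  # asymmetric null, where minlik and central genuinely differ
  expect_equal(binom_exact_two_sided(9, 10, 0.7),
               stats::binom.test(9, 10, 0.7)$p.value, tolerance = 1e-10)
  expect_equal(binom_exact_two_sided(9, 10, 0.7, method = "central"),
               2 * min(stats::pbinom(9, 10, 0.7),
                       stats::pbinom(8, 10, 0.7, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("binomial p is symmetric about n/2 and non-increasing in |k - n/2|", {
  for (n in c(7, 20, 101)) {
    p <- vapply(0:n, function(k) binom_exact_two_sided(k, n, 0.5), numeric(1))
    expect_equal(p, rev(p), tolerance = 1e-12)       # p(k) = p(n - k)
    lower <- p[seq_len(floor(n / 2) + 1)]            # k = 0 .. floor(n/2)
    expect_true(all(diff(lower) >= -1e-12))          # grows toward the centre
  }
})

test_that("correlations match direct-formula oracles", {
  expect_equal(cor_with_p(c(1, 2, 3), c(2, 4, 6), "pearson")$r, 1, tolerance = 1e-12)
  x <- c(5, 1, 4, 2, 3)
  expect_equal(cor_with_p(x, -x, "spearman")$r, -1, tolerance = 1e-12)
  set.seed(42)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  fit <- cor_with_p(x, y, "pearson")
  expect_equal(fit$r, r_oracle, tolerance = 1e-12)
  expect_equal(fit$p, stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  sp <- cor_with_p(x, y, "spearman")
  expect_equal(sp$r, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(cor_with_p(rep(1, 5), 1:5), "constant")
  expect_error(cor_with_p(1:2, 2:3), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rnorm(40); y <- rnorm(40)
  base <- cor_with_p(x, y, "spearman")
  for (f in list(exp, function(z) z^3, function(z) 5 * z - 2)) {
    expect_equal(cor_with_p(f(x), y, "spearman")$r, base$r, tolerance = 1e-12)
    expect_equal(cor_with_p(x, f(y), "spearman")$r, base$r, tolerance = 1e-12)
  }
})

test_that("concordance_by_scope counts, tests and correlates per scope", {
  rec <- make_records(gene = sprintf("g%d", 1:6),
                      ct = c("Ex", "Ex", "Ex", "Oli", "Oli", "Ast"),
                      coef = c(1, 1, -1, -2, 1, 0),
                      log2fc = c(0.5, -0.2, -0.4, -0.1, 0.3, 0.9))
  out <- concordance_by_scope(rec)
  all_row <- out[out$scope == "all", ]
  # the zero-coefficient record is excluded from the scope entirely
  expect_identical(all_row$n, 5L)
  expect_identical(all_row$k_same_sign, 4L)
  expect_equal(all_row$binom_p, binom_exact_two_sided(4, 5, 0.5), tolerance = 1e-12)
  ex <- out[out$scope == "Ex", ]
  expect_identical(c(ex$n, ex$k_same_sign), c(3L, 2L))
  # scope with < 3 records: counts present, correlation undefined
  oli <- out[out$scope == "Oli", ]
  expect_identical(oli$n, 2L)
  expect_true(is.na(oli$pearson_r))
  expect_false("Ast" %in% out$scope)   # its only record was unclassifiable
  # fully concordant input
  rec2 <- make_records(gene = c("a", "b", "c"), ct = "Ex",
                       coef = c(1, 2, -1), log2fc = c(2, 1, -3))
  out2 <- concordance_by_scope(rec2)
  expect_equal(out2$pct_same_sign[out2$scope == "all"], 100)
  expect_equal(out2$binom_p[out2$scope == "all"],
               binom_exact_two_sided(3, 3, 0.5), tolerance = 1e-12)
})

test_that("estimated same-sign fraction recovers the generator truth within 2 SE", {
  truth <- simulation_truth(rho = 0.37, same_sign_frac = 0.69, seed = 31)
  pd <- gen_peak_deg_tables(truth, 5000)
  res <- integrate_peaks_degs(pd$peaks, pd$degs)
  conc <- concordance_by_scope(res$records)
  all_row <- conc[conc$scope == "all", ]
  se <- sqrt(0.69 * 0.31 / all_row$n)
  expect_lt(abs(all_row$pct_same_sign / 100 - 0.69), 2 * se)
  # Pearson estimate lands near the calibrated target as well
  expect_lt(abs(all_row$pearson_r - 0.37), 3 * (1 - 0.37^2) / sqrt(all_row$n))
})

test_that("hypergeometric over-representation matches tail enumeration", {
  universe <- sprintf("u%02d", 1:20)
  term_genes <- universe[1:5]
  query <- c(universe[1:3], universe[18:19])   # overlap 3
  go <- make_go("some pathway", list(term_genes))
  out <- hypergeom_overrep(query, go, universe)
  p_oracle <- sum(vapply(3:5, function(j)
    choose(5, j) * choose(15, 5 - j), numeric(1))) / choose(20, 5)
  expect_equal(out$p, p_oracle, tolerance = 1e-12)
  expect_identical(out$overlap, 3L)
  # disjoint term
  go2 <- make_go(c("hit", "miss"), list(universe[1:4], universe[10:12]))
  out2 <- hypergeom_overrep(universe[1:4], go2, universe)
  expect_equal(out2$p[out2$term_name == "miss"], 1, tolerance = 1e-12)
  expect_identical(out2$overlap[out2$term_name == "miss"], 0L)
  # query equal to a term in a 10x universe: that term dominates
  big_universe <- sprintf("g%03d", 1:50)
  go3 <- make_go(c("target", "broad"),
                 list(big_universe[1:5], big_universe[1:30]))
  out3 <- hypergeom_overrep(big_universe[1:5], go3, big_universe)
  expect_lt(out3$p[out3$term_name == "target"], out3$p[out3$term_name == "broad"])
  expect_identical(out3$overlap[out3$term_name == "target"], 5L)
  expect_error(hypergeom_overrep("zzz", go3, big_universe), "subset")
  expect_error(hypergeom_overrep("g001", go3, character(0)), "empty universe")
})
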