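test_that("cpm matches its definition", {
  m <- matrix(c(100L, 0L, 5L), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(cpm(m, lib.sizes = 1e6)[, 1],
               c(g1 = 100, g2 = 0, g3 = 5))
  expect_equal(unname(cpm(m, lib.sizes = 2e6)["g3", 1]), 2.5)
  expect_error(cpm(m, lib.sizes = 0), class = "stratomics_input_error")
})

test_that("expression filter keeps cpm>1-in-two features and drops zeros", {
  libs <- rep(1e6, 4)
  m <- rbind(kept = c(2L, 2L, 0L, 0L),      # cpm 2 in two samples
             onehigh = c(5L, 0L, 0L, 0L),   # cpm >1 in one sample only
             boundary = c(1L, 1L, 1L, 1L),  # cpm exactly 1: strict, dropped
             zero = c(0L, 0L, 0L, 0L))
  colnames(m) <- paste0("s", 1:4)
  f <- filter_low_expression(m, lib.sizes = libs)
  expect_identical(rownames(f), "kept")
})

test_that("TMM factors are 1 for proportional columns and geo-mean 1", {
  m <- cbind(a = c(10L, 20L, 30L, 5L, 100L), b = c(20L, 40L, 60L, 10L, 200L))
  rownames(m) <- paste0("g", 1:5)
  f <- tmm_norm_factors(m)
  expect_equal(unname(f), c(1, 1))
  set.seed(5)
  m2 <- matrix(rnbinom(200 * 6, size = 5, mu = 50), 200, 6,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  f2 <- tmm_norm_factors(m2)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(101)
  g <- rep(c("a", "b"), each = 20)
  y0 <- matrix(rpois(2000 * 40, 100), 2000, 40,
               dimnames = list(paste0("g", 1:2000), paste0("s", 1:40)))
  expect_lt(estimate_common_dispersion(y0, g), 0.02)
  y4 <- matrix(rnbinom(2000 * 40, size = 1 / 0.4, mu = 100), 2000, 40,
               dimnames = dimnames(y0))
  phi <- estimate_common_dispersion(y4, g)
  expect_gt(phi, 0.3); expect_lt(phi, 0.5)
  const <- matrix(7L, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(estimate_common_dispersion(const, c("a", "a", "b", "b")), 0)
  expect_warning(z <- estimate_common_dispersion(
    matrix(0L, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
    c("a", "a", "b", "b")), "all-zero")
  expect_equal(z, 0)
})

test_that("exact test reproduces the binomial case and hand fold changes", {
  expect_equal(stratomics:::exact_nb_pvalue(3, 7, 1, 1, 0), 352 / 1024)
  m <- matrix(c(40L, 10L), 1, 2, dimnames = list("g", c("c1", "n1")))
  d <- exact_test(m, "c1", "n1", 0, lib.sizes = c(c1 = 1e6, n1 = 1e6),
                  prior.cpm = 0)
  expect_equal(d$log2fc, 2)
  m2 <- matrix(c(10L, 10L), 1, 2, dimnames = list("g", c("c1", "n1")))
  d2 <- exact_test(m2, "c1", "n1", 0.2, lib.sizes = c(c1 = 1e6, n1 = 1e6),
                   prior.cpm = 0)
  expect_equal(d2$log2fc, 0)
  expect_error(exact_test(m, character(0), "n1", 0, c(c1 = 1e6, n1 = 1e6)),
               class = "stratomics_input_error")
})

test_that("swapping group labels negates log2fc and keeps p", {
  set.seed(77)
  m <- matrix(rnbinom(100 * 8, size = 10, mu = 60), 100, 8,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  libs <- colSums(m)
  d1 <- exact_test(m, a, b, 0.1, libs)
  d2 <- exact_test(m, b, a, 0.1, libs)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$pvalue, d2$pvalue)
  expect_true(all(d1$pvalue >= 0 & d1$pvalue <= 1))
  expect_true(all(d1$padj >= d1$pvalue - 1e-15))
})

test_that("DE calls use strict thresholds", {
  tab <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(1.2, 1.0, -1.4, -0.2),
                    pvalue = c(0.01, 0.01, 0.04, 0.001))
  calls <- call_de(tab)
  expect_identical(calls$up, "a")     # b is at the boundary: excluded
  expect_identical(calls$down, "c")
})

test_that("TF annotation is a plain case-sensitive intersection", {
  r <- annotate_tfs(up = c("A", "b"), down = c("A2", "B2"),
                    tf_list = c("B2", "C", "B"))
  expect_identical(r$tf_up, character(0))
  expect_identical(r$tf_down, "B2")
  expect_true(all(c(r$tf_up, r$tf_down) %in% c("A", "b", "A2", "B2")))
  expect_error(annotate_tfs("A", "B", character(0)),
               class = "stratomics_input_error")
})

test_that("exact test agrees with edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  m <- matrix(rnbinom(300 * 10, size = 1 / 0.15, mu = 80), 300, 10,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:10)))
  a <- paste0("s", 1:5); b <- paste0("s", 6:10)
  libs <- rep(sum(m) / 10, 10)  # equal libraries: no pseudo-count drift
  mine <- exact_test(m, a, b, 0.15, lib.sizes = libs)
  ref <- edgeR::exactTestBySmallP(
    y1 = m[, a], y2 = m[, b], dispersion = 0.15)
  expect_equal(mine$pvalue, pmin(1, ref), tolerance = 1e-8)
})
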