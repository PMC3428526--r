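test_that("Fisher exact p agrees with stats::fisher.test", {
  # fixed extreme table plus a random battery
  expect_equal(fisher_exact_2x2(5, 0, 95, 100),
               fisher.test(matrix(c(5, 95, 0, 100), 2))$p.value,
               tolerance = 1e-12)
  withr::with_seed(17, {
    for (i in 1:200) {
      cells <- rpois(4, sample(c(1, 5, 40), 1))
      got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
      want <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("two-sided Fisher p is symmetric in the group columns", {
  withr::with_seed(43, {
    for (i in 1:50) {
      cells <- rpois(4, 8)
      expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                   fisher_exact_2x2(cells[2], cells[1], cells[4], cells[3]),
                   tolerance = 1e-12)
    }
  })
})

test_that("doubling the evidence never weakens the Fisher p", {
  for (a in 0:6) for (b in 0:6) {
    p1 <- fisher_exact_2x2(a, b, 20 - a, 20 - b)
    p2 <- fisher_exact_2x2(2 * a, 2 * b, 40 - 2 * a, 40 - 2 * b)
    expect_lte(p2, p1 + 1e-12)
  }
})

make_presence_fixture <- function() {
  samples <- paste0("s", 1:9)
  baseline <- rnorm(5, 20, 2)   # protein baselines dominate per-sample spread
  log2m <- baseline + matrix(rnorm(5 * 9, 0, 0.3), 5, 9,
                             dimnames = list(paste0("P", 1:5), samples))
  counts <- matrix(rpois(45, 10), 5, 9,
                   dimnames = list(paste0("P", 1:5), samples))
  # P1: present in group A only, strongly
  log2m["P1", 6:9] <- NA
  counts["P1", ] <- c(30L, 28L, 35L, 32L, 31L, 0L, 0L, 0L, 0L)
  prot <- protein_table_from_log2(log2m, counts)
  list(prot = prot, design = exp_design(samples, 5))
}

test_that("spectral-count Fisher test flags one-group proteins", {
  withr::with_seed(47, {
    fx <- make_presence_fixture()
    fis <- fisher_presence(fx$prot, fx$design)
    expect_true(fis$fisher_hit[fis$protein_group_id == "P1"])
    expect_identical(fis$direction[fis$protein_group_id == "P1"], "A")
    # identical counts, equal totals: p = 1
    even <- protein_quant_table(
      c("Q1", "Q2"), list("Q1", "Q2"), c(FALSE, FALSE),
      matrix(2, 2, 4, dimnames = list(NULL, paste0("s", 1:4))),
      matrix(5L, 2, 4, dimnames = list(NULL, paste0("s", 1:4))))
    d4 <- exp_design(paste0("s", 1:4), 2)
    fe <- fisher_presence(even, d4)
    expect_equal(fe$fisher_p, c(1, 1))
    # zero counts in both groups: invalid test, p = 1
    zero <- protein_quant_table(
      c("Q1", "Q2"), list("Q1", "Q2"), c(FALSE, FALSE),
      matrix(2, 2, 4, dimnames = list(NULL, paste0("s", 1:4))),
      matrix(c(0L, 0L, 0L, 0L, 5L, 5L, 5L, 5L), 2, 4, byrow = TRUE,
             dimnames = list(NULL, paste0("s", 1:4))))
    fz <- fisher_presence(zero, d4)
    expect_false(fz$valid_test[1])
    expect_equal(fz$fisher_p[1], 1)
  })
})

test_that("imputation only fills missing cells, reproducibly", {
  withr::with_seed(53, {
    m <- matrix(rnorm(60, 20, 2), 10, 6,
                dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
    miss <- sample(60, 18)
    m[miss] <- NA
    spec <- imputation_spec(seed = 99)
    i1 <- impute_downshifted_normal(m, spec)
    i2 <- impute_downshifted_normal(m, spec)
    expect_identical(i1, i2)
    expect_equal(i1[!is.na(m)], m[!is.na(m)])
    expect_false(anyNA(i1))
    # complete matrix returned unchanged
    full <- matrix(rnorm(12, 20), 3, 4,
                   dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
    expect_identical(impute_downshifted_normal(full, spec), full)
    # a column with < 2 observations cannot be imputed
    m2 <- m
    m2[2:10, 1] <- NA
    expect_error(impute_downshifted_normal(m2, spec), "s1")
  })
})

test_that("imputed values follow the downshifted normal distribution", {
  withr::with_seed(59, {
    n <- 2e5
    m <- matrix(NA_real_, n, 1, dimnames = list(NULL, "s1"))
    m[1:1000, 1] <- rnorm(1000, 20, 2)
    mu <- mean(m[1:1000, 1]); sdv <- sd(m[1:1000, 1])
    out <- impute_downshifted_normal(m, imputation_spec(0.3, 1.8, seed = 2))
    imp <- out[1001:n, 1]
    expect_lt(abs(mean(imp) - (mu - 1.8 * sdv)), 0.02 * sdv)
    expect_lt(abs(sd(imp) / (0.3 * sdv) - 1), 0.02)
  })
})

test_that("presence branch consolidates extreme separations and nests", {
  withr::with_seed(61, {
    samples <- paste0("s", 1:9)
    P <- 40
    log2m <- rnorm(P, 20, 2) +
      matrix(rnorm(P * 9, 0, 0.3), P, 9,
             dimnames = list(sprintf("P%02d", 1:P), samples))
    counts <- matrix(rpois(P * 9, 10), P, 9,
                     dimnames = list(sprintf("P%02d", 1:P), samples))
    log2m["P01", 6:9] <- NA
    counts["P01", ] <- c(40L, 45L, 38L, 42L, 41L, 0L, 0L, 0L, 0L)
    prot <- protein_table_from_log2(log2m, counts)
    des <- exp_design(samples, 5)
    res <- run_presence_branch(prot, des, imputation_spec(seed = 4),
                               seed = 4)
    expect_true(res$consolidated[res$protein_group_id == "P01"])
    expect_true(all(res$fisher_hit[res$consolidated]))
  })
})

test_that("branch overlap reports intersection and direction concordance", {
  ab <- data.frame(protein_group_id = c("P1", "P2", "P3"),
                   refined = c(TRUE, TRUE, FALSE),
                   mean_diff = c(2, -1, 0), stringsAsFactors = FALSE)
  attr(ab, "groups") <- c("A", "B")
  pr <- data.frame(protein_group_id = c("P1", "P2", "P3"),
                   consolidated = c(TRUE, FALSE, TRUE),
                   direction = c("B", "A", "A"), stringsAsFactors = FALSE)
  ov <- branch_overlap(ab, pr)
  expect_identical(ov$shared, "P1")
  expect_identical(ov$only_abundance, "P2")
  expect_identical(ov$only_presence, "P3")
  # P1 up in B by abundance (positive diff) and excess counts in B: concordant
  expect_true(ov$concordant[["P1"]])
  # disjoint and identical sets
  pr2 <- pr; pr2$consolidated <- c(FALSE, FALSE, TRUE)
  expect_length(branch_overlap(ab, pr2)$shared, 0)
  pr3 <- pr; pr3$consolidated <- c(TRUE, TRUE, FALSE)
  expect_setequal(branch_overlap(ab, pr3)$shared, c("P1", "P2"))
})
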