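test_that("top-peptide selection ranks by median and breaks ties by key", {
  samples <- paste0("s", 1:4)
  m <- matrix(rep(c(5, 3, 3, 1), each = 4), 4, 4, byrow = TRUE,
              dimnames = list(c("ZPEP", "BPEP", "APEP", "CPEP"), samples))
  sel <- select_top_peptides(m, k = 3)
  # tie between APEP and BPEP at median 3: lexicographic order decides
  expect_identical(rownames(sel), c("ZPEP", "APEP", "BPEP"))
  expect_identical(rownames(select_top_peptides(m, k = 10)),
                   c("ZPEP", "APEP", "BPEP", "CPEP"))
})

test_that("zero-noise equal groups give no group effect", {
  m <- matrix(rep(c(20, 22), each = 6), 2, 6, byrow = TRUE,
              dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  grp <- rep(c("A", "B"), each = 3)
  fit <- fit_me_anova(m, grp)
  expect_equal(fit$group_effect, 0, tolerance = 1e-10)
  expect_equal(fit$p_value, 1)
})

test_that("single peptide with plain weighting equals the pooled t-test", {
  withr::with_seed(5, {
    x <- rnorm(4, 20); y <- rnorm(4, 21)
    m <- matrix(c(x, y), 1, dimnames = list("p1", paste0("s", 1:8)))
    grp <- rep(c("A", "B"), each = 4)
    fit <- fit_me_anova(m, grp, robust = FALSE)
    oracle <- t.test(y, x, var.equal = TRUE)
    expect_equal(fit$p_value, oracle$p.value, tolerance = 1e-10)
    expect_equal(fit$group_effect, mean(y) - mean(x), tolerance = 1e-10)
  })
})

test_that("additive peptide offsets and an exact group shift are separated", {
  samples <- paste0("s", 1:8)
  grp <- rep(c("A", "B"), each = 4)
  base <- c(rep(20, 4), rep(21, 4))   # group shift exactly 1
  m <- rbind(p1 = base, p2 = base + 2)
  colnames(m) <- samples
  fit <- fit_me_anova(m, grp)
  expect_equal(fit$group_effect, 1, tolerance = 1e-9)
  expect_equal(fit$n_peptides_used, 2)
})

test_that("non-robust fit equals the normal-equations solution", {
  withr::with_seed(11, {
    m <- matrix(rnorm(24, 20), 3, 8,
                dimnames = list(paste0("p", 1:3), paste0("s", 1:8)))
    m[sample(24, 4)] <- NA
    grp <- rep(c("A", "B"), each = 4)
    fit <- fit_me_anova(m, grp, robust = FALSE)
    # oracle: explicit normal equations on the same long-format design
    obs <- which(!is.na(m), arr.ind = TRUE)
    y <- m[obs]
    g <- as.integer(grp[obs[, 2]] == "B")
    pep <- factor(rownames(m)[obs[, 1]])
    X <- cbind(1, g, model.matrix(~pep)[, -1])
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(fit$group_effect, beta[2], tolerance = 1e-9)
  })
})

test_that("robust fit downweights a gross outlier more than least squares", {
  withr::with_seed(13, {
    m <- matrix(rnorm(18, 20, 0.1), 2, 9,
                dimnames = list(c("p1", "p2"), paste0("s", 1:9)))
    m[2, ] <- m[2, ] + 1
    grp <- c(rep("A", 5), rep("B", 4))
    m[1, 9] <- m[1, 9] + 8   # one wild cell in group B
    eff_robust <- fit_me_anova(m, grp, robust = TRUE)$group_effect
    eff_ols <- fit_me_anova(m, grp, robust = FALSE)$group_effect
    expect_lt(abs(eff_robust), abs(eff_ols))
  })
})

test_that("group effect inestimable under one-group observation is flagged", {
  m <- matrix(NA_real_, 1, 6, dimnames = list("p1", paste0("s", 1:6)))
  m[1, 1:3] <- c(20, 20.1, 19.9)   # observed in group A only
  fit <- fit_me_anova(m, rep(c("A", "B"), each = 3))
  expect_false(fit$converged)
  expect_true(is.na(fit$p_value))
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "domain")
  withr::with_seed(19, {
    for (i in 1:20) {
      p <- runif(50)^2
      p[sample(50, 5)] <- NA
      got <- bh_adjust(p)
      ok <- !is.na(p)
      expect_equal(got[ok], p.adjust(p[ok], method = "BH"))
      expect_true(all(is.na(got[!ok])))
      # monotone: adjusted order preserves raw order
      o <- order(p[ok])
      expect_true(all(diff(got[ok][o]) > -1e-12))
    }
  })
})

test_that("Welch t-test matches stats::t.test and handles degeneracy", {
  withr::with_seed(23, {
    m <- matrix(rnorm(27, 20), 3, 9,
                dimnames = list(paste0("p", 1:3), paste0("s", 1:9)))
    des <- exp_design(colnames(m), 5)
    tt <- group_ttest(m, des)
    for (i in 1:3) {
      oracle <- t.test(m[i, 6:9], m[i, 1:5])
      expect_equal(tt$p_value[i], oracle$p.value, tolerance = 1e-9)
      expect_equal(tt$t_statistic[i], unname(oracle$statistic),
                   tolerance = 1e-9)
    }
  })
  # identical constant groups: t = 0, p = 1
  m0 <- matrix(5, 1, 6, dimnames = list("p1", paste0("s", 1:6)))
  tt0 <- group_ttest(m0, exp_design(colnames(m0), 3))
  expect_equal(tt0$t_statistic, 0)
  expect_equal(tt0$p_value, 1)
  # clear separation with tiny jitter: p below 1e-6
  m1 <- matrix(c(0, 0, 0, 1, 1, 1) + 1e-6 * c(1, -1, 0, 1, -1, 0), 1,
               dimnames = list("p1", paste0("s", 1:6)))
  tt1 <- group_ttest(m1, exp_design(colnames(m1), 3))
  expect_lt(tt1$p_value, 1e-6)
})

test_that("swapping group labels negates t and keeps p", {
  withr::with_seed(29, {
    m <- matrix(rnorm(18, 20), 2, 9,
                dimnames = list(c("p1", "p2"), paste0("s", 1:9)))
    d1 <- study_design(colnames(m), rep("EXPERIMENTAL", 9),
                       c(rep("A", 5), rep("B", 4)))
    d2 <- study_design(colnames(m), rep("EXPERIMENTAL", 9),
                       c(rep("B", 5), rep("A", 4)))
    t1 <- group_ttest(m, d1)
    t2 <- group_ttest(m, d2)
    expect_equal(t1$t_statistic, -t2$t_statistic)
    expect_equal(t1$p_value, t2$p_value)
    expect_equal(t1$mean_diff, -t2$mean_diff)
  })
})

test_that("proteins with too few observations defer to the presence branch", {
  m <- matrix(c(20, 21, 20.5, NA, NA, NA, NA, NA, 20), 1,
              dimnames = list("p1", paste0("s", 1:9)))
  tt <- group_ttest(m, exp_design(colnames(m), 5))
  expect_true(is.na(tt$p_value))
})

test_that("permutation FDR is deterministic and ranks extreme proteins first", {
  withr::with_seed(31, {
    m <- matrix(rnorm(50 * 9), 50, 9,
                dimnames = list(paste0("p", 1:50), paste0("s", 1:9)))
    m[1, 6:9] <- m[1, 6:9] + 10   # one overwhelming effect
    des <- exp_design(colnames(m), 5)
    tt <- group_ttest(m, des)
    t_obs <- setNames(tt$t_statistic, rownames(m))
    q1 <- permutation_fdr(t_obs, m, des, n_perm = 250, seed = 7)
    q2 <- permutation_fdr(t_obs, m, des, n_perm = 250, seed = 7)
    expect_identical(q1, q2)
    expect_equal(q1[[1]], 0)
    expect_true(all(q1 >= 0 & q1 <= 1, na.rm = TRUE))
    # monotone non-increasing in |t|
    o <- order(abs(t_obs))
    expect_true(all(diff(q1[o]) < 1e-12))
    expect_error(permutation_fdr(t_obs, m, des, n_perm = 5), "n_perm")
  })
})

test_that("a 5-vs-4 design enumerates all 125 non-identity label splits", {
  withr::with_seed(37, {
    m <- matrix(rnorm(10 * 9), 10, 9,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:9)))
    des <- exp_design(colnames(m), 5)
    tt <- group_ttest(m, des)
    t_obs <- setNames(tt$t_statistic, rownames(m))
    # enumeration makes the result independent of the seed
    qa <- permutation_fdr(t_obs, m, des, n_perm = 250, seed = 1)
    qb <- permutation_fdr(t_obs, m, des, n_perm = 250, seed = 999)
    expect_identical(qa, qb)
  })
})

test_that("fully null data yields uninformative q values", {
  withr::with_seed(41, {
    m <- matrix(rnorm(1000 * 9), 1000, 9,
                dimnames = list(paste0("p", 1:1000), paste0("s", 1:9)))
    des <- exp_design(colnames(m), 5)
    tt <- group_ttest(m, des)
    q <- permutation_fdr(setNames(tt$t_statistic, rownames(m)), m, des,
                         n_perm = 125, seed = 3)
    expect_gte(median(q, na.rm = TRUE), 0.5)
  })
})

test_that("abundance branch nests refined inside pre-selected", {
  ds <- generate_dataset(simulation_config(n_proteins = 60, frac_de = 0.2,
                                           seed = 101))
  filt <- filter_peptides(ds$peptides, ds$design)
  fw <- drop_reverse_proteins(ds$proteins)
  res <- run_abundance_branch(filt, fw, ds$design, seed = 101)
  expect_true(all(res$preselected[res$refined]))
  expect_gte(sum(res$preselected), sum(res$refined))
  # statistics invariant under joint column+label permutation
  perm <- withr::with_seed(1, sample(ncol(ds$peptides$intensity)))
  pep2 <- peptide_quant_table(filt$peptide_key, filt$protein_group_ids,
                              filt$is_reverse,
                              filt$intensity[, perm, drop = FALSE],
                              filt$msms_count[, perm, drop = FALSE])
  res2 <- run_abundance_branch(pep2, fw, ds$design, seed = 101)
  expect_equal(res2$p_meanova, res$p_meanova, tolerance = 1e-9)
})
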