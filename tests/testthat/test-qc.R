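make_qc_fixture <- function() {
  # 4 WTL replicates + 4 experimental samples, 6 peptides
  samples <- c(paste0("w", 1:4), paste0("e", 1:4))
  intensity <- matrix(100, 6, 8, dimnames = list(NULL, samples))
  intensity[1, "w1"] <- NA                 # peptide 1 in 3/4 WTL (high tier)
  intensity[2, c("w1", "w2")] <- NA        # 2/4 (medium)
  intensity[3, c("w1", "w2", "w3")] <- NA  # 1/4 (low)
  pep <- peptide_quant_table(paste0("PEP", 1:6),
                             c(list("P1"), list(c("P1", "P2")),
                               as.list(paste0("P", 2:5))),
                             rep(FALSE, 6), intensity)
  design <- study_design(samples,
                         c(rep("WTL-CTRL", 4), rep("EXPERIMENTAL", 4)),
                         c(rep("", 4), "A", "A", "B", "B"))
  list(pep = pep, design = design)
}

test_that("identification counts tally observed features per sample", {
  fx <- make_qc_fixture()
  counts <- identification_counts(fx$pep, fx$design)
  expect_equal(counts$n_total[counts$sample_id == "w1"], 3)
  expect_equal(counts$n_total[counts$sample_id == "e1"], 6)
  # unique-only never exceeds the total
  expect_true(all(counts$n_unique <= counts$n_total))
  expect_equal(counts$n_unique[counts$sample_id == "e1"], 5)
})

test_that("count summaries follow the mean/sd/CV formulas", {
  counts <- data.frame(sample_id = c("a", "b"), n_total = c(90, 110))
  des <- study_design(c("a", "b"), rep("WTL-CTRL", 2), c("", ""))
  s <- count_summary(counts, des, "WTL-CTRL")
  expect_equal(s$mean, 100)
  expect_equal(s$sd, sd(c(90, 110)))
  expect_equal(s$cv_pct, 100 * sd(c(90, 110)) / 100, tolerance = 1e-9)
  # scale invariance of the CV
  counts10 <- counts; counts10$n_total <- 10 * counts10$n_total
  s10 <- count_summary(counts10, des, "WTL-CTRL")
  expect_equal(s10$cv_pct, s$cv_pct)
  expect_equal(s10$mean, 10 * s$mean)
  # constant counts: zero sd and CV
  counts0 <- data.frame(sample_id = c("a", "b"), n_total = c(100, 100))
  expect_equal(count_summary(counts0, des, "WTL-CTRL")$cv_pct, 0)
})

test_that("pairwise Pearson uses shared observations and is symmetric", {
  withr::with_seed(83, {
    m <- matrix(rnorm(40, 20), 10, 4,
                dimnames = list(paste0("p", 1:10),
                                c("w1", "w2", "w3", "w4")))
    m[, "w2"] <- m[, "w1"]          # duplicated column
    m[1:3, "w3"] <- NA
    des <- study_design(colnames(m), rep("WTL-CTRL", 4), rep("", 4))
    pp <- pairwise_pearson(m, des, "WTL-CTRL")
    expect_equal(pp$cor["w1", "w2"], 1)
    expect_equal(pp$cor, t(pp$cor))
    expect_equal(unname(diag(pp$cor)), rep(1, 4))
    # oracle: explicit covariance/sd formula on the shared positions
    sh <- !is.na(m[, "w1"]) & !is.na(m[, "w3"])
    x <- m[sh, "w1"]; y <- m[sh, "w3"]
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pp$cor["w1", "w3"], r_hand, tolerance = 1e-12)
  })
})

test_that("a pair with too few shared observations is excluded with warning", {
  m <- matrix(c(1, 2, 3, 4, NA, NA, NA, 5), 4, 2,
              dimnames = list(paste0("p", 1:4), c("a", "b")))
  des <- study_design(c("a", "b"), rep("LCM-CTRL", 2), c("", ""))
  expect_warning(pp <- pairwise_pearson(m, des, "LCM-CTRL"), "a/b")
  expect_true(is.na(pp$cor["a", "b"]))
})

test_that("reproducibility tiers match the 33/67 percent bands", {
  fx <- make_qc_fixture()
  tiers <- reproducibility_tiers(fx$pep, fx$design, "WTL-CTRL")
  # 6 peptides observed in >= 1 WTL sample: 4x full + 1x 3/4 high;
  # 2/4 medium; 1/4 low
  expect_equal(tiers$n_features, 6)
  expect_equal(tiers$high, 4 / 6)   # 3 complete + one at 3/4
  expect_equal(tiers$medium, 1 / 6)
  expect_equal(tiers$low, 1 / 6)
  expect_equal(tiers$low + tiers$medium + tiers$high, 1, tolerance = 1e-9)
})

test_that("tier boundaries resolve exactly at 1/3 and 2/3", {
  samples <- paste0("w", 1:12)
  intensity <- matrix(NA_real_, 3, 12, dimnames = list(NULL, samples))
  intensity[1, 1:4] <- 100   # 4/12 = 33.3 % -> low
  intensity[2, 1:6] <- 100   # 6/12 = 50 % -> medium
  intensity[3, 1:8] <- 100   # 8/12 = 66.7 % -> high
  pep <- peptide_quant_table(paste0("PEP", 1:3),
                             as.list(paste0("P", 1:3)), rep(FALSE, 3),
                             intensity)
  des <- study_design(samples, rep("WTL-CTRL", 12), rep("", 12))
  tiers <- reproducibility_tiers(pep, des, "WTL-CTRL")
  expect_equal(tiers$low, 1 / 3)
  expect_equal(tiers$medium, 1 / 3)
  expect_equal(tiers$high, 1 / 3)
  expect_equal(tiers$low + tiers$medium + tiers$high, 1, tolerance = 1e-9)
})

test_that("feature CVs are computed on the linear scale over multi-sample features", {
  samples <- c("w1", "w2", "w3")
  intensity <- matrix(c(100, 100, 100,
                        50, 150, NA,
                        80, NA, NA), 3, 3, byrow = TRUE,
                      dimnames = list(NULL, samples))
  pep <- peptide_quant_table(paste0("PEP", 1:3), as.list(paste0("P", 1:3)),
                             rep(FALSE, 3), intensity)
  des <- study_design(samples, rep("WTL-CTRL", 3), rep("", 3))
  cv <- feature_cv(pep, des, "WTL-CTRL")
  expect_length(cv$cv_pct, 2)   # the single-observation feature is excluded
  expect_equal(unname(cv$cv_pct[1]), 0)
  expect_equal(unname(cv$cv_pct[2]), 100 * sd(c(50, 150)) / 100,
               tolerance = 1e-9)
})

test_that("set overlap partitions the union", {
  ov <- set_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_union, 4)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$n_only_a, 1)
  expect_equal(ov$n_only_b, 1)
  expect_equal(ov$n_union, ov$n_shared + ov$n_only_a + ov$n_only_b)
  same <- set_overlap(c("a", "b"), c("a", "b"))
  expect_equal(same$pct_shared, 100)
  expect_equal(set_overlap(c("a"), c("b"))$n_shared, 0)
})

test_that("QC metrics are invariant to feature row order", {
  fx <- make_qc_fixture()
  perm <- c(4, 1, 6, 2, 5, 3)
  pep2 <- subset_peptides(fx$pep, perm)
  t1 <- reproducibility_tiers(fx$pep, fx$design, "WTL-CTRL")
  t2 <- reproducibility_tiers(pep2, fx$design, "WTL-CTRL")
  expect_equal(t1[c("low", "medium", "high")], t2[c("low", "medium", "high")])
  c1 <- identification_counts(fx$pep)
  c2 <- identification_counts(pep2)
  expect_equal(c1$n_total, c2$n_total)
})

test_that("the full QC report assembles every section and writes a TSV", {
  withr::with_seed(89, {
    ds <- generate_dataset(simulation_config(
      n_proteins = 40, n_wtl_ctrl = 4, n_lcm_ctrl = 3, frac_de = 0.1,
      seed = 17))
    rep <- qc_report(ds$peptides, ds$proteins, ds$design)
    expect_named(rep$per_class,
                 c("WTL-CTRL", "LCM-CTRL", "EXPERIMENTAL"))
    for (cl in names(rep$per_class)) {
      e <- rep$per_class[[cl]]
      expect_true(e$peptide_counts$mean > 0)
      tiers <- e$peptide_tiers
      expect_equal(tiers$low + tiers$medium + tiers$high, 1,
                   tolerance = 1e-9)
      expect_true(all(abs(e$peptide_pearson$cor) <= 1 + 1e-12))
      expect_true(all(e$peptide_cv$cv_pct >= 0))
    }
    expect_equal(rep$control_overlap$n_union,
                 rep$control_overlap$n_shared +
                   rep$control_overlap$n_only_a +
                   rep$control_overlap$n_only_b)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_qc_report(rep, path)
    tab <- read.delim(path)
    expect_true(all(c("identification", "reproducibility", "tiers",
                      "overlap") %in% tab$section))
  })
})
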