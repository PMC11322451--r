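test_that("paired_perm_ttest reproduces the classic t and exhaustive p", {
  o1 <- c(0, 0, 0, 0)
  o2 <- c(1, 2, 3, 4)
  res <- paired_perm_ttest(o1, o2, exhaustive = TRUE)
  expect_equal(res$t, unname(t.test(o2, o1, paired = TRUE)$statistic),
               tolerance = 1e-12)
  expect_equal(res$t, 3.872983, tolerance = 1e-6)
  expect_equal(res$p, 2 / 16)            # only +/- identity reach |t_obs|
  expect_equal(res$p, oracle_signflip_p(o2 - o1))
  # all-zero differences
  z <- paired_perm_ttest(c(1, 2, 3), c(1, 2, 3), exhaustive = TRUE)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
})

test_that("exhaustive p matches the independent enumeration oracle", {
  set.seed(13)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n), 2)
    if (sum(d^2) == 0) next
    res <- paired_perm_ttest(numeric(n), d, exhaustive = TRUE)
    expect_equal(res$p, oracle_signflip_p(d), tolerance = 1e-12)
  }
})

test_that("sampled p converges to exhaustive within binomial error", {
  set.seed(77)
  for (rep in 1:5) {
    d <- rnorm(10)
    pe <- paired_perm_ttest(numeric(10), d, exhaustive = TRUE)$p
    ps <- paired_perm_ttest(numeric(10), d, n_perm = 2000, seed = rep)$p
    tol <- 4 * sqrt(pe * (1 - pe) / 2000) + 2 / 2000
    expect_lt(abs(ps - pe), tol)
  }
})

test_that("swapping o1 and o2 negates t and preserves the two-sided p", {
  set.seed(5)
  o1 <- rnorm(8); o2 <- rnorm(8)
  a <- paired_perm_ttest(o1, o2, exhaustive = TRUE)
  b <- paired_perm_ttest(o2, o1, exhaustive = TRUE)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # sampled: seeded reproducibility
  s1 <- paired_perm_ttest(o1, o2, n_perm = 500, seed = 4)
  s2 <- paired_perm_ttest(o1, o2, n_perm = 500, seed = 4)
  expect_identical(s1, s2)
})

test_that("degenerate zero-variance differences use the all-flip convention", {
  expect_warning(res <- paired_perm_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1),
                                          exhaustive = TRUE),
                 "zero-variance")
  expect_true(is.infinite(res$t) && res$t > 0)
  expect_equal(res$p, 2 / 16)  # all-plus and all-minus patterns tie
})

test_that("bh_fdr implements the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- bh_fdr(p)
  expect_true(all(q <= 0.05))            # all four rejected at q <= 0.05
  expect_equal(q, oracle_bh(p))
  expect_equal(bh_fdr(0.37), 0.37)       # single p: q = p
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (rep in 1:10) {
    pr <- runif(sample(2:40, 1))
    qr <- bh_fdr(pr)
    expect_equal(qr, oracle_bh(pr), tolerance = 1e-12)
    expect_true(all(qr >= pr - 1e-12))
    o <- order(pr)
    expect_true(all(diff(qr[o]) >= -1e-12))  # monotone in ranked p
  }
})

mk_cohort_mats <- function(n_subj, nm, edit = NULL) {
  # identical t0/t1/t2 lognormal matrices per subject, optionally edited
  lapply(seq_len(n_subj), function(s) {
    set.seed(100 + s)
    P <- length(nm)
    m <- named_matrix(0, nm)
    ut <- upper.tri(m)
    m[ut] <- exp(rnorm(sum(ut), 0, 0.5))
    m <- m + t(m)
    mats <- list(t0 = m, t1 = m, t2 = m)
    if (!is.null(edit)) mats <- edit(mats, s)
    mats
  })
}

test_that("edgewise_compare respects support and recovers a planted edge", {
  nm <- sprintf("N%d", 1:6)
  mats <- mk_cohort_mats(10, nm, edit = function(mats, s) {
    mats$t1["N1", "N2"] <- mats$t1["N2", "N1"] <- 2 * mats$t0["N1", "N2"]
    mats$t2 <- mats$t1
    mats
  })
  sup <- named_matrix(TRUE, nm); diag(sup) <- FALSE
  sup["N3", "N4"] <- sup["N4", "N3"] <- FALSE
  res <- edgewise_compare(mats, "early", sup, exhaustive = TRUE)
  expect_equal(nrow(res), 14)                      # 15 pairs - masked edge
  expect_false(any(res$i == 3 & res$j == 4))
  hit <- res[res$i == 1 & res$j == 2, ]
  expect_equal(hit$p, 2 / 1024)                    # minimum attainable p
  expect_equal(hit$direction, "increase")
  expect_equal(hit$p, min(res$p))
  # all other edges are exactly null here (d = 0)
  expect_true(all(res$p[!(res$i == 1 & res$j == 2)] == 1))
  # late interval is fully null
  late <- edgewise_compare(mats, "late", sup, exhaustive = TRUE)
  expect_true(all(late$p == 1))
})

test_that("interval_abs_diff evaluates the printed-difference magnitudes", {
  nm <- sprintf("N%d", 1:4)
  # uniform path 1 -> 3 -> 2 on one edge for every subject, others constant
  mats <- lapply(1:10, function(s) {
    base <- named_matrix(0, nm)
    base[upper.tri(base)] <- 1 + s / 10
    base <- base + t(base)
    t1 <- base; t2 <- base
    t1["N1", "N2"] <- t1["N2", "N1"] <- base["N1", "N2"] + 2  # 1 -> 3
    t2["N1", "N2"] <- t2["N2", "N1"] <- base["N1", "N2"] + 1  # 3 -> 2
    list(t0 = base, t1 = t1, t2 = t2)
  })
  sup <- named_matrix(TRUE, nm); diag(sup) <- FALSE
  res <- suppressWarnings(interval_abs_diff(mats, sup, exhaustive = TRUE))
  tgt <- res[res$i == 1 & res$j == 2, ]
  expect_equal(tgt$mean_abs_early, 2)
  expect_equal(tgt$mean_abs_late, 1)
  expect_equal(tgt$greater_interval, "early")
  expect_equal(tgt$p, 2 / 1024)  # constant nonzero d: all-flip convention
  # identical timepoints everywhere else: |diff| = 0, p = 1
  rest <- res[!(res$i == 1 & res$j == 2), ]
  expect_true(all(rest$mean_abs_early == 0))
  expect_true(all(rest$p == 1))
})

test_that("classify_edge follows the hemisphere decision rule", {
  p <- toy_parcellation(n_side = 2, n_mid = 1)
  expect_equal(classify_edge("R001", "R002", p), "ipsilateral")
  expect_equal(classify_edge("L001", "L002", p), "contralateral")
  expect_equal(classify_edge("L001", "R002", p), "commissural")
  expect_equal(classify_edge("R001", "M001", p), "unclassified")
  expect_equal(classify_edge(c(1, 3), c(2, 4), p),
               c("contralateral", "ipsilateral"))
})

test_that("lateralization chi-squares match hand-computed values", {
  # perfectly independent table
  d0 <- rep(c("increase", "decrease"), times = c(20, 20))
  c0 <- rep(c("ipsilateral", "contralateral"), each = 10, times = 2)
  r0 <- lateralization_tests(d0, c0)
  expect_equal(r0$chi2_independence, 0)
  # constructed counts: contralateral 49 inc / 51 dec, ipsi 38 inc / 62 dec
  dirs <- c(rep("increase", 49), rep("decrease", 51),
            rep("increase", 38), rep("decrease", 62))
  cls <- c(rep("contralateral", 100), rep("ipsilateral", 100))
  r <- lateralization_tests(dirs, cls)
  hand <- 200 * (49 * 62 - 51 * 38)^2 / (100 * 100 * 87 * 113)
  expect_equal(r$chi2_independence, hand, tolerance = 1e-9)
  expect_equal(r$chi2_independence, 2.461612, tolerance = 1e-5)
  # goodness of fit: 56 vs 44 increases against 50/50
  d2 <- rep("increase", 100)
  c2 <- rep(c("contralateral", "ipsilateral"), times = c(56, 44))
  # add one decrease per class so the 2x2 stays well-defined
  d2 <- c(d2, "decrease", "decrease")
  c2 <- c(c2, "contralateral", "ipsilateral")
  r2 <- lateralization_tests(d2, c2)
  expect_equal(r2$chi2_gof, (56 - 50)^2 / 50 + (44 - 50)^2 / 50,
               tolerance = 1e-9)
  expect_equal(r2$chi2_gof, 1.44, tolerance = 1e-9)
  expect_equal(r2$prop_increase_contra, 0.56)
  # empty class is an error
  expect_error(lateralization_tests(rep("increase", 4),
                                    rep("ipsilateral", 4)), "undefined")
})

test_that("nodewise and global comparisons calibrate on identical timepoints", {
  cfg <- synthetic_config(n_subjects = 5, regions_per_hemisphere = 4,
                          n_insular_subregions = 2, noise_log_sd = 0,
                          effect_decrease_ipsi = 1, effect_increase_contra = 1,
                          effect_increase_periresection = 1,
                          volume_shape = c(12, 12, 12), seed = 21)
  gen <- generate_cohort(cfg)
  mats <- canonical_matrices(gen$cohort)
  nw <- nodewise_compare(mats, gen$cohort$parcellation, "nodal_strength",
                         "whole_brain", "early", exhaustive = TRUE)
  expect_true(all(nw$p == 1))                  # identical timepoints
  expect_equal(nrow(nw), 9)
  gl <- global_compare(mats, gen$cohort$parcellation, "ipsilateral", "early",
                       exhaustive = TRUE, small_world = FALSE)
  expect_true(all(gl$p[!is.na(gl$p)] == 1))
  # empty scope yields an empty result
  p0 <- toy_parcellation(2, 0)
  m0 <- named_matrix(1, p0$labels$name); diag(m0) <- 0
  mats0 <- lapply(1:3, function(s) list(t0 = m0, t1 = m0, t2 = m0))
  empty <- nodewise_compare(mats0, p0, "nodal_strength",
                            "contralateral_insular", "early",
                            exhaustive = TRUE)
  expect_equal(nrow(empty), 0)
})
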