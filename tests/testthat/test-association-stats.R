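test_that("Fisher exact p matches printed-style examples and the oracle", {
  # 0/9 vs 5/13 responders: p = 0.14 at two decimals
  expect_equal(round(fisher_exact_2x2(0, 9, 5, 13)$p, 2), 0.14)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p, 1)
  expect_equal(fisher_exact_2x2(0, 9, 5, 13)$p, fisher_oracle(0, 9, 5, 13))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 3, 4)$p, "empty margin")
  expect_equal(p0, 1)
})

test_that("Fisher p equals enumeration and the mainstream implementation on small tables", {
  # all tables with margins <= 12
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    if (a + b + cc + d == 0) next
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    p <- fisher_exact_2x2(a, b, cc, d, odds_ratio = FALSE)$p
    expect_equal(p, fisher_oracle(a, b, cc, d), tolerance = 1e-12)
    expect_equal(p, fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(8)
  for (i in 1:20) {
    t <- rpois(4, 6)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
        t[1] + t[3] == 0 || t[2] + t[4] == 0) next
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4])$p,
                 fisher_exact_2x2(t[4], t[3], t[2], t[1])$p,
                 tolerance = 1e-12)
  }
})

test_that("conditional-MLE odds ratio handles empty cells", {
  expect_equal(fisher_exact_2x2(0, 10, 5, 5)$odds_ratio, 0)
  expect_gt(fisher_exact_2x2(8, 2, 2, 8)$odds_ratio, 1)
})

test_that("response rates implement the CRc and CR definitions", {
  p <- make_patients(c("CR", "CRi", "none", "none"))
  expect_equal(response_rates(p, "CRc")$percent, 50)
  expect_equal(response_rates(p, "CR")$percent, 25)
  expect_equal(response_rates(make_patients(rep("none", 5)), "CRc")$percent,
               0)
  expect_error(response_rates(make_patients(c("CR", "PR")), "CRc"),
               "unknown response")
  grp <- make_patients(c("CR", "none", "CRp", "none"),
                       cluster = c("R", "R", "S", "S"))
  rr <- response_rates(grp, "CRc", group = "cluster")
  expect_equal(rr$n_response, c(1L, 1L))
  expect_equal(rr$n_total, c(2L, 2L))
})

test_that("exhaustive permutation p matches the enumeration oracle", {
  x <- c(1, 1, 0, 0)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  mm <- matrix(x, nrow = 1, dimnames = list("S1", NULL))
  res <- permutation_dmc(mm, labels)
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_perm, 6)
  expect_equal(res$p, 1 / 3)                     # 2 of C(4,2)=6 arrangements
  expect_equal(res$p, perm_oracle_p(x, labels))
  # constant site -> p = 1
  const <- matrix(0.4, 1, 6)
  expect_equal(permutation_dmc(const, rep(c(TRUE, FALSE), 3))$p, 1)
  # random small matrices vs oracle
  set.seed(12)
  X <- matrix(runif(40), 5, 8)
  lab <- rep(c(TRUE, FALSE), each = 4)
  res2 <- permutation_dmc(X, lab)
  for (i in 1:5) expect_equal(res2$p[i], perm_oracle_p(X[i, ], lab))
})

test_that("Monte-Carlo permutation p uses the add-one estimator and a seed", {
  set.seed(20)
  X <- matrix(runif(15 * 20), 15, 20)
  lab <- rep(c(TRUE, FALSE), 10)
  a <- permutation_dmc(X, lab, B = 200, seed = 5, exhaustive_max = 10)
  b <- permutation_dmc(X, lab, B = 200, seed = 5, exhaustive_max = 10)
  expect_identical(a, b)
  expect_equal(a$mode[1], "monte-carlo")
  expect_true(all(a$p >= 1 / 201) && all(a$p <= 1))
  expect_error(permutation_dmc(X, rep(TRUE, 20)), "per label")
})

test_that("discovery/validation intersection is symmetric", {
  pd <- tibble::tibble(site_id = sprintf("S%02d", 1:6),
                       p = c(0.01, 0.2, 0.03, 0.5, 0.04, 0.9))
  pv <- tibble::tibble(site_id = sprintf("S%02d", 1:6),
                       p = c(0.04, 0.01, 0.8, 0.01, 0.02, 0.7))
  expect_setequal(discovery_validation(pd, pv), c("S01", "S05"))
  expect_setequal(discovery_validation(pv, pd),
                  discovery_validation(pd, pv))
  # disjoint significant sets -> empty
  pv2 <- dplyr::mutate(pv, p = rev(pd$p))
  expect_length(discovery_validation(pd[c(1, 3, 5), ] |>
                                       dplyr::mutate(p = 0.01),
                                     pv2[c(1, 3, 5), ] |>
                                       dplyr::mutate(p = 0.5)), 0)
  # identical all-significant lists -> all sites
  all_sig <- dplyr::mutate(pd, p = 0.01)
  expect_length(discovery_validation(all_sig, all_sig), 6)
  expect_error(discovery_validation(pd, pv[1:3, ]), "same site universe")
})

test_that("planted discovery/validation signal survives the intersection", {
  set.seed(33)
  n_sites <- 300
  planted <- 1:10
  sim_cohort_p <- function() {
    X <- matrix(runif(n_sites * 30, 0.3, 0.7), n_sites, 30)
    lab <- rep(c(TRUE, FALSE), 15)
    X[planted, lab] <- X[planted, lab] + 0.4
    permutation_dmc(X, lab, B = 300, seed = sample.int(1e6, 1))[, c("site_id", "p")]
  }
  inter <- discovery_validation(sim_cohort_p(), sim_cohort_p())
  planted_ids <- sprintf("%d", planted)
  expect_gte(sum(planted_ids %in% inter), 8)
  expect_lte(length(setdiff(inter, planted_ids)), 5)
})

test_that("feature enrichment reports odds ratios with infinity at degeneracy", {
  sites <- tibble::tibble(site_id = sprintf("S%02d", 1:20),
                          is_cgi = rep(c(TRUE, FALSE), each = 10))
  # all hits CGI, no background CGI hit impossible here; force degeneracy:
  sites2 <- tibble::tibble(site_id = sprintf("S%02d", 1:20),
                           is_cgi = c(rep(TRUE, 5), rep(FALSE, 15)))
  fe <- feature_enrichment(sprintf("S%02d", 1:5), sites2)
  expect_equal(fe$odds_ratio, Inf)
  expect_lt(fe$p, 0.01)
  # planted 2x enrichment detected at scale
  set.seed(14)
  big <- tibble::tibble(site_id = sprintf("S%04d", 1:500),
                        is_cgi = runif(500) < 0.3)
  w <- ifelse(big$is_cgi, 2, 1)
  hits <- sample(big$site_id, 120, prob = w)
  fe2 <- feature_enrichment(hits, big)
  expect_gt(fe2$odds_ratio, 1)
  expect_error(feature_enrichment("SX", big), "subset")
})

test_that("uniform hits show no enrichment in most seeds", {
  set.seed(26)
  flags <- 0L
  for (i in 1:20) {
    sites <- tibble::tibble(site_id = sprintf("S%04d", 1:400),
                            is_cgi = runif(400) < 0.3,
                            is_ctcf = runif(400) < 0.15)
    fe <- feature_enrichment(sample(sites$site_id, 80), sites)
    if (any(fe$p < 0.05 / nrow(fe))) flags <- flags + 1L
  }
  expect_lte(flags / 20, 0.10)
})

test_that("maximum LINE-1 demethylation is baseline minus minimum, floored", {
  l1 <- tibble::tibble(patient_id = rep("P001", 4), day = c(0, 8, 15, 22),
                       line1_pct = c(70, 60, 50, 65))
  expect_equal(max_line1_demethylation(l1)$max_demethylation, 20)
  up <- dplyr::mutate(l1, line1_pct = c(70, 72, 75, 71))
  expect_equal(max_line1_demethylation(up)$max_demethylation, 0)
  base_only <- l1[1, ]
  res <- max_line1_demethylation(base_only)
  expect_true(is.na(res$max_demethylation))
  expect_true(res$flag_missing)
  expect_error(max_line1_demethylation(dplyr::mutate(l1, line1_pct = 120)),
               "\\[0, 100\\]")
})

test_that("LINE-1 demethylation differs between simulated R and S classes", {
  co <- simulate_cohort(cohort_sim_config(n_sites = 2, depth_mean = 5,
                                          seed = 7))
  l1 <- max_line1_demethylation(co$line1)
  cls <- co$truth$classes$latent_class[match(l1$patient_id,
                                             co$truth$classes$patient_id)]
  cmp <- compare_groups(l1$max_demethylation, cls, "wilcoxon")
  expect_lt(cmp$p, 0.05)
  expect_lt(mean(l1$max_demethylation[cls == "resistant"]),
            mean(l1$max_demethylation[cls == "sensitive"]))
})

test_that("group comparison wrappers run t, Mann-Whitney and ANOVA", {
  set.seed(4)
  v <- c(rnorm(20), rnorm(20, 2), rnorm(20, 4))
  g3 <- rep(c("a", "b", "c"), each = 20)
  expect_lt(compare_groups(v, g3, "anova")$p, 1e-6)
  expect_lt(compare_groups(v[1:40], g3[1:40], "t")$p, 1e-4)
  expect_lt(compare_groups(v[1:40], g3[1:40], "wilcoxon")$p, 1e-4)
  expect_error(compare_groups(v, rep("a", 60)), "2 groups")
})
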