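test_that("read signatures are classified by restriction-product prefix", {
  expect_equal(classify_read_signature(c("CCGGGATTA", "GGGTTCA", "ATCGA")),
               c("methylated", "unmethylated", "unknown"))
  # CCGGG wins over the bare GGG rule; N is tolerated in the alphabet
  expect_equal(classify_read_signature("CCGGGGGG"), "methylated")
  expect_equal(classify_read_signature("GGGNNT"), "unmethylated")
  expect_error(classify_read_signature("ACGU"), "ACGTN")
  expect_error(classify_read_signature(""), "non-empty")
})

test_that("site methylation is the methylated-read fraction with missing at zero depth", {
  expect_equal(site_methylation(5, 15), 0.25)
  expect_equal(site_methylation(0, 20), 0)
  expect_equal(site_methylation(7, 0), 1)
  expect_true(is.na(site_methylation(0, 0)))
  expect_error(site_methylation(-1, 5), "non-negative")
})

test_that("coverage filter applies the reads/sample-fraction rule at the boundary", {
  vals <- rbind(rep(0.5, 4), rep(0.5, 4), rep(0.5, 4))
  cov <- rbind(c(25, 25, 25, 10),   # 3/4 = 0.75 >= 0.75 -> kept, one missing
               c(25, 25, 10, 10),   # 2/4 -> dropped
               c(25, 25, 25, 25))
  mm <- make_mm(vals, cov)
  f <- coverage_filter(mm, min_reads = 20, min_sample_frac = 0.75)
  expect_equal(f$values$site_id, c("S00001", "S00003"))
  expect_true(is.na(f$values[[5]][1]))  # low-coverage entry masked
  expect_equal(sum(is.na(epiresist:::value_matrix(f$values))), 1)

  ident <- coverage_filter(mm, min_reads = 0)
  expect_equal(ident$values, mm$values)

  expect_error(coverage_filter(mm, min_sample_frac = 0), "min_sample_frac")
  expect_error(coverage_filter(mm, min_sample_frac = 1.5), "min_sample_frac")
})

test_that("tightening the coverage threshold never retains more sites", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- matrix(runif(200), 20, 10)
    cov <- matrix(rpois(200, 22), 20, 10)
    mm <- make_mm(vals, cov)
    kept <- vapply(c(0, 10, 20, 30, 40), function(mr) {
      nrow(coverage_filter(mm, min_reads = mr)$values)
    }, numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("PMM imputation draws donors from the site's observed values", {
  vals <- matrix(runif(100, 0.2, 0.8), 10, 10)
  vals[cbind(1:5, 1:5)] <- NA
  mm <- make_mm(vals)
  imp <- impute_pmm(mm, n_donors = 3, seed = 4)
  im <- epiresist:::value_matrix(imp$values)
  expect_false(any(is.na(im)))
  for (i in 1:5) {
    expect_true(im[i, i] %in% vals[i, -i])       # donor membership
    expect_equal(im[i, -i], vals[i, -i],         # observed untouched
                 ignore_attr = TRUE)
  }
  # no missing -> unchanged
  full <- make_mm(matrix(runif(20), 4, 5))
  expect_identical(impute_pmm(full), full)
  # constant observed values force the imputed value
  const <- matrix(0.4, 3, 6)
  const[1, 2] <- NA
  expect_equal(epiresist:::value_matrix(impute_pmm(make_mm(const),
                                                   seed = 1)$values)[1, 2],
               0.4, ignore_attr = TRUE)
})

test_that("PMM with one donor picks the closest predicted mean", {
  set.seed(7)
  vals <- matrix(runif(60, 0.1, 0.9), 6, 10)
  vals[2, 4] <- NA
  mm <- make_mm(vals)
  imp <- impute_pmm(mm, n_donors = 1, seed = 2)
  # independent reconstruction of the per-site linear predictions
  x <- colMeans(vals, na.rm = TRUE)
  y <- vals[2, ]
  obs <- !is.na(y)
  fit <- lm(y[obs] ~ x[obs])
  pred <- coef(fit)[1] + coef(fit)[2] * x
  nearest <- which.min(abs(pred[obs] - pred[4]))
  expect_equal(epiresist:::value_matrix(imp$values)[2, 4],
               y[obs][nearest], ignore_attr = TRUE)
})

test_that("PMM rejects unimputable sites by name", {
  vals <- matrix(runif(20), 2, 10)
  vals[1, ] <- NA
  expect_error(impute_pmm(make_mm(vals)), "S00001")
  vals2 <- matrix(runif(20), 2, 10)
  vals2[2, 3:10] <- NA
  expect_error(impute_pmm(make_mm(vals2), n_donors = 5), "S00002")
})

test_that("hypervariable site selection uses the strict n-1 SD rule", {
  vals <- rbind(rep(0.3, 6),                     # SD 0 -> out
                rep(c(0, 1), 3),                 # SD ~0.55 -> in
                c(0.5, 0.5, 0.6, 0.6, 0.5, 0.6)) # SD ~0.055 -> out
  hv <- hypervariable_sites(make_mm(vals), 0.10)
  expect_equal(hv$site_id, "S00002")
  expect_equal(hv$sd, sd(rep(c(0, 1), 3)))
  # brute-force agreement on a random matrix
  set.seed(3)
  m <- matrix(runif(200), 20, 10)
  hv2 <- hypervariable_sites(make_mm(m), 0.25)
  manual <- which(apply(m, 1, sd) > 0.25)
  expect_equal(hv2$site_id, sprintf("S%05d", manual))
})

test_that("methylation clustering recovers planted blocks and labels them", {
  set.seed(42)
  n_sites <- 40
  mk_block <- function(mean_cgi, n) {
    vapply(seq_len(n), function(i) {
      pmin(pmax(c(rnorm(n_sites / 2, mean_cgi, 0.05),
                  rnorm(n_sites / 2, 0.5, 0.05)), 0), 1)
    }, numeric(n_sites))
  }
  recovered <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    vals <- cbind(mk_block(0.1, 10), mk_block(0.4, 10), mk_block(0.8, 10),
                  mk_block(0.1, 3))  # 3 normals identical to the low block
    colnames(vals) <- c(sprintf("P%03d", 1:30), sprintf("N%02d", 1:3))
    mm <- make_mm(vals, is_cgi = rep(c(TRUE, FALSE), each = n_sites / 2))
    cl <- cluster_methylation(mm, k = 3,
                              normal_sample_ids = sprintf("N%02d", 1:3))
    want <- rep(c("normal-like", "intermediate", "CIMP-like", "normal-like"),
                c(10, 10, 10, 3))
    if (all(cl$assignment$label == want)) recovered <- recovered + 1L
  }
  expect_gte(recovered / n_seeds, 0.95)
})

test_that("clustering is invariant to sample order and constant shifts", {
  set.seed(9)
  vals <- cbind(matrix(rnorm(60, 0.2, 0.03), 20, 3),
                matrix(rnorm(60, 0.7, 0.03), 20, 3))
  colnames(vals) <- sprintf("P%03d", 1:6)
  vals <- pmin(pmax(vals, 0), 1)
  mm <- make_mm(vals)
  cl <- cluster_methylation(mm, k = 2)
  perm <- sample(6)
  cl_p <- cluster_methylation(make_mm(vals[, perm]), k = 2)
  m1 <- cl$assignment$label[match(sprintf("P%03d", 1:6),
                                  cl$assignment$sample_id)]
  m2 <- cl_p$assignment$label[match(sprintf("P%03d", 1:6),
                                    cl_p$assignment$sample_id)]
  expect_equal(m1, m2)
  shifted <- pmin(pmax(vals + 0.05, 0), 1)
  cl_s <- cluster_methylation(make_mm(shifted), k = 2)
  expect_equal(cl_s$assignment$cluster, cl$assignment$cluster)
})

test_that("normals split across clusters falls back to methylation ordering", {
  set.seed(13)
  vals <- cbind(matrix(rnorm(40, 0.15, 0.02), 10, 4),
                matrix(rnorm(40, 0.8, 0.02), 10, 4))
  vals <- pmin(pmax(vals, 0), 1)
  colnames(vals) <- c(sprintf("P%03d", 1:6), "N01", "N02")
  # N01 sits in the low block, N02 in the high one: no majority for k = 2
  vals[, "N01"] <- pmin(pmax(rnorm(10, 0.15, 0.02), 0), 1)
  mm <- make_mm(vals)
  expect_warning(
    cl <- cluster_methylation(mm, k = 2,
                              normal_sample_ids = c("N01", "N02")),
    "no majority")
  expect_true(cl$fallback)
  expect_setequal(cl$labels, c("normal-like", "CIMP-like"))
})

test_that("estimated methylation converges to truth with depth", {
  set.seed(2)
  for (true_m in c(0.1, 0.5, 0.9)) {
    r <- simulate_signature_reads(true_m, 2e5)
    est <- site_methylation(r$meth_reads, r$unmeth_reads)
    expect_lt(abs(est - true_m), 0.01)
  }
})
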