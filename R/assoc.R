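#  Exact 2x2 association tests, permutation differential methylation,
#  discovery/validation intersection, feature enrichment, and LINE-1
#  demethylation summaries.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The table is `rbind(c(a, b), c(c, d))` with rows = group and columns =
#' outcome. The two-sided p-value is the minimum-likelihood convention: the
#' sum of hypergeometric point probabilities (margins fixed) not exceeding
#' the observed table's probability, with a `1 + 1e-7` relative guard for
#' floating-point ties — the convention of mainstream implementations.
#' The odds ratio is the conditional maximum-likelihood estimate (0 and
#' `Inf` allowed for empty cells).
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param odds_ratio Compute the conditional-MLE odds ratio (skippable for
#'   bulk sweeps).
#' @return Tibble with `p`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, odds_ratio = TRUE) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort("cells must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("table total must be positive.")
  m1 <- a + b
  k1 <- a + c
  N <- sum(cells)
  if (m1 == 0 || m1 == N || k1 == 0 || k1 == N) {
    warn("empty margin: p = 1 by convention.")
    p <- 1
  } else {
    support <- max(0, k1 - (N - m1)):min(k1, m1)
    probs <- dhyper(support, m1, N - m1, k1)
    p_obs <- dhyper(a, m1, N - m1, k1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (odds_ratio) {
    unname(fisher.test(matrix(cells, 2, byrow = TRUE))$estimate)
  } else NA_real_
  tibble::tibble(p = p, odds_ratio = or)
}

#' Response rate table
#'
#' Composite complete response (CRc) counts CR + CRp + CRi; CR counts CR
#' only.
#'
#' @param patients Tibble with a `response` column in
#'   `c("CR", "CRp", "CRi", "none")`.
#' @param scope `"CRc"` or `"CR"`.
#' @param group Optional grouping column name; default one overall row.
#' @return Tibble with `n_response`, `n_total`, `percent` per group.
#' @export
response_rates <- function(patients, scope = c("CRc", "CR"), group = NULL) {
  scope <- match.arg(scope)
  valid <- c("CR", "CRp", "CRi", "none")
  if (any(is.na(patients$response)) || !all(patients$response %in% valid)) {
    abort(paste("unknown response category;",
                "expected CR, CRp, CRi or none."))
  }
  hit <- if (scope == "CRc") patients$response %in% c("CR", "CRp", "CRi")
  else patients$response == "CR"
  df <- tibble::tibble(.hit = hit)
  if (!is.null(group)) df[[group]] <- patients[[group]]
  df |>
    dplyr::group_by(dplyr::across(dplyr::any_of(group))) |>
    dplyr::summarise(
      scope = scope,
      n_response = sum(.data$.hit),
      n_total = dplyr::n(),
      percent = 100 * sum(.data$.hit) / dplyr::n(),
      .groups = "drop"
    )
}

#' Permutation test for differential methylation
#'
#' Per-site statistic: absolute difference in mean methylation between
#' responders and non-responders. Labels are permuted jointly across all
#' sites. When the number of distinct label arrangements `choose(n, n1)` is
#' at most `exhaustive_max`, all arrangements are enumerated and the
#' empirical p is the exact fraction of arrangements (including the observed
#' one) attaining the observed statistic or more; otherwise `B` random
#' permutations are drawn and the add-one estimator
#' `p = (1 + #{permuted >= observed}) / (1 + B)` is used, so p is never 0.
#'
#' @param mm A complete `meth_matrix`, or a numeric sites-by-samples matrix.
#' @param labels Logical (or 0/1) responder labels, one per sample, in the
#'   sample order of `mm`.
#' @param B Number of random permutations.
#' @param seed Integer seed for the random mode.
#' @param exhaustive_max Enumeration cutoff on `choose(n, n1)`.
#' @return Tibble per site: `site_id`, `observed` (statistic), `p`,
#'   `p_bh` (Benjamini-Hochberg), `n_perm`, `mode`.
#' @export
permutation_dmc <- function(mm, labels, B = 1000, seed = 1L,
                            exhaustive_max = 10000) {
  X <- if (inherits(mm, "meth_matrix")) value_matrix(mm$values) else
    as.matrix(mm)
  if (any(is.na(X))) abort("matrix has missing values; impute first.")
  labels <- as.logical(labels)
  n <- ncol(X)
  if (length(labels) != n) abort("`labels` length must match sample count.")
  n1 <- sum(labels)
  if (n1 < 2 || n - n1 < 2) {
    abort("need at least 2 samples per label class.")
  }
  contrast <- function(idx1) {
    v <- rep(-1 / (n - n1), n)
    v[idx1] <- 1 / n1
    v
  }
  observed <- abs(as.vector(X %*% contrast(which(labels))))

  n_arr <- choose(n, n1)
  if (n_arr <= exhaustive_max) {
    combos <- combn(n, n1)
    P <- apply(combos, 2, contrast)
    stats <- abs(X %*% P)
    p <- rowMeans(stats >= observed - 1e-12)
    n_perm <- ncol(combos)
    mode <- "exhaustive"
  } else {
    P <- with_seed(seed, {
      vapply(seq_len(B), function(b) contrast(sample.int(n, n1)),
             numeric(n))
    })
    stats <- abs(X %*% P)
    p <- (1 + rowSums(stats >= observed - 1e-12)) / (1 + B)
    n_perm <- B
    mode <- "monte-carlo"
  }
  tibble::tibble(
    site_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    observed = unname(observed),
    p = unname(p),
    p_bh = unname(p.adjust(p, method = "BH")),
    n_perm = n_perm,
    mode = mode
  )
}

#' Discovery/validation intersection of significant sites
#'
#' @param p_discovery,p_validation Tibbles with `site_id` and `p` over the
#'   same site universe.
#' @param alpha Significance level applied to both cohorts.
#' @return Character vector of site ids with `p < alpha` in both.
#' @export
discovery_validation <- function(p_discovery, p_validation, alpha = 0.05) {
  if (!setequal(p_discovery$site_id, p_validation$site_id)) {
    abort("discovery and validation must cover the same site universe.")
  }
  intersect(p_discovery$site_id[p_discovery$p < alpha],
            p_validation$site_id[p_validation$p < alpha])
}

#' Genomic-feature enrichment of hit sites
#'
#' Per annotation flag, an exact test of the 2x2 table hit/non-hit by
#' flagged/unflagged over the site universe.
#'
#' @param hits Character vector of hit site ids (subset of the universe).
#' @param sites Site annotation tibble (`site_id` plus logical flag
#'   columns).
#' @param features Flag columns to test (defaults to the `is_*` columns
#'   present). Features absent from the universe are skipped.
#' @return Tibble per feature: counts, `odds_ratio`, `p`.
#' @export
feature_enrichment <- function(hits, sites,
                               features = intersect(
                                 c("is_cgi", "is_ctcf", "is_enhancer",
                                   "is_promoter"), names(sites))) {
  if (!all(hits %in% sites$site_id)) {
    abort("`hits` must be a subset of the site universe.")
  }
  is_hit <- sites$site_id %in% hits
  purrr::map_dfr(features, function(f) {
    flag <- sites[[f]]
    if (is.null(flag) || !any(flag)) return(tibble::tibble())
    ft <- fisher_exact_2x2(sum(is_hit & flag), sum(is_hit & !flag),
                           sum(!is_hit & flag), sum(!is_hit & !flag))
    tibble::tibble(
      feature = f,
      hit_flagged = sum(is_hit & flag),
      hit_total = sum(is_hit),
      bg_flagged = sum(!is_hit & flag),
      bg_total = sum(!is_hit),
      odds_ratio = ft$odds_ratio,
      p = ft$p
    )
  })
}

#' Maximum LINE-1 demethylation during cycle 1
#'
#' `baseline - min(on-treatment values)`, floored at 0 percentage points.
#'
#' @param line1 Tibble `patient_id`, `day`, `line1_pct` (day 0 = baseline).
#' @return Tibble per patient: `baseline`, `max_demethylation`,
#'   `flag_missing` (no on-treatment values).
#' @export
max_line1_demethylation <- function(line1) {
  if (any(line1$line1_pct < 0 | line1$line1_pct > 100, na.rm = TRUE)) {
    abort("LINE-1 values must be percentages in [0, 100].")
  }
  line1 |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      baseline = .data$line1_pct[.data$day == 0][1],
      max_demethylation = ifelse(
        any(.data$day > 0),
        pmax(.data$line1_pct[.data$day == 0][1] -
               min(.data$line1_pct[.data$day > 0]), 0),
        NA_real_
      ),
      flag_missing = !any(.data$day > 0) |
        is.na(.data$line1_pct[.data$day == 0][1]),
      .groups = "drop"
    )
}

#' Two-group descriptor comparison
#'
#' Contract-level wrappers with standard definitions: Mann-Whitney
#' (mid-rank ties), Welch t, or one-way ANOVA for 3+ groups.
#'
#' @param values Numeric vector.
#' @param group Group labels (2 or more levels).
#' @param test `"wilcoxon"`, `"t"`, or `"anova"`.
#' @return Tibble with `test`, `statistic`, `p`.
#' @export
compare_groups <- function(values, group,
                           test = c("wilcoxon", "t", "anova")) {
  test <- match.arg(test)
  group <- factor(group)
  if (nlevels(group) < 2) abort("need at least 2 groups.")
  res <- switch(
    test,
    wilcoxon = {
      w <- wilcox.test(values ~ group, exact = FALSE)
      c(w$statistic, w$p.value)
    },
    t = {
      tt <- t.test(values ~ group)
      c(tt$statistic, tt$p.value)
    },
    anova = {
      av <- stats::anova(stats::aov(values ~ group))
      c(av$`F value`[1], av$`Pr(>F)`[1])
    }
  )
  tibble::tibble(test = test, statistic = unname(res[1]), p = unname(res[2]))
}

#' Read a LINE-1 series CSV
#'
#' @param path CSV with `patient_id`, `day`, `line1_pct`.
#' @return Tibble.
#' @export
read_line1 <- function(path) readr::read_csv(path, show_col_types = FALSE)
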