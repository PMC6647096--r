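#  DREAM methylation processing.
#
#  DREAM (Digital Restriction Enzyme Analysis of Methylation) digests genomic
#  DNA sequentially with two neoschizomers cutting CCCGGG: SmaI cuts only
#  unmethylated sites and leaves blunt ends, XmaI is methylation-insensitive
#  and leaves a 5' CCGG overhang. Reads starting CCGGG therefore carry the
#  methylated signature; reads starting GGG carry the unmethylated one. The
#  per-site methylation level is the fraction of signature reads that are
#  methylated. This module turns signature counts into a filtered, imputed
#  methylation matrix, selects hypervariable sites, and clusters samples into
#  normal-like / intermediate / CIMP-like groups.

#' Classify a read by its DREAM restriction signature
#'
#' @param read_prefix Character vector of read 5' prefixes (uppercase DNA,
#'   `ACGTN` alphabet).
#' @return Character vector in `c("methylated", "unmethylated", "unknown")`:
#'   `CCGGG...` is the XmaI (methylated) product, `GGG...` (not `CCGGG`) the
#'   SmaI blunt (unmethylated) product.
#' @export
classify_read_signature <- function(read_prefix) {
  if (!is.character(read_prefix) || any(is.na(read_prefix)) ||
      any(!nzchar(read_prefix))) {
    abort("`read_prefix` must be non-empty strings.")
  }
  if (any(grepl("[^ACGTN]", read_prefix))) {
    abort("`read_prefix` contains non-ACGTN characters.")
  }
  dplyr::case_when(
    startsWith(read_prefix, "CCGGG") ~ "methylated",
    startsWith(read_prefix, "GGG") ~ "unmethylated",
    TRUE ~ "unknown"
  )
}

#' Per-site methylation fraction from signature counts
#'
#' @param meth_reads,unmeth_reads Non-negative integer vectors.
#' @return Methylated fraction `meth / (meth + unmeth)` in `[0, 1]`; `NA`
#'   where the total is zero (a missing value, not an error).
#' @export
site_methylation <- function(meth_reads, unmeth_reads) {
  if (any(meth_reads < 0, na.rm = TRUE) || any(unmeth_reads < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative.")
  }
  total <- meth_reads + unmeth_reads
  ifelse(total > 0, meth_reads / total, NA_real_)
}

#' Build a methylation matrix from long signature counts
#'
#' @param counts Long tibble with `site_id`, `sample_id`, `meth_reads`,
#'   `unmeth_reads`.
#' @param sites Site annotation tibble (`site_id`, `chrom`, `pos`, flags).
#' @return A `meth_matrix`: list with `values` (tibble, `site_id` + one
#'   fraction column per sample; `NA` = missing), `coverage` (same shape,
#'   total reads), and `sites`.
#' @export
methylation_from_counts <- function(counts, sites = NULL) {
  need <- c("site_id", "sample_id", "meth_reads", "unmeth_reads")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(need, collapse = ", ")))
  }
  long <- dplyr::mutate(
    counts,
    value = site_methylation(.data$meth_reads, .data$unmeth_reads),
    coverage = .data$meth_reads + .data$unmeth_reads
  )
  values <- tidyr::pivot_wider(long[, c("site_id", "sample_id", "value")],
                               names_from = "sample_id",
                               values_from = "value")
  coverage <- tidyr::pivot_wider(long[, c("site_id", "sample_id", "coverage")],
                                 names_from = "sample_id",
                                 values_from = "coverage")
  coverage[is.na(coverage)] <- 0L
  if (is.null(sites)) {
    sites <- tibble::tibble(site_id = values$site_id)
  }
  new_meth_matrix(values, coverage, sites)
}

new_meth_matrix <- function(values, coverage, sites) {
  structure(list(values = values, coverage = coverage, sites = sites),
            class = "meth_matrix")
}

#' Construct a methylation matrix from plain matrices
#'
#' @param values Numeric sites-by-samples matrix of methylation fractions
#'   (`NA` = missing), with row and column names.
#' @param coverage Integer matrix of the same shape (total reads); defaults
#'   to full coverage (useful for already-processed fractions).
#' @param sites Optional site annotation tibble (`site_id` plus flags);
#'   defaults to bare ids.
#' @return A `meth_matrix`.
#' @export
as_meth_matrix <- function(values, coverage = NULL, sites = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("P%03d", seq_len(ncol(values)))
  }
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    abort("methylation fractions must lie in [0, 1].")
  }
  if (is.null(coverage)) {
    coverage <- matrix(1e6L, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!all(dim(coverage) == dim(values))) {
    abort("`coverage` must match the shape of `values`.")
  }
  dimnames(coverage) <- dimnames(values)
  if (is.null(sites)) sites <- tibble::tibble(site_id = rownames(values))
  vt <- dplyr::bind_cols(tibble::tibble(site_id = rownames(values)),
                         tibble::as_tibble(values))
  ct <- dplyr::bind_cols(tibble::tibble(site_id = rownames(values)),
                         tibble::as_tibble(coverage))
  new_meth_matrix(vt, ct, sites)
}

#' @export
print.meth_matrix <- function(x, ...) {
  sc <- sample_cols(x$values)
  vm <- value_matrix(x$values)
  cat("<meth_matrix> ", nrow(x$values), " sites x ", length(sc),
      " samples; ", sum(is.na(vm)), " missing (",
      sprintf("%.1f%%", 100 * mean(is.na(vm))), ")\n", sep = "")
  invisible(x)
}

#' Coverage filter for methylation matrices
#'
#' Keeps sites covered with at least `min_reads` reads in at least
#' `min_sample_frac` of samples; entries below `min_reads` become missing.
#' Site order is preserved.
#'
#' @param mm A `meth_matrix`.
#' @param min_reads Minimum total reads for an entry to be trusted.
#' @param min_sample_frac Minimum fraction of samples meeting `min_reads`
#'   for a site to be retained (in `(0, 1]`).
#' @return A filtered `meth_matrix`.
#' @export
coverage_filter <- function(mm, min_reads = 20, min_sample_frac = 0.75) {
  stopifnot(inherits(mm, "meth_matrix"))
  if (nrow(mm$values) == 0) abort("empty methylation matrix.")
  check_count(min_reads, "min_reads")
  if (!is.numeric(min_sample_frac) || length(min_sample_frac) != 1 ||
      is.na(min_sample_frac) || min_sample_frac <= 0 || min_sample_frac > 1) {
    abort("`min_sample_frac` must lie in (0, 1].")
  }
  cov <- value_matrix(mm$coverage)
  ok <- cov >= min_reads
  keep <- rowMeans(ok) >= min_sample_frac
  values <- mm$values
  vm <- value_matrix(values)
  vm[!ok] <- NA_real_
  values[, sample_cols(values)] <- vm
  new_meth_matrix(values[keep, , drop = FALSE],
                  mm$coverage[keep, , drop = FALSE],
                  mm$sites[mm$sites$site_id %in% values$site_id[keep], ,
                           drop = FALSE])
}

#' Impute missing methylation values by predictive mean matching
#'
#' For each site, entry predictions come from a per-site linear regression of
#' observed methylation on the sample-wise mean methylation (one regressor).
#' Each missing entry receives the observed value of a donor drawn uniformly
#' among the `n_donors` observed entries of the same site whose predicted
#' means are closest to the missing entry's prediction. Observed entries are
#' never altered, and every imputed value is a member of its site's observed
#' values.
#'
#' @param mm A `meth_matrix`.
#' @param n_donors Donor pool size (default 5).
#' @param seed Integer seed making donor draws reproducible.
#' @return A complete `meth_matrix`.
#' @export
impute_pmm <- function(mm, n_donors = 5, seed = 1L) {
  stopifnot(inherits(mm, "meth_matrix"))
  check_count(n_donors, "n_donors", min = 1)
  vm <- value_matrix(mm$values)
  if (!any(is.na(vm))) return(mm)
  n_obs <- rowSums(!is.na(vm))
  if (any(n_obs == 0)) {
    abort(paste("site(s) fully missing:",
                paste(head(rownames(vm)[n_obs == 0], 5), collapse = ", ")))
  }
  if (any(n_obs < n_donors)) {
    abort(paste0("site(s) with fewer than n_donors = ", n_donors,
                 " observed values: ",
                 paste(head(rownames(vm)[n_obs < n_donors], 5),
                       collapse = ", ")))
  }
  x <- colMeans(vm, na.rm = TRUE)  # sample-wise mean methylation
  with_seed(seed, {
    for (s in which(rowSums(is.na(vm)) > 0)) {
      y <- vm[s, ]
      obs <- !is.na(y)
      pred <- if (sd(x[obs]) > 0) {
        fit <- lm(y[obs] ~ x[obs])
        coef(fit)[1] + coef(fit)[2] * x
      } else {
        rep(mean(y[obs]), length(y))
      }
      for (j in which(!obs)) {
        d <- order(abs(pred[obs] - pred[j]))[seq_len(n_donors)]
        donor <- if (n_donors == 1) d else d[sample.int(n_donors, 1)]
        vm[s, j] <- y[obs][donor]
      }
    }
  })
  values <- mm$values
  values[, sample_cols(values)] <- vm
  new_meth_matrix(values, mm$coverage, mm$sites)
}

#' Hypervariable methylation sites
#'
#' @param mm A complete (post-imputation) `meth_matrix`.
#' @param sd_threshold Sites with across-sample standard deviation (n - 1
#'   denominator) strictly greater than this are returned. 0.10 corresponds
#'   to the conventional "SD > 10%" cutoff on the 0-1 fraction scale.
#' @return Tibble with `site_id` and `sd`, one row per hypervariable site.
#' @export
hypervariable_sites <- function(mm, sd_threshold = 0.10) {
  stopifnot(inherits(mm, "meth_matrix"))
  vm <- value_matrix(mm$values)
  if (any(is.na(vm))) abort("matrix has missing values; impute first.")
  sds <- apply(vm, 1, sd)
  tibble::tibble(site_id = rownames(vm)[sds > sd_threshold],
                 sd = unname(sds[sds > sd_threshold]))
}

#' Cluster samples by hypervariable methylation
#'
#' Ward-linkage hierarchical clustering on Euclidean distance between
#' samples, cut at `k` clusters. The cluster holding a strict majority of the
#' normal control samples is labeled `normal-like`; among the rest, the
#' cluster with the highest mean methylation at CGI-flagged sites is
#' `CIMP-like` and the others `intermediate`. Without normals (or when they
#' split with no majority) labeling falls back to ordering all clusters by
#' mean CGI methylation (lowest = normal-like) and the result is flagged.
#'
#' @param mm A complete `meth_matrix`, typically restricted to hypervariable
#'   sites (see `sites` argument).
#' @param k Number of clusters (>= 2).
#' @param normal_sample_ids Character vector of normal control sample ids
#'   (possibly empty).
#' @param sites Optional character vector of site ids to cluster on (e.g.
#'   `hypervariable_sites(mm)$site_id`).
#' @return A `meth_clusters` object; `tidy()` gives the per-sample
#'   assignment.
#' @export
cluster_methylation <- function(mm, k = 3, normal_sample_ids = character(),
                                sites = NULL) {
  stopifnot(inherits(mm, "meth_matrix"))
  check_count(k, "k", min = 2)
  vm <- value_matrix(mm$values)
  if (!is.null(sites)) vm <- vm[rownames(vm) %in% sites, , drop = FALSE]
  if (any(is.na(vm))) abort("matrix has missing values; impute first.")
  if (!all(normal_sample_ids %in% colnames(vm))) {
    abort("`normal_sample_ids` must be a subset of the samples.")
  }
  hc <- hclust(dist(t(vm)), method = "ward.D")
  cl <- cutree(hc, k = k)

  is_cgi <- if ("is_cgi" %in% names(mm$sites)) {
    mm$sites$is_cgi[match(rownames(vm), mm$sites$site_id)]
  }
  if (is.null(is_cgi) || all(!is_cgi %in% c(TRUE, FALSE)) || !any(is_cgi, na.rm = TRUE)) {
    cgi_rows <- rep(TRUE, nrow(vm))  # no CGI annotation: overall mean stands in
  } else {
    cgi_rows <- !is.na(is_cgi) & is_cgi
  }
  cgi_mean <- vapply(seq_len(k), function(g) {
    mean(vm[cgi_rows, cl == g, drop = FALSE])
  }, numeric(1))

  labels <- rep(NA_character_, k)
  fallback <- FALSE
  if (length(normal_sample_ids)) {
    tab <- table(factor(cl[normal_sample_ids], levels = seq_len(k)))
    if (max(tab) > length(normal_sample_ids) / 2) {
      normal_cl <- as.integer(names(which.max(tab)))
      labels[normal_cl] <- "normal-like"
      rest <- setdiff(seq_len(k), normal_cl)
      labels[rest[which.max(cgi_mean[rest])]] <- "CIMP-like"
      labels[is.na(labels)] <- "intermediate"
    } else {
      fallback <- TRUE
      warn("normal samples split across clusters with no majority; labels fall back to mean-methylation ordering.")
    }
  } else {
    fallback <- TRUE
  }
  if (fallback) {
    ord <- order(cgi_mean)
    labels[ord[1]] <- "normal-like"
    labels[ord[k]] <- "CIMP-like"
    labels[is.na(labels)] <- "intermediate"
  }

  structure(
    list(
      assignment = tibble::tibble(
        sample_id = colnames(vm),
        cluster = unname(cl),
        label = labels[cl]
      ),
      hclust = hc,
      labels = labels,
      cgi_mean = cgi_mean,
      sites = rownames(vm),
      fallback = fallback
    ),
    class = "meth_clusters"
  )
}

#' @export
print.meth_clusters <- function(x, ...) {
  cat("<meth_clusters> ", nrow(x$assignment), " samples, ",
      length(x$labels), " clusters on ", length(x$sites), " sites\n", sep = "")
  print(table(x$assignment$label))
  invisible(x)
}

#' @method tidy meth_clusters
#' @export
tidy.meth_clusters <- function(x, ...) x$assignment

#' @method glance meth_clusters
#' @export
glance.meth_clusters <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$assignment),
    n_clusters = length(x$labels),
    n_sites = length(x$sites),
    label_fallback = x$fallback
  )
}

# ---- I/O -------------------------------------------------------------------

#' Read a wide signature-count TSV
#'
#' Expects `site_id`, `chrom`, `pos` then `<sample>_meth_reads` /
#' `<sample>_unmeth_reads` column pairs, as written by [write_cohort()].
#'
#' @param path TSV path.
#' @return List with `sites` (minimal annotation) and long `counts`.
#' @export
read_signature_counts <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- intersect(names(wide), meta_cols)
  long <- tidyr::pivot_longer(wide, -dplyr::all_of(meta),
                              names_to = c("sample_id", "kind"),
                              names_pattern = "(.*)_(meth_reads|unmeth_reads)",
                              values_to = "reads")
  counts <- tidyr::pivot_wider(long, names_from = "kind",
                               values_from = "reads")
  list(sites = wide[, meta], counts = counts[, c("site_id", "sample_id",
                                                 "meth_reads", "unmeth_reads")])
}

#' Flag sites by overlap with BED annotation tracks
#'
#' BED intervals are 0-based half-open; site positions are 1-based. Uses
#' rtracklayer/GenomicRanges for import and overlap.
#'
#' @param sites Site tibble with `chrom`, `pos`.
#' @param cgi,ctcf,enhancer Optional BED paths; each sets the matching
#'   `is_*` flag.
#' @return `sites` with `is_cgi` / `is_ctcf` / `is_enhancer` columns updated.
#' @export
annotate_sites_bed <- function(sites, cgi = NULL, ctcf = NULL,
                               enhancer = NULL) {
  for (pkg in c("rtracklayer", "GenomicRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("package `", pkg, "` is required for BED annotation."))
    }
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos, width = 1)
  )
  flag <- function(path) {
    bed <- rtracklayer::import(path, format = "BED")
    GenomicRanges::countOverlaps(gr_sites, bed) > 0
  }
  if (!is.null(cgi)) sites$is_cgi <- flag(cgi)
  if (!is.null(ctcf)) sites$is_ctcf <- flag(ctcf)
  if (!is.null(enhancer)) sites$is_enhancer <- flag(enhancer)
  sites
}

#' Write a methylation matrix to TSV
#'
#' @param mm A `meth_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylation_tsv <- function(mm, path) {
  stopifnot(inherits(mm, "meth_matrix"))
  readr::write_tsv(mm$values, path)
  invisible(path)
}
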