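#  7-gene qPCR expression panel and the z4 resistance classifier.
#
#  Relative expression per gene is dCT = mean Ct(GAPDH) - mean Ct(target)
#  over triplicates (higher dCT = higher expression). Per-gene z-scores are
#  standardized across the cohort, and the 4-gene classifier
#  z4 = zCDA + zP15 + zCTCF - zDNMT3B summarizes the resistance signature:
#  negative z4 (high DNMT3B, low CDA/P15/CTCF) predicts resistance to
#  hypomethylating therapy.

#' Delta-Ct from qPCR triplicates
#'
#' `dct = mean(Ct GAPDH) - mean(Ct target)`, averaging the non-missing wells
#' of each triplicate. Patients whose target (or GAPDH) triplicate is fully
#' missing get `NA` and are flagged.
#'
#' @param ct Tibble with `patient_id`, `gene`, `ct1..ct3`,
#'   `gapdh1..gapdh3` (one row per patient-gene assay).
#' @return Tibble `patient_id`, `gene`, `dct`, `flag_missing`.
#' @export
delta_ct <- function(ct) {
  need <- c("patient_id", "gene", paste0("ct", 1:3), paste0("gapdh", 1:3))
  if (!all(need %in% names(ct))) {
    abort(paste("`ct` needs columns:", paste(need, collapse = ", ")))
  }
  tgt <- rowMeans(ct[, paste0("ct", 1:3)], na.rm = TRUE)
  gap <- rowMeans(ct[, paste0("gapdh", 1:3)], na.rm = TRUE)
  tgt[is.nan(tgt)] <- NA_real_
  gap[is.nan(gap)] <- NA_real_
  tibble::tibble(
    patient_id = ct$patient_id,
    gene = ct$gene,
    dct = gap - tgt,
    flag_missing = is.na(tgt) | is.na(gap)
  )
}

#' Cohort z-scores of delta-Ct, per gene
#'
#' Standardizes each gene across patients: `(dct - mean) / sd` with the
#' n - 1 SD, so each gene has cohort mean 0 and SD 1.
#'
#' @param dct Long tibble `patient_id`, `gene`, `dct` (e.g. [delta_ct()]
#'   output).
#' @param by Optional column name to standardize within (e.g. `"cohort"` for
#'   a separate discovery/validation standardization); default pools the
#'   whole table.
#' @return Input with a `z` column appended.
#' @export
zscore_panel <- function(dct, by = NULL) {
  if (!all(c("patient_id", "gene", "dct") %in% names(dct))) {
    abort("`dct` needs columns patient_id, gene, dct.")
  }
  grp <- if (is.null(by)) "gene" else c("gene", by)
  out <- dct |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      .n_obs = sum(!is.na(.data$dct)),
      .sd = sd(.data$dct, na.rm = TRUE),
      z = (.data$dct - mean(.data$dct, na.rm = TRUE)) / .data$.sd
    ) |>
    dplyr::ungroup()
  if (any(out$.n_obs < 2)) {
    abort(paste("gene(s) with fewer than 2 observed dCT values:",
                paste(unique(out$gene[out$.n_obs < 2]), collapse = ", ")))
  }
  bad <- unique(out$gene[!is.na(out$.sd) & out$.sd == 0])
  if (length(bad)) {
    abort(paste("zero dCT standard deviation for gene(s):",
                paste(bad, collapse = ", ")))
  }
  dplyr::select(out, -".n_obs", -".sd")
}

#' The 4-gene z4 resistance score
#'
#' `z4 = zCDA + zP15 + zCTCF - zDNMT3B`. Patients missing any component get
#' `NA` with a flag.
#'
#' @param z Long tibble `patient_id`, `gene`, `z` covering at least CDA,
#'   P15, CTCF and DNMT3B.
#' @return Tibble `patient_id`, `z4`, `flag_missing`.
#' @export
z4_score <- function(z) {
  comp <- c("CDA", "P15", "CTCF", "DNMT3B")
  wide <- z |>
    dplyr::filter(.data$gene %in% comp) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "gene",
                       values_from = "z")
  for (g in setdiff(comp, names(wide))) wide[[g]] <- NA_real_
  tibble::tibble(
    patient_id = wide$patient_id,
    z4 = wide$CDA + wide$P15 + wide$CTCF - wide$DNMT3B,
    flag_missing = is.na(wide$CDA) | is.na(wide$P15) | is.na(wide$CTCF) |
      is.na(wide$DNMT3B)
  )
}

#' Classify patients by z4 threshold
#'
#' `z4 < threshold` predicts resistance; `z4 >= threshold` (boundary
#' included) predicts sensitivity.
#'
#' @param z4 Numeric vector of z4 scores.
#' @param threshold Decision threshold (default 0).
#' @return Character vector `"predicted-resistant"` /
#'   `"predicted-sensitive"` (`NA` passed through).
#' @export
classify_z4 <- function(z4, threshold = 0) {
  ifelse(is.na(z4), NA_character_,
         ifelse(z4 < threshold, "predicted-resistant", "predicted-sensitive"))
}

#' Two-group expression clustering (R/S) on the 7-gene panel
#'
#' Ward-linkage hierarchical clustering of patients on Euclidean distance
#' over the per-gene z-scores, cut at `k = 2`. The resistant cluster R is
#' the one with the higher mean zDNMT3B and the lower mean zP15; if the two
#' criteria conflict, DNMT3B decides. If both criteria tie exactly, the
#' cluster with the lower mean zCDA is R (logged in the result).
#'
#' @param z Long tibble `patient_id`, `gene`, `z` over the 7 panel genes
#'   (complete).
#' @param k Number of clusters (2 for the R/S dichotomy).
#' @return An `expr_clusters` object: `assignment` tibble (`patient_id`,
#'   `cluster` in R/S), `gene_means` (per-cluster mean z by gene, the
#'   labeling evidence), `separation` (Euclidean distance between cluster
#'   mean profiles), `tiebreak_used` flag.
#' @export
cluster_expression <- function(z, k = 2) {
  check_count(k, "k", min = 2)
  wide <- tidyr::pivot_wider(z, id_cols = "patient_id", names_from = "gene",
                             values_from = "z")
  zm <- as.matrix(wide[, -1])
  rownames(zm) <- wide$patient_id
  if (any(is.na(zm))) abort("z matrix must be complete.")
  hc <- hclust(dist(zm), method = "ward.D")
  cl <- cutree(hc, k = k)

  gene_means <- purrr::map_dfr(seq_len(k), function(g) {
    tibble::tibble(cluster = g, gene = colnames(zm),
                   mean_z = colMeans(zm[cl == g, , drop = FALSE]))
  })
  m <- function(g, gene) gene_means$mean_z[gene_means$cluster == g &
                                             gene_means$gene == gene]
  # R = high DNMT3B, low P15; DNMT3B dominates on conflict.
  tiebreak <- FALSE
  d3b <- vapply(seq_len(k), function(g) m(g, "DNMT3B"), numeric(1))
  p15 <- vapply(seq_len(k), function(g) m(g, "P15"), numeric(1))
  if (k == 2 && d3b[1] == d3b[2]) {
    if (p15[1] != p15[2]) {
      r_cl <- which.min(p15)
    } else {
      tiebreak <- TRUE
      cda <- vapply(seq_len(k), function(g) m(g, "CDA"), numeric(1))
      r_cl <- which.min(cda)
    }
  } else {
    r_cl <- which.max(d3b)
  }
  label <- ifelse(seq_len(k) == r_cl, "R", "S")
  if (k > 2) label[label == "S"] <- "S"  # all non-R clusters labeled S

  profiles <- vapply(seq_len(k), function(g)
    colMeans(zm[cl == g, , drop = FALSE]), numeric(ncol(zm)))
  separation <- if (k == 2) sqrt(sum((profiles[, 1] - profiles[, 2])^2)) else
    NA_real_

  structure(
    list(
      assignment = tibble::tibble(patient_id = rownames(zm),
                                  cluster = label[cl]),
      gene_means = dplyr::mutate(gene_means,
                                 cluster = label[.data$cluster]),
      separation = separation,
      tiebreak_used = tiebreak,
      hclust = hc
    ),
    class = "expr_clusters"
  )
}

#' @export
print.expr_clusters <- function(x, ...) {
  cat("<expr_clusters> ", nrow(x$assignment), " patients: ",
      sum(x$assignment$cluster == "R"), " R / ",
      sum(x$assignment$cluster == "S"), " S (separation ",
      sprintf("%.2f", x$separation), ")\n", sep = "")
  invisible(x)
}

#' @method tidy expr_clusters
#' @export
tidy.expr_clusters <- function(x, ...) x$assignment

#' @method glance expr_clusters
#' @export
glance.expr_clusters <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$assignment),
    n_resistant = sum(x$assignment$cluster == "R"),
    separation = x$separation,
    tiebreak_used = x$tiebreak_used
  )
}

#' Full expression-panel workflow
#'
#' Runs [delta_ct()], [zscore_panel()], [z4_score()], [classify_z4()] and
#' [cluster_expression()] and returns one patient-level table.
#'
#' @param ct Ct-triplicate tibble (see [delta_ct()]).
#' @param z4_threshold Threshold for [classify_z4()].
#' @return List with `table` (patient_id, z4, z4_class, cluster) and
#'   `clusters` (the `expr_clusters` object).
#' @export
expression_workflow <- function(ct, z4_threshold = 0) {
  dct <- delta_ct(ct)
  z <- zscore_panel(dct)
  z4 <- z4_score(z)
  cl <- cluster_expression(z)
  tab <- dplyr::left_join(z4[, c("patient_id", "z4")], cl$assignment,
                          by = "patient_id")
  tab$z4_class <- classify_z4(tab$z4, z4_threshold)
  list(table = tab, clusters = cl)
}

#' Read a Ct-triplicate CSV
#'
#' @param path CSV with `patient_id`, `gene`, `ct1..ct3`, `gapdh1..gapdh3`.
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
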