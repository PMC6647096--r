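#  Targeted-panel variant filtering and mutation summaries.
#
#  Calls from a myeloid amplicon panel are filtered through a fixed cascade
#  (depth >= 100, quality >= 50, VAF >= 5%, COSMIC hematopoietic annotation,
#  absent from common dbSNP at population frequency > 1%), collapsed to a
#  binary gene-by-patient mutation matrix, and summarized: combined RAS
#  (KRAS | NRAS) status with a mutual-exclusivity report, and exact-test
#  comparison of per-gene frequencies against an external reference cohort
#  with Bonferroni family control.

FILTER_RULES <- c("depth", "qual", "vaf", "cosmic", "dbsnp")

#' Filter panel variant calls through the quality cascade
#'
#' A call passes iff `depth >= min_depth`, `qual >= min_qual`,
#' `vaf >= min_vaf`, `cosmic_heme` is `TRUE`, and `dbsnp_common_freq` is
#' absent (`NA`) or `<= max_pop_freq`. The rejection tally attributes each
#' failing call to the first failing rule in that order (pass/fail itself is
#' order-independent). Records with missing depth/qual/vaf are rejected with
#' reason `"parse"`.
#'
#' @param calls Tibble with columns `patient_id`, `gene`, `depth`, `qual`,
#'   `vaf`, `cosmic_heme`, `dbsnp_common_freq` (NA = not in dbSNP common).
#' @param min_depth,min_qual,min_vaf,max_pop_freq Cascade thresholds.
#' @return List with `passed` (tibble of passing calls) and `tally`
#'   (tibble `rule`, `n_rejected`, including `parse`).
#' @export
filter_variants <- function(calls, min_depth = 100, min_qual = 50,
                            min_vaf = 0.05, max_pop_freq = 0.01) {
  check_positive(min_depth, "min_depth")
  check_positive(min_qual, "min_qual")
  check_positive(min_vaf, "min_vaf")
  check_positive(max_pop_freq, "max_pop_freq")
  need <- c("patient_id", "gene", "depth", "qual", "vaf", "cosmic_heme",
            "dbsnp_common_freq")
  if (!all(need %in% names(calls))) {
    abort(paste("`calls` needs columns:", paste(need, collapse = ", ")))
  }
  malformed <- is.na(calls$depth) | is.na(calls$qual) | is.na(calls$vaf) |
    is.na(calls$cosmic_heme)
  ok <- !malformed
  fail_depth <- ok & calls$depth < min_depth
  fail_qual <- ok & !fail_depth & calls$qual < min_qual
  fail_vaf <- ok & !fail_depth & !fail_qual & calls$vaf < min_vaf
  fail_cosmic <- ok & !fail_depth & !fail_qual & !fail_vaf & !calls$cosmic_heme
  fail_dbsnp <- ok & !fail_depth & !fail_qual & !fail_vaf & !fail_cosmic &
    !is.na(calls$dbsnp_common_freq) & calls$dbsnp_common_freq > max_pop_freq
  passed <- ok & !fail_depth & !fail_qual & !fail_vaf & !fail_cosmic &
    !fail_dbsnp
  tally <- tibble::tibble(
    rule = c(FILTER_RULES, "parse"),
    n_rejected = c(sum(fail_depth), sum(fail_qual), sum(fail_vaf),
                   sum(fail_cosmic), sum(fail_dbsnp), sum(malformed))
  )
  list(passed = calls[passed, , drop = FALSE], tally = tally)
}

#' Binary gene-by-patient mutation matrix
#'
#' @param passed Tibble of passing calls (`patient_id`, `gene`).
#' @param patients Character vector of all patient ids (patients without
#'   calls appear as all-zero columns).
#' @param panel_genes Character vector of panel genes (matrix rows).
#' @return A `mutation_matrix`: list with `matrix` (0/1 integer matrix,
#'   genes x patients) and `burden` (tibble `patient_id`, `n_mutations`).
#' @export
build_mutation_matrix <- function(passed, patients,
                                  panel_genes = PANEL_GENES) {
  if (!all(passed$gene %in% panel_genes)) {
    abort(paste("call gene(s) outside the panel:",
                paste(unique(setdiff(passed$gene, panel_genes)), collapse = ", ")))
  }
  if (!all(passed$patient_id %in% patients)) {
    abort(paste("call(s) for unknown patient:",
                paste(unique(setdiff(passed$patient_id, patients)),
                      collapse = ", ")))
  }
  m <- matrix(0L, nrow = length(panel_genes), ncol = length(patients),
              dimnames = list(panel_genes, patients))
  if (nrow(passed)) {
    m[cbind(match(passed$gene, panel_genes),
            match(passed$patient_id, patients))] <- 1L
  }
  structure(
    list(
      matrix = m,
      burden = tibble::tibble(patient_id = patients,
                              n_mutations = unname(colSums(m)))
    ),
    class = "mutation_matrix"
  )
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("<mutation_matrix> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " patients; median burden ", median(x$burden$n_mutations), "\n",
      sep = "")
  invisible(x)
}

#' @method tidy mutation_matrix
#' @export
tidy.mutation_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$matrix,
                                        responseName = "mutated",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("gene", "patient_id", "mutated"))
}

#' Combined RAS (KRAS | NRAS) status
#'
#' @param mut A `mutation_matrix` whose panel includes KRAS and NRAS.
#' @return List with `status` (tibble `patient_id`, `ras_mut`) and
#'   `exclusivity_violations` (patients mutated in both; expected empty
#'   because KRAS and NRAS mutations are mutually exclusive in AML).
#' @export
ras_status <- function(mut) {
  stopifnot(inherits(mut, "mutation_matrix"))
  if (!all(c("KRAS", "NRAS") %in% rownames(mut$matrix))) {
    abort("mutation matrix must contain KRAS and NRAS rows.")
  }
  k <- mut$matrix["KRAS", ]
  n <- mut$matrix["NRAS", ]
  list(
    status = tibble::tibble(patient_id = colnames(mut$matrix),
                            ras_mut = unname((k + n) > 0)),
    exclusivity_violations = colnames(mut$matrix)[k == 1 & n == 1]
  )
}

#' Compare cohort mutation frequencies with a reference cohort
#'
#' Per gene, a two-sided exact 2x2 test of mutated/unmutated counts in the
#' cohort versus the reference, flagged at the Bonferroni-adjusted level
#' `alpha_family / n_tests` (0.05 / 19 ~ 0.0026 for the conventional
#' 19-gene myeloid comparison).
#'
#' @param mut A `mutation_matrix`.
#' @param reference_freqs Tibble with `gene` and `freq` (fraction mutated in
#'   the reference cohort).
#' @param n_ref Reference cohort size.
#' @param alpha_family Family-wise alpha.
#' @param n_tests Number of tests in the family (Bonferroni divisor).
#' @return Tibble per shared gene: counts, frequencies, odds ratio, exact
#'   `p`, the Bonferroni threshold, and a significance flag. Genes missing
#'   from the reference are skipped with a warning.
#' @export
compare_frequencies <- function(mut, reference_freqs, n_ref,
                                alpha_family = 0.05, n_tests = 19) {
  stopifnot(inherits(mut, "mutation_matrix"))
  check_count(n_ref, "n_ref", min = 1)
  genes <- rownames(mut$matrix)
  missing <- setdiff(genes, reference_freqs$gene)
  if (length(missing)) {
    warn(paste("gene(s) missing from reference, skipped:",
               paste(missing, collapse = ", ")))
  }
  genes <- intersect(genes, reference_freqs$gene)
  n_cohort <- ncol(mut$matrix)
  threshold <- alpha_family / n_tests
  purrr::map_dfr(genes, function(g) {
    a <- sum(mut$matrix[g, ])
    ref_k <- round(reference_freqs$freq[reference_freqs$gene == g][1] * n_ref)
    ft <- fisher_exact_2x2(a, n_cohort - a, ref_k, n_ref - ref_k)
    tibble::tibble(
      gene = g,
      n_mut_cohort = a, n_cohort = n_cohort,
      n_mut_ref = ref_k, n_ref = n_ref,
      freq_cohort = a / n_cohort, freq_ref = ref_k / n_ref,
      odds_ratio = ft$odds_ratio, p = ft$p,
      alpha_bonferroni = threshold,
      significant = ft$p < threshold
    )
  })
}

#' Read a VCF-like variant call TSV
#'
#' @param path TSV with the columns described in [filter_variants()].
#' @return Tibble of calls.
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    gene = readr::col_character(),
                    dbsnp_common_freq = readr::col_double(),
                    .default = readr::col_guess()
                  ))
}
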