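#  Synthetic r/r AML cohort generator.
#
#  Emulates the joint structure the downstream biomarker analysis assumes:
#  a latent treatment-resistant subgroup (~20% of patients) carrying
#  RAS-pathway mutations at a higher rate, CpG-island hypermethylation
#  (CIMP-like), high DNMT3B / low CDA, P15 and CTCF expression, a lower
#  composite response rate, blunted LINE-1 demethylation on treatment, and
#  shorter overall survival.

PANEL_GENES <- c(
  "KRAS", "NRAS", "IDH1", "IDH2", "DNMT3A", "TP53", "ASXL1", "NPM1",
  "FLT3", "TET2", "RUNX1", "CEBPA", "WT1", "SF3B1", "SRSF2", "U2AF1",
  "EZH2", "GATA2", "KIT"
)

#  Per-gene sporadic (non-RAS, non-IDH) mutation rates, tuned so the median
#  per-patient burden is 1 (observed range 0-5 in the study cohort size).
OTHER_GENE_RATES <- c(
  DNMT3A = 0.12, TP53 = 0.08, ASXL1 = 0.10, NPM1 = 0.08, FLT3 = 0.10,
  TET2 = 0.08, RUNX1 = 0.10, CEBPA = 0.03, WT1 = 0.05, SF3B1 = 0.03,
  SRSF2 = 0.04, U2AF1 = 0.03, EZH2 = 0.02, GATA2 = 0.02, KIT = 0.03
)

GENE_LOCI <- tibble::tibble(
  gene  = c("KRAS", "NRAS", "IDH1", "IDH2", "DNMT3A", "TP53", "ASXL1",
            "NPM1", "FLT3", "TET2", "RUNX1", "CEBPA", "WT1", "SF3B1",
            "SRSF2", "U2AF1", "EZH2", "GATA2", "KIT"),
  chrom = c("chr12", "chr1", "chr2", "chr15", "chr2", "chr17", "chr20",
            "chr5", "chr13", "chr4", "chr21", "chr19", "chr11", "chr2",
            "chr17", "chr21", "chr7", "chr3", "chr4"),
  pos   = c(25398284L, 115258747L, 209113112L, 90631934L, 25457242L,
            7577120L, 31022441L, 170837543L, 28592642L, 106157698L,
            36252877L, 33792742L, 32417945L, 198266834L, 74732959L,
            44524456L, 148508727L, 128204951L, 55599321L)
)

EXPRESSION_GENES <- c("CDA", "P15", "P21", "DNMT1", "DNMT3A", "DNMT3B", "CTCF")

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the pipeline was designed around:
#' 122 analyzable patients, a ~20% latent resistant subgroup with a 0%
#' composite response (CRc) rate versus 29% among sensitive patients, RAS
#' mutations in 44% vs 10%, and median overall survival of 154 vs 237 days.
#'
#' @param n_patients Number of patients.
#' @param frac_resistant Probability a patient belongs to the latent
#'   resistant class.
#' @param crc_rate_sensitive,crc_rate_resistant Composite complete response
#'   (CR + CRp + CRi) probability per class.
#' @param ras_rate_resistant,ras_rate_sensitive Probability of a KRAS or NRAS
#'   mutation per class (the two are mutually exclusive within a patient).
#' @param median_survival_resistant,median_survival_sensitive Median overall
#'   survival in days; survival is exponential with rate `log(2) / median`.
#' @param censor_horizon Administrative censoring horizon in days; each
#'   patient additionally draws an independent uniform censoring time on
#'   `[0, censor_horizon]`.
#' @param n_sites Number of CpG (CCCGGG) sites in the methylation layer.
#' @param frac_cgi_sites Fraction of sites flagged as CpG-island sites.
#' @param depth_mean Mean sequencing depth per site and sample (Poisson).
#' @param n_normals Number of normal blood control samples in the
#'   methylation layer (no clinical record).
#' @param frac_phase1 Fraction of patients assigned to the phase I
#'   (discovery) cohort; the rest are phase II (validation).
#' @param expression_effects Named numeric vector of per-gene delta-Ct shifts
#'   applied to resistant-class patients. Sign pattern: DNMT3B up; CDA, P15,
#'   CTCF down.
#' @param ct_noise_sd Patient-level biological noise SD on delta-Ct, in Ct
#'   units.
#' @param cgi_shift_resistant Mean methylation elevation at CGI sites for
#'   resistant-class patients (CIMP-like), on the 0-1 fraction scale.
#' @param line1_demeth_mean_resistant,line1_demeth_mean_sensitive Mean of the
#'   maximum LINE-1 demethylation (percentage points) during cycle 1.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   seed.
#'
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 122,
                              frac_resistant = 0.20,
                              crc_rate_sensitive = 0.29,
                              crc_rate_resistant = 0.00,
                              ras_rate_resistant = 0.44,
                              ras_rate_sensitive = 0.10,
                              median_survival_resistant = 154,
                              median_survival_sensitive = 237,
                              censor_horizon = 1100,
                              n_sites = 2000,
                              frac_cgi_sites = 0.4,
                              depth_mean = 50,
                              n_normals = 5,
                              frac_phase1 = 27 / 122,
                              expression_effects = c(CDA = -1.4, P15 = -1.4,
                                                     P21 = 0, DNMT1 = -1.4,
                                                     DNMT3A = 1.4, DNMT3B = 1.4,
                                                     CTCF = -1.4),
                              ct_noise_sd = 0.5,
                              cgi_shift_resistant = 0.25,
                              line1_demeth_mean_resistant = 15.4,
                              line1_demeth_mean_sensitive = 26.3,
                              seed = 1L) {
  check_count(n_patients, "n_patients", min = 2)
  check_fraction(frac_resistant, "frac_resistant")
  check_fraction(crc_rate_sensitive, "crc_rate_sensitive")
  check_fraction(crc_rate_resistant, "crc_rate_resistant")
  check_fraction(ras_rate_resistant, "ras_rate_resistant")
  check_fraction(ras_rate_sensitive, "ras_rate_sensitive")
  check_fraction(frac_cgi_sites, "frac_cgi_sites")
  check_fraction(frac_phase1, "frac_phase1")
  check_positive(median_survival_resistant, "median_survival_resistant")
  check_positive(median_survival_sensitive, "median_survival_sensitive")
  check_positive(censor_horizon, "censor_horizon")
  check_positive(depth_mean, "depth_mean")
  check_count(n_sites, "n_sites", min = 1)
  check_count(n_normals, "n_normals", min = 0)
  if (!all(EXPRESSION_GENES %in% names(expression_effects))) {
    abort("`expression_effects` must name all 7 panel genes.")
  }
  check_positive(ct_noise_sd, "ct_noise_sd")
  structure(
    list(
      n_patients = as.integer(n_patients),
      frac_resistant = frac_resistant,
      crc_rate_sensitive = crc_rate_sensitive,
      crc_rate_resistant = crc_rate_resistant,
      ras_rate_resistant = ras_rate_resistant,
      ras_rate_sensitive = ras_rate_sensitive,
      median_survival_resistant = median_survival_resistant,
      median_survival_sensitive = median_survival_sensitive,
      censor_horizon = censor_horizon,
      n_sites = as.integer(n_sites),
      frac_cgi_sites = frac_cgi_sites,
      depth_mean = depth_mean,
      n_normals = as.integer(n_normals),
      frac_phase1 = frac_phase1,
      expression_effects = expression_effects[EXPRESSION_GENES],
      ct_noise_sd = ct_noise_sd,
      cgi_shift_resistant = cgi_shift_resistant,
      line1_demeth_mean_resistant = line1_demeth_mean_resistant,
      line1_demeth_mean_sensitive = line1_demeth_mean_sensitive,
      seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

#' Draw DREAM signature read counts for one or more sites
#'
#' Methylated-signature reads are binomial in the true methylation fraction;
#' methylated + unmethylated reads always sum to the supplied depth.
#'
#' @param true_methylation Numeric vector of true methylation fractions in
#'   `[0, 1]`.
#' @param depth Integer vector of total read depths (recycled).
#' @return A tibble with columns `meth_reads` and `unmeth_reads`.
#' @export
simulate_signature_reads <- function(true_methylation, depth) {
  check_fraction(true_methylation, "true_methylation")
  if (any(is.na(depth)) || any(depth < 0)) {
    abort("`depth` must be non-negative.")
  }
  n <- max(length(true_methylation), length(depth))
  true_methylation <- rep_len(true_methylation, n)
  depth <- rep_len(as.integer(depth), n)
  meth <- rbinom(n, size = depth, prob = true_methylation)
  tibble::tibble(meth_reads = meth, unmeth_reads = depth - meth)
}

#' Simulate a complete synthetic cohort
#'
#' Generates every layer the pipeline consumes: a clinical/outcome table,
#' qPCR Ct triplicates for the 7-gene expression panel, filtered-quality
#' panel variant calls (plus a few artifact calls that the filter cascade
#' should remove), DREAM signature read counts over annotated CpG sites
#' (patients plus normal controls), a LINE-1 methylation series per patient,
#' and the latent truth (class labels and true methylation).
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `aml_cohort` with elements `patients`,
#'   `expression`, `variants`, `sites`, `signature_counts`, `line1`, and
#'   `truth`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  if (!inherits(config, "cohort_sim_config")) {
    abort("`config` must be created by cohort_sim_config().")
  }
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    resistant <- runif(n) < config$frac_resistant

    patients <- simulate_clinical(ids, resistant, config)
    expression <- simulate_expression(ids, resistant, config)
    variants <- simulate_variants(ids, resistant, config)
    meth <- simulate_methylation_layer(ids, resistant, config)
    line1 <- simulate_line1(ids, resistant, config)

    patients$ras_mut <- ids %in%
      variants$patient_id[variants$gene %in% c("KRAS", "NRAS") & variants$pass_truth]
    patients$idh1_mut <- ids %in%
      variants$patient_id[variants$gene == "IDH1" & variants$pass_truth]
    patients$idh2_mut <- ids %in%
      variants$patient_id[variants$gene == "IDH2" & variants$pass_truth]

    structure(
      list(
        patients = patients,
        expression = expression,
        variants = dplyr::select(variants, -"pass_truth"),
        sites = meth$sites,
        signature_counts = meth$counts,
        line1 = line1,
        truth = list(
          classes = tibble::tibble(
            patient_id = ids,
            latent_class = ifelse(resistant, "resistant", "sensitive")
          ),
          methylation = meth$true_methylation,
          variant_truth = variants[variants$pass_truth,
                                   c("patient_id", "gene")]
        ),
        config = config
      ),
      class = "aml_cohort"
    )
  })
}

#' @export
print.aml_cohort <- function(x, ...) {
  cls <- table(x$truth$classes$latent_class)
  cat("<aml_cohort> ", nrow(x$patients), " patients (",
      paste(names(cls), cls, sep = ": ", collapse = ", "), "), ",
      nrow(x$sites), " CpG sites, ", x$config$n_normals,
      " normal controls\n", sep = "")
  invisible(x)
}

# ---- layer generators (internal) -------------------------------------------

simulate_clinical <- function(ids, resistant, config) {
  n <- length(ids)
  crc_p <- ifelse(resistant, config$crc_rate_resistant,
                  config$crc_rate_sensitive)
  crc <- runif(n) < crc_p
  # CR vs CRp/CRi split among composite responders: 60/40, then CRp/CRi even.
  subtype <- ifelse(runif(n) < 0.6, "CR",
                    ifelse(runif(n) < 0.5, "CRp", "CRi"))
  response <- ifelse(crc, subtype, "none")

  med <- ifelse(resistant, config$median_survival_resistant,
                config$median_survival_sensitive)
  t_death <- rexp(n, rate = log(2) / med)
  # Administrative censoring: uniform accrual over the first half of the
  # study window, follow-up to the horizon, so censoring times are uniform
  # on [horizon/2, horizon] (independent of survival).
  t_cens <- runif(n, config$censor_horizon / 2, config$censor_horizon)
  survival_days <- pmin(t_death, t_cens)
  event <- as.integer(t_death <= t_cens)

  lognorm_med <- function(med_r, med_s, sdlog) {
    rlnorm(n, meanlog = log(ifelse(resistant, med_r, med_s)), sdlog = sdlog)
  }
  tibble::tibble(
    patient_id = ids,
    cohort = ifelse(runif(n) < config$frac_phase1, "phaseI", "phaseII"),
    response = response,
    survival_days = round(survival_days, 1),
    event = event,
    age = pmin(pmax(rnorm(n, 62, 12), 20), 90),
    sex = ifelse(runif(n) < 0.6, "M", "F"),
    cyto_risk = sample(c("poor", "intermediate", "unevaluable"), n,
                       replace = TRUE, prob = c(0.42, 0.48, 0.10)),
    pb_blasts = pmin(lognorm_med(72, 4, 1.0), 99),
    bm_blasts = pmin(lognorm_med(71, 26, 0.5), 95),
    platelets = lognorm_med(25, 41, 0.8),
    hemoglobin = lognorm_med(9.3, 9.2, 0.15),
    wbc = lognorm_med(9.9, 1.8, 1.0)
  )
}

simulate_expression <- function(ids, resistant, config) {
  n <- length(ids)
  #  The latent resistant class is the single co-regulation factor: it
  #  shifts all affected gene means jointly; residual variation is i.i.d.
  base_dct <- c(CDA = -4, P15 = -6, P21 = -4, DNMT1 = -5, DNMT3A = -6,
                DNMT3B = -7, CTCF = -4)
  purrr::map_dfr(EXPRESSION_GENES, function(g) {
    dct_true <- base_dct[[g]] +
      config$expression_effects[[g]] * resistant +
      rnorm(n, 0, config$ct_noise_sd)
    gapdh_true <- rnorm(n, 20, 0.3)
    target_true <- gapdh_true - dct_true
    tech <- function(mu) t(vapply(mu, function(m) m + rnorm(3, 0, 0.15),
                                  numeric(3)))
    tg <- tech(target_true)
    gp <- tech(gapdh_true)
    tibble::tibble(
      patient_id = ids, gene = g,
      ct1 = tg[, 1], ct2 = tg[, 2], ct3 = tg[, 3],
      gapdh1 = gp[, 1], gapdh2 = gp[, 2], gapdh3 = gp[, 3]
    )
  })
}

simulate_variants <- function(ids, resistant, config) {
  n <- length(ids)
  ras_p <- ifelse(resistant, config$ras_rate_resistant,
                  config$ras_rate_sensitive)
  has_ras <- runif(n) < ras_p
  ras_gene <- ifelse(runif(n) < 0.5, "KRAS", "NRAS")  # mutually exclusive

  rows <- list()
  for (i in seq_len(n)) {
    genes <- character(0)
    if (has_ras[i]) genes <- ras_gene[i]
    if (runif(1) < 0.07) genes <- c(genes, "IDH1")
    if (runif(1) < 0.12) genes <- c(genes, "IDH2")
    others <- names(OTHER_GENE_RATES)[runif(length(OTHER_GENE_RATES)) <
                                        OTHER_GENE_RATES]
    genes <- unique(c(genes, others))
    if (length(genes)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = ids[i], gene = genes,
        depth = as.integer(round(runif(length(genes), 500, 5000))),
        qual = round(runif(length(genes), 60, 100), 1),
        vaf = round(0.05 + 0.8 * stats::rbeta(length(genes), 2, 5), 4),
        cosmic_heme = TRUE,
        dbsnp_common_freq = ifelse(runif(length(genes)) < 0.2, 0.001, NA_real_),
        pass_truth = TRUE
      )
    }
    # Artifact call that one cascade rule should reject.
    if (runif(1) < 0.4) {
      fail <- sample(c("depth", "qual", "vaf", "cosmic", "dbsnp"), 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = ids[i],
        gene = sample(PANEL_GENES, 1),
        depth = if (fail == "depth") 50L else 1500L,
        qual = if (fail == "qual") 30 else 80,
        vaf = if (fail == "vaf") 0.02 else 0.25,
        cosmic_heme = fail != "cosmic",
        dbsnp_common_freq = if (fail == "dbsnp") 0.05 else NA_real_,
        pass_truth = FALSE
      )
    }
  }
  calls <- dplyr::bind_rows(rows)
  calls <- dplyr::left_join(calls, GENE_LOCI, by = "gene")
  calls$ref <- sample(c("A", "C", "G", "T"), nrow(calls), replace = TRUE)
  calls$alt <- vapply(calls$ref,
                      function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                      character(1))
  dplyr::select(calls, "patient_id", "gene", "chrom", "pos", "ref", "alt",
                "depth", "qual", "vaf", "cosmic_heme", "dbsnp_common_freq",
                "pass_truth")
}

simulate_methylation_layer <- function(ids, resistant, config) {
  n_sites <- config$n_sites
  is_cgi <- runif(n_sites) < config$frac_cgi_sites
  sites <- tibble::tibble(
    site_id = sprintf("S%05d", seq_len(n_sites)),
    chrom = sample(paste0("chr", 1:22), n_sites, replace = TRUE),
    pos = sample.int(2e8, n_sites),
    is_cgi = is_cgi,
    is_ctcf = runif(n_sites) < 0.15,
    is_enhancer = runif(n_sites) < 0.10,
    is_promoter = is_cgi & runif(n_sites) < 0.6,
    gene = ifelse(runif(n_sites) < 0.3,
                  sample(PANEL_GENES, n_sites, replace = TRUE), NA_character_)
  )
  # Normal blood baseline: CGI sites largely unmethylated, non-CGI moderate.
  base <- ifelse(is_cgi, stats::rbeta(n_sites, 1, 9),
                 stats::rbeta(n_sites, 6, 4))

  all_ids <- c(ids, if (config$n_normals > 0)
    sprintf("N%02d", seq_len(config$n_normals)))
  resistant_all <- c(resistant, rep(FALSE, config$n_normals))
  is_normal <- c(rep(FALSE, length(ids)), rep(TRUE, config$n_normals))

  # Per-sample CGI elevation: CIMP-like for the resistant class, a milder
  # spread among sensitive patients, none for normals.
  cgi_shift <- ifelse(is_normal, 0,
                      ifelse(resistant_all,
                             config$cgi_shift_resistant + rnorm(length(all_ids), 0, 0.05),
                             abs(rnorm(length(all_ids), 0, 0.08))))
  drift <- ifelse(is_normal, 0, rnorm(length(all_ids), 0, 0.03))

  true_m <- matrix(
    vapply(seq_along(all_ids), function(j) {
      m <- base + is_cgi * cgi_shift[j] + drift[j]
      pmin(pmax(m, 0), 1)
    }, numeric(n_sites)),
    nrow = n_sites, dimnames = list(NULL, all_ids))

  depth <- matrix(rpois(n_sites * length(all_ids), config$depth_mean),
                  nrow = n_sites)
  meth <- matrix(rbinom(n_sites * length(all_ids), as.vector(depth),
                        as.vector(true_m)), nrow = n_sites)

  counts <- tibble::tibble(
    site_id = rep(sites$site_id, times = length(all_ids)),
    sample_id = rep(all_ids, each = n_sites),
    meth_reads = as.vector(meth),
    unmeth_reads = as.vector(depth - meth)
  )
  truth <- tibble::as_tibble(true_m)
  truth <- dplyr::bind_cols(tibble::tibble(site_id = sites$site_id), truth)
  list(sites = sites, counts = counts, true_methylation = truth)
}

simulate_line1 <- function(ids, resistant, config) {
  n <- length(ids)
  baseline <- pmin(pmax(rnorm(n, 75, 4), 50), 95)
  target <- pmax(rnorm(n, ifelse(resistant,
                                 config$line1_demeth_mean_resistant,
                                 config$line1_demeth_mean_sensitive), 12), 0)
  target <- pmin(target, baseline * 0.9)
  purrr::map_dfr(seq_len(n), function(i) {
    vals <- c(baseline[i] - target[i] * runif(1, 0.3, 0.9),
              baseline[i] - target[i],
              baseline[i] - target[i] * runif(1, 0.3, 0.9))
    tibble::tibble(
      patient_id = ids[i],
      day = c(0L, 8L, 15L, 22L),
      line1_pct = round(pmin(pmax(c(baseline[i], vals[sample.int(3)]), 0), 100), 2)
    )
  })
}

#' Write a synthetic cohort to the pipeline's input file formats
#'
#' Emits a wide TSV signature-count matrix (`site_id`, `chrom`, `pos`, then a
#' `<sample>_meth` / `<sample>_unmeth` column pair per sample), a BED file per
#' annotation track (CGI, CTCF, enhancer; 0-based half-open), a VCF-like
#' variant TSV, a Ct-triplicate CSV, a clinical CSV, a LINE-1 CSV, and a
#' truth CSV of latent class labels.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aml_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "signature_counts.tsv"),
    cgi = file.path(dir, "cgi.bed"),
    ctcf = file.path(dir, "ctcf.bed"),
    enhancer = file.path(dir, "enhancer.bed"),
    variants = file.path(dir, "variants.tsv"),
    expression = file.path(dir, "expression_ct.csv"),
    clinical = file.path(dir, "clinical.csv"),
    line1 = file.path(dir, "line1.csv"),
    truth = file.path(dir, "truth.csv")
  )
  wide <- tidyr::pivot_wider(
    cohort$signature_counts,
    names_from = "sample_id",
    values_from = c("meth_reads", "unmeth_reads"),
    names_glue = "{sample_id}_{.value}"
  )
  samples <- unique(cohort$signature_counts$sample_id)
  ord <- as.vector(rbind(paste0(samples, "_meth_reads"),
                         paste0(samples, "_unmeth_reads")))
  wide <- dplyr::left_join(cohort$sites[, c("site_id", "chrom", "pos")],
                           wide[, c("site_id", ord)], by = "site_id")
  readr::write_tsv(wide, paths[["counts"]])

  write_bed <- function(flag, path) {
    b <- cohort$sites[cohort$sites[[flag]], c("chrom", "pos")]
    b <- tibble::tibble(chrom = b$chrom, start = b$pos - 1L, end = b$pos)
    readr::write_tsv(b, path, col_names = FALSE)
  }
  write_bed("is_cgi", paths[["cgi"]])
  write_bed("is_ctcf", paths[["ctcf"]])
  write_bed("is_enhancer", paths[["enhancer"]])

  readr::write_tsv(cohort$variants, paths[["variants"]])
  readr::write_csv(cohort$expression, paths[["expression"]])
  readr::write_csv(cohort$patients, paths[["clinical"]])
  readr::write_csv(cohort$line1, paths[["line1"]])
  readr::write_csv(cohort$truth$classes, paths[["truth"]])
  invisible(paths)
}
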