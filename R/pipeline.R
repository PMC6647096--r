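#  End-to-end orchestration: methylation -> variants -> expression ->
#  association -> survival, from a structured config, with deterministic
#  seeds and a manifest.

#' Pipeline configuration
#'
#' Thresholds default to the analysis conventions used throughout the
#' package: coverage >= 20 reads in >= 75% of samples, hypervariable SD >
#' 0.10, variant depth >= 100 / quality >= 50 / VAF >= 5% / population
#' frequency <= 1%, z4 threshold 0, alpha 0.05.
#'
#' @param input An `aml_cohort` (in-memory) or a named list of file paths
#'   (`counts`, `variants`, `expression`, `clinical`, `line1`) as written by
#'   [write_cohort()].
#' @param min_reads,min_sample_frac,sd_threshold Methylation-stage
#'   thresholds.
#' @param min_depth,min_qual,min_vaf,max_pop_freq Variant-stage thresholds.
#' @param z4_threshold,alpha,b_permutations Analysis-stage settings.
#' @param stages Character vector of stages to run (subset of
#'   `c("methylation", "variants", "expression", "association",
#'   "survival")`).
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            min_reads = 20, min_sample_frac = 0.75,
                            sd_threshold = 0.10,
                            min_depth = 100, min_qual = 50, min_vaf = 0.05,
                            max_pop_freq = 0.01,
                            z4_threshold = 0, alpha = 0.05,
                            b_permutations = 1000,
                            stages = c("methylation", "variants",
                                       "expression", "association",
                                       "survival"),
                            seed = 1L) {
  known <- c("methylation", "variants", "expression", "association",
             "survival")
  if (!all(stages %in% known)) {
    abort(paste("unknown stage(s):",
                paste(setdiff(stages, known), collapse = ", ")))
  }
  structure(
    list(input = input, min_reads = min_reads,
         min_sample_frac = min_sample_frac, sd_threshold = sd_threshold,
         min_depth = min_depth, min_qual = min_qual, min_vaf = min_vaf,
         max_pop_freq = max_pop_freq, z4_threshold = z4_threshold,
         alpha = alpha, b_permutations = b_permutations,
         stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

load_pipeline_input <- function(input) {
  if (inherits(input, "aml_cohort")) {
    return(list(
      sites = input$sites, counts = input$signature_counts,
      variants = input$variants, expression = input$expression,
      clinical = input$patients, line1 = input$line1,
      checksums = NULL
    ))
  }
  if (!is.list(input)) abort("`input` must be an aml_cohort or a path list.")
  paths <- unlist(input)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste("input file(s) not found:", paste(missing, collapse = ", ")))
  }
  sc <- if (!is.null(input$counts)) read_signature_counts(input$counts)
  list(
    sites = sc$sites,
    counts = sc$counts,
    variants = if (!is.null(input$variants)) read_variants(input$variants),
    expression = if (!is.null(input$expression))
      read_ct_table(input$expression),
    clinical = if (!is.null(input$clinical)) read_clinical(input$clinical),
    line1 = if (!is.null(input$line1)) read_line1(input$line1),
    checksums = tools::md5sum(paths)
  )
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      file.create(file.path(out_dir, paste0(name, ".partial")))
    }
    abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full biomarker pipeline
#'
#' Executes the configured stages in order and returns a result bundle with
#' a manifest (package version, seed, thresholds, input checksums when the
#' inputs are files). Identical config and inputs give identical outputs.
#' On a stage failure the run halts with a stage-named error and, when
#' `out_dir` is set, leaves a `<stage>.partial` marker.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for per-stage TSV/CSV outputs.
#' @return A list of class `pipeline_result`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  dat <- load_pipeline_input(config$input)
  res <- list()
  st <- config$stages

  if ("methylation" %in% st) {
    res$methylation <- run_stage("methylation", out_dir, {
      mm <- methylation_from_counts(dat$counts, dat$sites)
      mm <- coverage_filter(mm, config$min_reads, config$min_sample_frac)
      mm <- impute_pmm(mm, seed = config$seed)
      hv <- hypervariable_sites(mm, config$sd_threshold)
      normals <- grep("^N\\d", sample_cols(mm$values), value = TRUE)
      cl <- if (nrow(hv) >= 2 && length(sample_cols(mm$values)) >= 3) {
        cluster_methylation(mm, k = 3, normal_sample_ids = normals,
                            sites = hv$site_id)
      } else NULL
      if (!is.null(out_dir)) {
        write_methylation_tsv(mm, file.path(out_dir, "methylation.tsv"))
        if (!is.null(cl)) {
          readr::write_csv(cl$assignment,
                           file.path(out_dir, "methylation_clusters.csv"))
        }
      }
      list(matrix = mm, hypervariable = hv, clusters = cl)
    })
  }

  if ("variants" %in% st) {
    res$variants <- run_stage("variants", out_dir, {
      fv <- filter_variants(dat$variants, config$min_depth, config$min_qual,
                            config$min_vaf, config$max_pop_freq)
      mut <- build_mutation_matrix(fv$passed, dat$clinical$patient_id,
                                   union(PANEL_GENES,
                                         unique(fv$passed$gene)))
      ras <- ras_status(mut)
      if (!is.null(out_dir)) {
        readr::write_tsv(tidy(mut), file.path(out_dir, "mutations.tsv"))
        readr::write_csv(fv$tally, file.path(out_dir, "filter_tally.csv"))
      }
      list(filtered = fv, matrix = mut, ras = ras)
    })
  }

  if ("expression" %in% st) {
    res$expression <- run_stage("expression", out_dir, {
      wf <- expression_workflow(dat$expression, config$z4_threshold)
      if (!is.null(out_dir)) {
        readr::write_csv(wf$table, file.path(out_dir, "expression_z4.csv"))
      }
      wf
    })
  }

  if ("association" %in% st) {
    res$association <- run_stage("association", out_dir, {
      out <- list()
      clinical <- dat$clinical
      if (!is.null(res$expression)) {
        clinical <- dplyr::left_join(
          clinical, res$expression$table[, c("patient_id", "cluster", "z4",
                                             "z4_class")],
          by = "patient_id")
        crc <- response_rates(clinical, "CRc", group = "cluster")
        out$crc_by_cluster <- crc
        if (nrow(crc) == 2) {
          out$fisher_cluster <- fisher_exact_2x2(
            crc$n_response[crc$cluster == "R"],
            crc$n_total[crc$cluster == "R"] -
              crc$n_response[crc$cluster == "R"],
            crc$n_response[crc$cluster == "S"],
            crc$n_total[crc$cluster == "S"] -
              crc$n_response[crc$cluster == "S"])
        }
      }
      if (!is.null(res$methylation) && !is.null(res$methylation$clusters)) {
        mm <- res$methylation$matrix
        pts <- intersect(sample_cols(mm$values), clinical$patient_id)
        cr <- clinical$response[match(pts, clinical$patient_id)] == "CR"
        if (sum(cr) >= 2 && sum(!cr) >= 2) {
          sub <- mm$values[, c("site_id", pts)]
          X <- value_matrix(sub)
          out$dmc <- permutation_dmc(X, cr, B = config$b_permutations,
                                     seed = config$seed)
          out$enrichment <- feature_enrichment(
            out$dmc$site_id[out$dmc$p < config$alpha], mm$sites)
        }
      }
      if (!is.null(dat$line1)) {
        out$line1 <- max_line1_demethylation(dat$line1)
      }
      if (!is.null(out_dir) && !is.null(out$dmc)) {
        readr::write_tsv(out$dmc, file.path(out_dir, "dmc.tsv"))
      }
      out
    })
  }

  if ("survival" %in% st) {
    res$survival <- run_stage("survival", out_dir, {
      clinical <- dat$clinical
      out <- list(km_overall = km_estimate(clinical$survival_days,
                                           clinical$event))
      if (!is.null(res$expression)) {
        cl <- res$expression$table$cluster[
          match(clinical$patient_id, res$expression$table$patient_id)]
        clinical$cluster <- cl
        out$km_by_cluster <- clinical |>
          dplyr::group_by(.data$cluster) |>
          dplyr::group_map(~ km_estimate(.x$survival_days, .x$event)) |>
          setNames(sort(unique(cl)))
        out$logrank_cluster <- logrank_test(clinical$survival_days,
                                            clinical$event, cl)
        out$two_year <- two_year_survival(clinical, group = "cluster")
      }
      if (!is.null(out_dir)) {
        readr::write_tsv(tidy(out$km_overall),
                         file.path(out_dir, "km_overall.tsv"))
      }
      out
    })
  }

  manifest <- list(
    package = as.character(utils::packageVersion("epiresist")),
    seed = config$seed,
    stages = st,
    thresholds = config[setdiff(names(config), c("input", "stages", "seed"))],
    input_checksums = dat$checksums,
    n_patients = if (!is.null(dat$clinical)) nrow(dat$clinical) else NA
  )
  structure(c(res, list(manifest = manifest)), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}

#' Group-characteristics report
#'
#' Builds a per-expression-cluster characteristics table in the shape of a
#' clinical-trial baseline table: group sizes, median (range) of age and
#' blood counts, response rates, median survival and crude 2-year rate,
#' with comparison p-values when there are two or more nonempty groups
#' (Mann-Whitney for continuous descriptors, exact test for rates).
#'
#' @param result A `pipeline_result` with at least the expression stage (and
#'   a clinical table).
#' @param clinical The clinical tibble used in the run (required when the
#'   pipeline input was an `aml_cohort`, pass `cohort$patients`).
#' @return Tibble: one row per characteristic, one column per group, plus
#'   `p`.
#' @export
make_report <- function(result, clinical) {
  stopifnot(inherits(result, "pipeline_result"))
  if (is.null(result$expression)) {
    abort("report requires the expression stage.")
  }
  df <- dplyr::left_join(
    clinical,
    result$expression$table[, c("patient_id", "cluster")],
    by = "patient_id")
  df <- df[!is.na(df$cluster), , drop = FALSE]
  groups <- sort(unique(df$cluster))
  if (!length(groups)) abort("no labeled patients.")

  med_range <- function(v) {
    if (!length(v)) return("n=0")
    sprintf("%.1f (%.1f-%.1f)", median(v), min(v), max(v))
  }
  cont_vars <- c(age = "age", pb_blasts = "pb_blasts",
                 bm_blasts = "bm_blasts", platelets = "platelets",
                 hemoglobin = "hemoglobin", wbc = "wbc")
  cont_vars <- cont_vars[cont_vars %in% names(df)]

  rows <- list()
  rows[[1]] <- c(list(characteristic = "n"),
                 setNames(as.list(as.character(
                   vapply(groups, function(g) sum(df$cluster == g),
                          numeric(1)))), groups),
                 list(p = NA_real_))
  for (v in cont_vars) {
    p <- if (length(groups) >= 2 &&
             all(vapply(groups, function(g)
               sum(df$cluster == g & !is.na(df[[v]])) > 0, logical(1)))) {
      compare_groups(df[[v]], df$cluster, "wilcoxon")$p
    } else NA_real_
    rows[[length(rows) + 1]] <- c(
      list(characteristic = paste0(v, ", median (range)")),
      setNames(lapply(groups, function(g) med_range(df[[v]][df$cluster == g])),
               groups),
      list(p = p))
  }
  for (scope in c("CR", "CRc")) {
    rr <- response_rates(df, scope, group = "cluster")
    cells <- setNames(lapply(groups, function(g) {
      r <- rr[rr$cluster == g, ]
      if (!nrow(r)) "n=0" else sprintf("%d/%d (%.0f%%)", r$n_response,
                                       r$n_total, r$percent)
    }), groups)
    p <- if (nrow(rr) == 2) {
      fisher_exact_2x2(rr$n_response[1], rr$n_total[1] - rr$n_response[1],
                       rr$n_response[2], rr$n_total[2] - rr$n_response[2],
                       odds_ratio = FALSE)$p
    } else NA_real_
    rows[[length(rows) + 1]] <- c(
      list(characteristic = paste0(scope, " rate")), cells, list(p = p))
  }
  if (all(c("survival_days", "event") %in% names(df))) {
    meds <- setNames(lapply(groups, function(g) {
      d <- df[df$cluster == g, ]
      if (!nrow(d)) return("n=0")
      m <- km_estimate(d$survival_days, d$event)$median
      if (is.na(m)) "not reached" else sprintf("%.0f", m)
    }), groups)
    p <- if (length(groups) >= 2) {
      logrank_test(df$survival_days, df$event, df$cluster)$p
    } else NA_real_
    rows[[length(rows) + 1]] <- c(
      list(characteristic = "median survival, days"), meds, list(p = p))
    ty <- two_year_survival(df, group = "cluster")
    cells <- setNames(lapply(groups, function(g) {
      r <- ty[ty$cluster == g, ]
      if (!nrow(r)) "n=0" else sprintf("%d/%d (%.0f%%)", r$n_survivors,
                                       r$n_total, r$percent)
    }), groups)
    p <- if (nrow(ty) == 2) {
      fisher_exact_2x2(ty$n_survivors[1], ty$n_total[1] - ty$n_survivors[1],
                       ty$n_survivors[2], ty$n_total[2] - ty$n_survivors[2],
                       odds_ratio = FALSE)$p
    } else NA_real_
    rows[[length(rows) + 1]] <- c(
      list(characteristic = "2-year survival rate"), cells, list(p = p))
  }
  purrr::map_dfr(rows, ~ tibble::as_tibble(.x))
}
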