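#  Internal argument checks shared across modules.

check_fraction <- function(x, name, allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must be a fraction in [0, 1]."))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x))) {
    abort(paste0("`", name, "` must be an integer >= ", min, "."))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be positive."))
  }
  invisible(x)
}

#  Wide site-by-sample methylation tibbles carry `site_id` plus one column per
#  sample; these helpers pull the two apart without repeating the column
#  bookkeeping at every call site.
meta_cols <- c("site_id", "chrom", "pos", "is_cgi", "is_ctcf", "is_enhancer",
               "is_promoter", "gene")

sample_cols <- function(df) setdiff(names(df), meta_cols)

value_matrix <- function(df) {
  sc <- sample_cols(df)
  m <- as.matrix(df[, sc, drop = FALSE])
  rownames(m) <- df$site_id
  m
}

#  Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
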