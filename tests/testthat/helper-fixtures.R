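# Shared fixtures: every dataset is built in code, seeded.

options(masspipe.log = FALSE)

# A tiny fully observed dataset with hand-set values.
tiny_dataset <- function(n_var = 3, n_sample = 4) {
  expr <- matrix(seq_len(n_var * n_sample), nrow = n_var,
                 dimnames = list(paste0("v", seq_len(n_var)),
                                 paste0("s", seq_len(n_sample))))
  si <- data.frame(sample_id = paste0("s", seq_len(n_sample)),
                   class = rep(c("Subject", "QC"),
                               length.out = n_sample),
                   group = rep(c("Case", "Control"),
                               length.out = n_sample),
                   injection_order = seq_len(n_sample),
                   stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = paste0("v", seq_len(n_var)),
                   mz = 100 + seq_len(n_var), rt = 30 * seq_len(n_var),
                   stringsAsFactors = FALSE)
  create_mass_dataset(expr, si, vi)
}

# Small randomized dataset via the generator (QC + subjects + NAs).
small_sim <- function(seed, n_subject = 12, n_qc = 4, n_variable = 20,
                      mv_rate = 0.1, ...) {
  generate_dataset(n_subject = n_subject, n_qc = n_qc,
                   n_variable = n_variable, mv_rate = mv_rate,
                   seed = seed, ...)
}

# A random spectrum with sorted fragments.
random_spectrum <- function(id, mz = 200, rt = 100, n_frag = 6) {
  ms2_spectrum(id, mz, rt,
               cbind(sort(runif(n_frag, 50, mz - 1)),
                     runif(n_frag, 1, 100)))
}

# --------------------------------------------------------------------------
# Random valid pipelines over the operation registry.  Steps respect the
# few real preconditions (no scaling before imputation, no log after
# scaling); everything else is drawn at random.  Returns the final
# dataset; its history can be replayed onto the base.
# --------------------------------------------------------------------------
random_pipeline <- function(ds, n_steps, seed) {
  set.seed(seed)
  has_na <- anyNA(extract_expression_data(ds))
  transformed <- FALSE   # scaled/logged: raw-scale ops no longer valid
  for (step in seq_len(n_steps)) {
    pool <- c("na_freq", "filter_samples", "filter_variables",
              "flag_noisy", "impute", "univariate")
    if (!transformed) pool <- c(pool, "normalize", "log")
    if (!has_na && !transformed) pool <- c(pool, "scale")
    op <- sample(pool, 1)
    ds <- switch(
      op,
      na_freq = mutate_variable_na_freq(ds, label = paste0("st", step)),
      filter_samples = {
        si <- extract_sample_info(ds)
        qc <- si$sample_id[si$class == "QC"]
        subj <- si$sample_id[si$class != "QC"]
        keep <- c(qc, sample(subj, max(4, round(0.85 * length(subj)))))
        filter_samples(ds, function(s) s$sample_id %in% keep)
      },
      filter_variables = {
        vi <- extract_variable_info(ds)
        keep <- sample(vi$variable_id,
                       max(5, round(0.85 * nrow(vi))))
        filter_variables(ds, function(v) v$variable_id %in% keep)
      },
      flag_noisy = flag_noisy_variables(ds),
      impute = {
        m <- sample(c("knn", "zero", "mean", "median", "minimum", "svd"), 1)
        out <- impute(ds, method = m, k = 5, rank = 3)
        has_na <- FALSE
        out
      },
      normalize = normalize_data(ds, sample(c("total", "median", "mean",
                                              "pqn"), 1)),
      log = {
        transformed <- TRUE
        log_transform(ds)
      },
      scale = {
        out <- tryCatch(scale_data(ds, sample(c("uv", "pareto", "center"), 1)),
                        error = function(e) NULL)
        if (is.null(out)) ds else {
          transformed <- TRUE
          out
        }
      },
      univariate = suppressWarnings(univariate_test(ds))
    )
    validate_mass_dataset(ds)
  }
  ds
}
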