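# Small in-code fixtures shared across the suite.

tiny_fa_table <- function() {
  metric_table(
    tibble::tibble(id = c("s1", "s2", "s3"),
                   roiA = c(0.41, 0.52, 0.47),
                   roiB = c(0.33, 0.38, 0.36)),
    metric = "fa",
    regions = region_info(c("roiA", "roiB"), hemisphere = "left", tissue = "wm")
  )
}

tiny_phenotypes <- function(n = 6) {
  tibble::tibble(
    id = sprintf("s%d", seq_len(n)),
    group = rep(c("TDC", "ASD"), length.out = n),
    age = seq(8, 8 + n - 1),
    sex = rep(c("M", "F"), length.out = n),
    iq_verbal = NA_real_, iq_nonverbal = NA_real_,
    iq_total = rep(100, n),
    ados_css = ifelse(rep(c(FALSE, TRUE), length.out = n), 5, NA),
    motion = rep(0.3, n)
  )
}

# a feature_matrix built directly from a numeric matrix, bypassing cohort IO
raw_features <- function(x, ages, metric = "fa", ids = sprintf("s%03d", seq_len(nrow(x)))) {
  if (is.null(colnames(x))) colnames(x) <- paste0(metric, ":r", seq_len(ncol(x)))
  structure(list(ids = ids, feature_names = colnames(x), x = x,
                 ages = ages, metrics = metric),
            class = "feature_matrix")
}

# noiseless cohort: every region an exact linear function of (effective) age
noiseless_config <- function(n_tdc = 80, n_asd = 20, deviation_sd = 0, seed = 1) {
  sim_config(n_tdc = n_tdc, n_asd = n_asd, noise_scale = 0,
             deviation_sd = deviation_sd, seed = seed)
}
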