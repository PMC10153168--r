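# Registry of denoising strategies.
#
# Two layers, mirroring the common literature strategies and the benchmark
# rows: four predefined families (simple, scrubbing, compcor, ica_aroma)
# and ten fully-specified benchmark strategies (baseline, simple,
# simple+gsr, scrubbing.5, scrubbing.5+gsr, scrubbing.2, scrubbing.2+gsr,
# compcor, compcor6, aroma).

strategy_spec <- function(name,
                          image_variant = "preproc",
                          high_pass = TRUE,
                          motion = "none",
                          wm_csf = "none",
                          global_signal = "none",
                          scrub = NA_integer_,
                          fd_threshold = NA_real_,
                          std_dvars_threshold = NA_real_,
                          compcor_mask = "none",
                          n_compcor = NA,
                          ica_aroma = FALSE,
                          demean = TRUE) {
  if (ica_aroma && (image_variant != "smoothAROMAnonaggr" || motion != "none")) {
    stop("ica_aroma strategies require the smoothAROMAnonaggr image variant ",
         "and no motion regressors")
  }
  structure(list(
    name = name, image_variant = image_variant, high_pass = high_pass,
    motion = motion, wm_csf = wm_csf, global_signal = global_signal,
    scrub = scrub, fd_threshold = fd_threshold,
    std_dvars_threshold = std_dvars_threshold,
    compcor_mask = compcor_mask, n_compcor = n_compcor,
    ica_aroma = ica_aroma, demean = demean
  ), class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat("<strategy_spec> ", x$name, "\n", sep = "")
  flds <- x[setdiff(names(x), "name")]
  for (f in names(flds)) cat(sprintf("  %-20s %s\n", f, format(flds[[f]])))
  invisible(x)
}

benchmark_registry <- function() {
  scrub5 <- list(scrub = 5L, fd_threshold = 0.5, std_dvars_threshold = 3)
  scrub2 <- list(scrub = 5L, fd_threshold = 0.2, std_dvars_threshold = 3)
  list(
    baseline = strategy_spec("baseline"),
    simple = strategy_spec("simple", motion = "full", wm_csf = "basic"),
    `simple+gsr` = strategy_spec("simple+gsr", motion = "full",
                                 wm_csf = "basic", global_signal = "basic"),
    scrubbing.5 = do.call(strategy_spec, c(list("scrubbing.5",
      motion = "full", wm_csf = "full"), scrub5)),
    `scrubbing.5+gsr` = do.call(strategy_spec, c(list("scrubbing.5+gsr",
      motion = "full", wm_csf = "full", global_signal = "basic"), scrub5)),
    scrubbing.2 = do.call(strategy_spec, c(list("scrubbing.2",
      motion = "full", wm_csf = "full"), scrub2)),
    `scrubbing.2+gsr` = do.call(strategy_spec, c(list("scrubbing.2+gsr",
      motion = "full", wm_csf = "full", global_signal = "basic"), scrub2)),
    compcor = strategy_spec("compcor", motion = "full",
                            compcor_mask = "anat_combined", n_compcor = "all"),
    compcor6 = strategy_spec("compcor6", motion = "full",
                             compcor_mask = "anat_combined", n_compcor = 6L),
    aroma = strategy_spec("aroma", image_variant = "smoothAROMAnonaggr",
                          wm_csf = "basic", ica_aroma = TRUE)
  )
}

# The four predefined families; `+gsr` handled by load_confounds_strategy.
predefined_registry <- function() {
  list(
    simple = strategy_spec("simple", motion = "full", wm_csf = "basic"),
    scrubbing = strategy_spec("scrubbing", motion = "full", wm_csf = "full",
                              scrub = 5L, fd_threshold = 0.2,
                              std_dvars_threshold = 3),
    compcor = strategy_spec("compcor", motion = "full",
                            compcor_mask = "anat_combined", n_compcor = "all"),
    ica_aroma = strategy_spec("ica_aroma",
                              image_variant = "smoothAROMAnonaggr",
                              wm_csf = "basic", ica_aroma = TRUE)
  )
}

#' Look up a denoising strategy by name
#'
#' @param name one of the ten benchmark strategy names or one of the four
#'   predefined families (`simple`, `scrubbing`, `compcor`, `ica_aroma`).
#' @return A `strategy_spec` holding the full parameter bundle.
#' @export
fc_strategy <- function(name) {
  reg <- benchmark_registry()
  if (name %in% names(reg)) return(reg[[name]])
  pre <- predefined_registry()
  if (name %in% names(pre)) return(pre[[name]])
  stop("unknown strategy '", name, "'; valid names: ",
       paste(unique(c(names(reg), names(pre))), collapse = ", "))
}

#' List the benchmark strategies with all parameters
#'
#' @return data.frame with one row per benchmark strategy and one column
#'   per parameter.
#' @export
list_strategies <- function() {
  reg <- benchmark_registry()
  do.call(rbind, lapply(reg, function(s) {
    data.frame(
      strategy = s$name, image = s$image_variant, high_pass = s$high_pass,
      motion = s$motion, wm_csf = s$wm_csf, global_signal = s$global_signal,
      scrub = s$scrub, fd_threshold = s$fd_threshold,
      std_dvars_threshold = s$std_dvars_threshold,
      compcor_mask = s$compcor_mask, n_compcor = as.character(s$n_compcor),
      ica_aroma = s$ica_aroma, demean = s$demean,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}
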