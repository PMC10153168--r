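# Confound parsing, category selection and the two loader APIs.

test_that("confounds pairing resolves siblings and rejects bad input", {
  df <- manual_conf_df(20)
  img <- write_pair(df)
  pair <- read_confounds_pair(img)
  expect_equal(pair$table$n_volumes, 20)
  expect_s3_class(pair$table, "confound_table")

  dir2 <- withr::local_tempdir()
  orphan <- file.path(dir2, "sub-02_task-rest_desc-preproc_bold.nii.gz")
  file.create(orphan)
  expect_error(read_confounds_pair(orphan), "expected.*confounds")
  expect_error(read_confounds_pair(file.path(dir2, "sub-02_bold.nii.gz")),
               "not an accepted BOLD")
})

test_that("n/a tokens parse as a volume-1 missing marker only", {
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "sub-01_task-rest")
  writeLines(c("trans_x\ttrans_x_derivative1",
               "0\tn/a", "1\t1", "3\t2"),
             paste0(stem, "_desc-confounds_timeseries.tsv"))
  img <- paste0(stem, "_desc-preproc_bold.nii.gz")
  file.create(img)
  tab <- read_confounds_pair(img)$table
  expect_identical(is.na(tab$data$trans_x_derivative1), c(TRUE, FALSE, FALSE))
  expect_equal(tab$data$trans_x, c(0, 1, 3))
})

test_that("TSV round trip preserves finite values and missing markers", {
  df <- manual_conf_df(15)
  tab <- confound_table(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confounds_tsv(tab, path)
  back <- utils::read.delim(path, na.strings = "n/a")
  expect_equal(as.data.frame(back), df, tolerance = 0)
})

test_that("expansion arithmetic yields (k, 2k, 2k, 4k) columns", {
  df <- manual_conf_df(12)
  tab <- confound_table(df)
  cases <- list(
    list(fn = function(o) expand_motion(tab, o), k = 6),
    list(fn = function(o) select_tissue(tab, "wm_csf", o), k = 2),
    list(fn = function(o) select_tissue(tab, "global_signal", o), k = 1))
  mult <- c(basic = 1, derivatives = 2, power2 = 2, full = 4)
  for (case in cases) {
    for (o in names(mult)) {
      expect_equal(ncol(case$fn(o)$matrix), case$k * mult[[o]],
                   info = paste(case$k, o))
    }
  }
  expect_identical(colnames(expand_motion(tab, "basic")$matrix),
                   c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z"))
})

test_that("motion derivative columns are imputed to 0 at volume 1", {
  df <- manual_conf_df(3)
  df$trans_x <- c(0, 1, 3)
  df$trans_x_derivative1 <- c(NA, 1, 2)
  sel <- expand_motion(confound_table(df), "derivatives")
  expect_equal(unname(sel$matrix[, "trans_x_derivative1"]), c(0, 1, 2))
})

test_that("missing expansion columns raise a named error", {
  df <- manual_conf_df(10)
  df$trans_x_power2 <- NULL
  expect_error(expand_motion(confound_table(df), "full"),
               "missing confound columns for category motion.*trans_x_power2")
})

test_that("compcor selects the 50% cumulative-variance prefix", {
  df <- manual_conf_df(10)
  tab <- confound_table(df)
  meta <- sidecar_meta(data.frame(
    name = sprintf("a_comp_cor_%02d", 0:4), mask = "combined",
    cumulative_variance_explained = c(0.20, 0.35, 0.48, 0.51, 0.60)))
  expect_equal(ncol(select_compcor(tab, meta, n = "all")$matrix), 4)
  expect_equal(ncol(select_compcor(tab, meta, n = 3)$matrix), 3)
  expect_error(select_compcor(tab, meta, n = 6), "only 5 available")
  empty <- sidecar_meta()
  expect_error(select_compcor(tab, empty), "combined-mask")
})

test_that("aroma selection checks image variant and column presence", {
  df <- manual_conf_df(10)
  tab <- confound_table(df)
  full <- select_aroma(tab, "smoothAROMAnonaggr", "full")
  expect_equal(ncol(full$matrix), 0)
  expect_error(select_aroma(tab, "preproc", "full"), "smoothAROMAnonaggr")
  agg <- select_aroma(tab, "preproc", "basic")
  expect_equal(unname(agg$counts["aroma"]), 4L)
  df2 <- df[!grepl("^aroma", names(df))]
  expect_error(select_aroma(confound_table(df2), "preproc", "basic"),
               "aroma_motion")
})

test_that("high-pass and non-steady-state columns are scanned correctly", {
  df <- manual_conf_df(10)
  tab <- confound_table(df)
  expect_equal(ncol(select_high_pass(tab)$matrix), 4)
  df2 <- df[!grepl("^cosine", names(df))]
  expect_error(select_high_pass(confound_table(df2)), "cosine")
  expect_equal(ncol(select_non_steady_state(tab)$matrix), 0)
  df$non_steady_state_outlier00 <- c(1, rep(0, 9))
  df$non_steady_state_outlier01 <- c(0, 1, rep(0, 8))
  sel <- select_non_steady_state(confound_table(df))
  expect_equal(ncol(sel$matrix), 2)
  # one-hot columns flag mutually distinct volumes
  expect_equal(max(rowSums(sel$matrix)), 1)
})

test_that("scrubbing mask matches the worked example and censors runs", {
  fd <- c(NA, 0.6, 0.1, 0.1, 0.1, 0.1, 0.1)
  df <- manual_conf_df(7, fd = fd, dvars = c(NA, rep(1, 6)))
  tab <- confound_table(df)
  m <- build_sample_mask(tab, fd_threshold = 0.5, min_segment = 5)
  # volume 2 censored; leading run {1} shorter than 5 also censored
  expect_identical(m$kept, 3:7)
  expect_equal(m$censored_count, 2L)

  all_low <- manual_conf_df(20, fd = c(NA, rep(0.1, 19)),
                            dvars = c(NA, rep(1, 19)))
  m2 <- build_sample_mask(confound_table(all_low), 0.5, min_segment = 5)
  expect_identical(m2$kept, 1:20)
})

test_that("scrubbing equals the brute-force oracle on enumerated traces", {
  for (n in c(4, 7, 10, 12)) {
    for (pattern in 0:(2^(n - 1) - 1)) {
      exceed <- c(FALSE, as.logical(bitwAnd(2^(0:(n - 2)), pattern)))
      fd <- ifelse(exceed, 0.9, 0.1)
      fd[1] <- NA
      df <- data.frame(framewise_displacement = fd,
                       std_dvars = c(NA, rep(1, n - 1)))
      m <- build_sample_mask(confound_table(df), 0.5, min_segment = 5)
      expect_identical(m$kept, as.integer(mask_oracle(exceed, 5)),
                       info = paste(n, pattern))
    }
  }
})

test_that("scrubbing equals the oracle on random traces and is monotone", {
  set.seed(42)
  for (rep in 1:25) {
    n <- 100
    fd <- c(NA, abs(rnorm(n - 1, 0.2, 0.15)))
    dv <- c(NA, abs(rnorm(n - 1, 1.5, 1)))
    df <- data.frame(framewise_displacement = fd, std_dvars = dv)
    tab <- confound_table(df)
    seg <- sample(1:6, 1)
    m <- build_sample_mask(tab, 0.3, 3, min_segment = seg)
    exceed <- (!is.na(fd) & fd > 0.3) | (!is.na(dv) & dv > 3)
    expect_identical(m$kept, as.integer(mask_oracle(exceed, seg)))
    # lowering the FD threshold never enlarges the kept set
    m_tight <- build_sample_mask(tab, 0.2, 3, min_segment = seg)
    expect_true(all(m_tight$kept %in% m$kept))
  }
})

test_that("load_confounds composes categories and demeans over kept rows", {
  df <- manual_conf_df(30)
  img <- write_pair(df, sidecar = default_sidecar())
  res <- load_confounds(img, strategy = c("high_pass", "motion", "wm_csf"),
                        motion = "basic", wm_csf = "basic")
  expect_equal(ncol(res$confounds$matrix), 6 + 2 + 4)
  expect_identical(res$sample_mask$kept, 1:30)
  # demeaned over retained volumes
  expect_lt(max(abs(colMeans(res$confounds$matrix))), 1e-12)

  empty <- load_confounds(img, strategy = character(0))
  expect_equal(ncol(empty$confounds$matrix), 0)
  expect_equal(empty$sample_mask$censored_count, 0L)

  expect_error(load_confounds(img, strategy = "bogus"), "unknown strategy")
})

test_that("selection rows align with the mask for scrubbed strategies", {
  fd <- c(NA, 0.6, 0.1, 0.1, 0.1, 0.1, 0.1)
  df <- manual_conf_df(7, fd = fd, dvars = c(NA, rep(1, 6)))
  img <- write_pair(df)
  res <- load_confounds(img, strategy = c("motion", "scrub"),
                        motion = "basic", scrub = 5, fd_threshold = 0.5)
  expect_identical(res$sample_mask$kept, 3:7)
  expect_equal(nrow(res$confounds$matrix), 7)
  kept_rows <- res$confounds$matrix[res$sample_mask$kept, ]
  expect_lt(max(abs(colMeans(kept_rows))), 1e-12)
})

test_that("list input returns per-path results in order", {
  dirs <- withr::local_tempdir()
  img1 <- write_pair(manual_conf_df(10), dir = file.path(dirs, "a"))
  img2 <- write_pair(manual_conf_df(14), dir = file.path(dirs, "b"))
  res <- load_confounds(c(img1, img2), strategy = "motion",
                        motion = "basic")
  expect_length(res, 2)
  expect_equal(nrow(res[[1]]$confounds$matrix), 10)
  expect_equal(nrow(res[[2]]$confounds$matrix), 14)
})

test_that("predefined strategies equal their explicit category bundles", {
  df <- manual_conf_df(40)
  img <- write_pair(df, sidecar = default_sidecar())
  img_sm <- write_pair(df, variant = "smoothAROMAnonaggr",
                       dir = dirname(img))

  bundles <- list(
    simple = list(img = img,
                  args = list(strategy = c("high_pass", "motion", "wm_csf",
                                           "non_steady_state"),
                              motion = "full", wm_csf = "basic")),
    scrubbing = list(img = img,
                     args = list(strategy = c("high_pass", "motion",
                                              "wm_csf", "scrub",
                                              "non_steady_state"),
                                 motion = "full", wm_csf = "full",
                                 scrub = 5, fd_threshold = 0.2,
                                 std_dvars_threshold = 3)),
    compcor = list(img = img,
                   args = list(strategy = c("high_pass", "motion",
                                            "compcor", "non_steady_state"),
                               motion = "full", n_compcor = "all")),
    ica_aroma = list(img = img_sm,
                     args = list(strategy = c("high_pass", "wm_csf",
                                              "ica_aroma",
                                              "non_steady_state"),
                                 wm_csf = "basic", ica_aroma = "full")))
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    via_name <- load_confounds_strategy(b$img, nm)
    via_bundle <- do.call(load_confounds, c(list(b$img), b$args))
    expect_identical(colnames(via_name$confounds$matrix),
                     colnames(via_bundle$confounds$matrix), info = nm)
    expect_equal(via_name$confounds$matrix, via_bundle$confounds$matrix,
                 info = nm)
    expect_identical(via_name$sample_mask$kept, via_bundle$sample_mask$kept,
                     info = nm)
  }
})

test_that("registry rows reproduce the benchmark parameter table", {
  tab <- list_strategies()
  expect_equal(nrow(tab), 10)
  expect_setequal(tab$strategy,
                  c("baseline", "simple", "simple+gsr", "scrubbing.5",
                    "scrubbing.5+gsr", "scrubbing.2", "scrubbing.2+gsr",
                    "compcor", "compcor6", "aroma"))
  expect_true(all(tab$high_pass))
  expect_true(all(tab$demean))
  expect_equal(tab$fd_threshold[tab$strategy == "scrubbing.2"], 0.2)
  expect_equal(tab$fd_threshold[tab$strategy == "scrubbing.5"], 0.5)
  expect_equal(tab$motion[tab$strategy == "baseline"], "none")
  expect_equal(tab$image[tab$strategy == "aroma"], "smoothAROMAnonaggr")
  expect_equal(tab$n_compcor[tab$strategy == "compcor6"], "6")
  expect_error(fc_strategy("not-a-strategy"), "valid names")
})

test_that("baseline keeps only cosine regressors; gsr variants add one", {
  df <- manual_conf_df(30)
  img <- write_pair(df)
  base <- load_confounds_strategy(img, "baseline")
  expect_equal(unname(base$confounds$counts["cosine"]), 4L)
  expect_equal(ncol(base$confounds$matrix), 4)
  s <- load_confounds_strategy(img, "simple")
  sg <- load_confounds_strategy(img, "simple+gsr")
  expect_equal(ncol(sg$confounds$matrix) - ncol(s$confounds$matrix), 1)
})

test_that("aggressive scrubbing retains a subset of liberal scrubbing", {
  set.seed(77)
  fd <- c(NA, abs(rnorm(59, 0.25, 0.2)))
  df <- manual_conf_df(60, fd = fd, dvars = c(NA, rep(1, 59)))
  img <- write_pair(df)
  k2 <- load_confounds_strategy(img, "scrubbing.2")$sample_mask$kept
  k5 <- load_confounds_strategy(img, "scrubbing.5")$sample_mask$kept
  expect_true(all(k2 %in% k5))
})
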