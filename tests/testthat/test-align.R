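test_that("linear segmentation maps cycle k onto slot k", {
  rec <- generate_record(60, duration_s = 2, seed = 1)
  rp <- rpeak_set(c(150, 650), 500)
  tpl <- build_template(2, 500, 60, 0.3)
  mp <- segment_cycles(rec, rp, "linear", template = tpl)
  expect_equal(nrow(mp), 1)
  expect_equal(c(mp$src_start, mp$src_stop), c(150, 650))
  expect_equal(c(mp$dst_start, mp$dst_stop),
               c(tpl$rpeak_slots[1], tpl$rpeak_slots[2]))
})

test_that("hrc segmentation degenerates to identity lengths at the target rate", {
  rec <- generate_record(60, first_r_s = 0.25, seed = 2)
  rp <- detect_rpeaks(rec)
  tpl <- default_template()
  mp <- segment_cycles(rec, rp, "hrc", template = tpl)
  expect_true(all((mp$src_stop - mp$src_start) ==
                  (mp$dst_stop - mp$dst_start)))
})

test_that("hrc keeps the QRS window fixed and stretches P/T regions", {
  rec <- generate_record(120, seed = 5)
  rp <- detect_rpeaks(rec)
  tpl <- default_template()  # 60 bpm target
  mp <- suppressWarnings(segment_cycles(rec, rp, "hrc", template = tpl))
  copies <- mp[mp$kind == "copy", ]
  expect_true(all((copies$src_stop - copies$src_start) ==
                  (copies$dst_stop - copies$dst_start)))
  # the fixed window is 35 ms + 55 ms of samples, split pre/post
  lens <- copies$src_stop - copies$src_start
  expect_true(all(lens %in% c(18, 28)))  # 35 ms and 55 ms at 500 Hz, rounded half-up
  stretch <- mp[mp$kind == "resample", ]
  expect_true(all((stretch$dst_stop - stretch$dst_start) >=
                  (stretch$src_stop - stretch$src_start)))
})

test_that("the mapping tiles the covered template span without gaps or overlaps", {
  for (hr in c(55, 87, 132)) {
    rec <- generate_record(hr, rr_jitter_frac = 0.05, seed = hr)
    rp <- detect_rpeaks(rec)
    mp <- suppressWarnings(segment_cycles(rec, rp, "hrc",
                                          template = default_template()))
    mp <- mp[mp$dst_stop > mp$dst_start, ]
    ord <- order(mp$dst_start)
    expect_true(all(mp$dst_start[ord][-1] == mp$dst_stop[ord][-nrow(mp)]))
    # source intervals ordered identically to target intervals
    expect_true(all(diff(mp$src_start[ord]) >= 0))
  }
})

test_that("transform places every mapped R-peak exactly on its template slot", {
  tpl <- default_template()
  for (strategy in c("hrc", "linear")) {
    rec <- generate_record(80, seed = 7)
    cfg <- alignment_config(tpl, strategy = strategy,
                            output = "full_signal")
    res <- suppressWarnings(transform(rec, cfg))
    peaks <- res$rpeaks_detected$indices
    cyc <- res$mapping[res$mapping$dst_start %in% tpl$rpeak_slots &
                       res$mapping$src_start %in% peaks, ]
    expect_gt(nrow(cyc), 0)
    # the sample at each receiving slot is the source R-peak sample
    for (i in seq_len(nrow(cyc))) {
      expect_equal(res$aligned[cyc$dst_start[i] + 1, 2],
                   rec$signal[cyc$src_start[i] + 1, 2])
    }
    # and the aligned lead II peaks sit on the slots
    for (s in cyc$dst_start) {
      win <- (s - 20):(s + 20)
      expect_equal(win[which.max(abs(res$aligned[win + 1, 2]))], s)
    }
  }
})

test_that("a record already on the template grid passes through unchanged", {
  tpl <- build_template(10, 500, 60, 0.3)
  rec <- generate_record(60, first_r_s = 0.3, seed = 1)
  res <- suppressWarnings(transform(rec, alignment_config(
    tpl, strategy = "hrc", output = "full_signal")))
  cov <- which(res$covered)
  expect_lt(max(abs(res$aligned[cov, ] - rec$signal[cov, ])), 1e-6)
  expect_true(all(!res$covered[1:150]))  # leading span zero-filled
  expect_equal(unname(res$aligned[10, 5]), 0)
})

test_that("fs or duration mismatch with the template is rejected", {
  rec <- generate_record(60, duration_s = 8, seed = 1)
  expect_error(transform(rec, alignment_config(default_template())),
               "match")
})

test_that("hrc median beats superimpose across heart rates; linear beats do not", {
  tpl <- default_template()
  beats <- lapply(c(50, 140), function(hr) {
    rec <- generate_record(hr, seed = 42)
    suppressWarnings(transform(rec, alignment_config(
      tpl, strategy = "hrc", output = "median_beat")))$aligned
  })
  for (lead in 1:12) {
    expect_gt(cor(beats[[1]][, lead], beats[[2]][, lead]), 0.99)
  }
})

test_that("transform is amplitude-linear given identical detected peaks", {
  tpl <- default_template()
  rec <- noisy_record(66, 15, seed = 9)
  cfg <- alignment_config(tpl, output = "full_signal")
  r1 <- suppressWarnings(transform(rec, cfg))
  sc <- ecg_record(rec$signal * 3.7, rec$fs)
  r2 <- suppressWarnings(transform(sc, cfg))
  expect_identical(r1$rpeaks_detected$indices, r2$rpeaks_detected$indices)
  expect_equal(r2$aligned, 3.7 * r1$aligned, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("median_beat is the pointwise median with midpoint convention", {
  b <- matrix(rnorm(40), ncol = 2)
  expect_equal(median_beat(list(b, b, b)), b, ignore_attr = TRUE)

  z <- matrix(0, 4, 1); o <- matrix(1, 4, 1)
  expect_equal(median_beat(list(z, z, o)), z, ignore_attr = TRUE)
  # even count: midpoint convention
  expect_equal(median_beat(list(z, o))[1, 1], 0.5)

  # one outlier cycle at 10x amplitude leaves the median at the clean value
  expect_equal(median_beat(list(b, b, 10 * b)), b, ignore_attr = TRUE)

  # brute-force per-sample oracle
  set.seed(31)
  cycles <- lapply(1:5, function(i) matrix(rnorm(30), ncol = 3))
  got <- median_beat(cycles)
  for (i in 1:10) for (j in 1:3) {
    expect_equal(got[i, j],
                 median(vapply(cycles, function(c) c[i, j], numeric(1))))
  }

  expect_error(median_beat(list(z, matrix(0, 5, 1))), "ragged")
  expect_error(median_beat(list()), "at least one")
})

test_that("beat_list output returns processed or raw cycles on demand", {
  tpl <- default_template()
  rec <- generate_record(72, rr_jitter_frac = 0.04, seed = 12)
  proc <- suppressWarnings(transform(rec, alignment_config(
    tpl, output = "beat_list")))
  lens <- vapply(proc$aligned, nrow, integer(1))
  expect_true(all(lens == proc$beat_len))

  raw <- suppressWarnings(transform(rec, alignment_config(
    tpl, output = "beat_list", beat_list_processed = FALSE)))
  raw_lens <- vapply(raw$aligned, nrow, integer(1))
  expect_equal(raw_lens,
               diff(raw$rpeaks_detected$indices))
  expect_gt(length(unique(raw_lens)), 1)  # jitter makes raw cycles ragged
})

test_that("batch alignment is order-preserving, fault-tolerant, and worker-invariant", {
  tpl <- default_template()
  cfg <- alignment_config(tpl, output = "median_beat")
  expect_equal(transform_batch(list(), cfg)$results, list())

  records <- lapply(1:8, function(i) generate_record(50 + 10 * i, seed = i))
  b1 <- transform_batch(records, cfg, n_workers = 1)
  b4 <- transform_batch(records, cfg, n_workers = 4)
  expect_identical(serialize(b1, NULL), serialize(b4, NULL))
  expect_length(b1$failures, 0)

  bad <- records[1:3]
  bad[[2]] <- ecg_record(matrix(0, 5000, 12), 500)  # flat line
  lenient <- transform_batch(bad, cfg)
  expect_null(lenient$results[[2]])
  expect_false(is.null(lenient$results[[1]]))
  expect_false(is.null(lenient$results[[3]]))
  expect_named(lenient$failures, "2")
  expect_error(transform_batch(bad, cfg, strict = TRUE), "2")
})
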