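test_that("ddCtFoldChange reproduces the hand-worked calibrator arithmetic", {
  ct <- makeCtTable(list(calib = c(CSP1 = 25, actin = 20),
                         s1 = c(CSP1 = 22, actin = 20)))
  res <- ddCtFoldChange(ct, "CSP1", "actin", "calib")

  # calibrator fold change is exactly 1
  expect_identical(res$fold_change[res$sample_id == "calib"], 1)
  # ddCt = (22-20) - (25-20) = -3 -> fold 8
  expect_identical(res$delta_delta_ct[res$sample_id == "s1"], -3)
  expect_identical(res$fold_change[res$sample_id == "s1"], 8)

  # one cycle below the calibrator dCt is one doubling
  ct2 <- makeCtTable(list(calib = c(CSP1 = 25, actin = 20),
                          s1 = c(CSP1 = 24, actin = 20)))
  expect_equal(ddCtFoldChange(ct2, "CSP1", "actin",
                              "calib")$fold_change[2L], 2)
})

test_that("ddCtFoldChange errors name the missing sample/gene and calibrator", {
  ct <- makeCtTable(list(calib = c(CSP1 = 25, actin = 20),
                         s1 = c(CSP1 = 22)))
  expect_error(ddCtFoldChange(ct, "CSP1", "actin", "calib"),
               "'actin' in sample 's1'")
  expect_error(ddCtFoldChange(ct, "CSP1", "actin", "nope"),
               "calibrator sample 'nope'")
  expect_error(ddCtFoldChange(ct[, -4], "CSP1", "actin", "calib"),
               "missing column")
})

test_that("fold changes are invariant to a constant Ct shift of one sample", {
  ct <- simulateCtTable(foldChanges = c(ctl = 1, a = 4, b = 0.5),
                        noiseSd = 0.2, seed = 8)
  res <- ddCtFoldChange(ct, "CSP1", "actin", "ctl")
  shifted <- ct
  shifted$ct[shifted$sample_id == "a"] <- shifted$ct[shifted$sample_id == "a"] + 3.7
  res2 <- ddCtFoldChange(shifted, "CSP1", "actin", "ctl")
  expect_equal(res2$fold_change, res$fold_change)
})

test_that("simulated Ct tables recover the generating fold changes", {
  # exact at zero noise
  ct <- simulateCtTable(foldChanges = c(ctl = 1, up = 8, down = 0.25),
                        noiseSd = 0, seed = 4)
  res <- ddCtFoldChange(ct, "CSP1", "actin", "ctl")
  expect_equal(res$fold_change[match(c("ctl", "up", "down"), res$sample_id)],
               c(1, 8, 0.25))

  # fold 1 everywhere stays 1
  ct1 <- simulateCtTable(foldChanges = c(a = 1, b = 1, c = 1), noiseSd = 0)
  expect_equal(ddCtFoldChange(ct1, "CSP1", "actin", "a")$fold_change,
               rep(1, 3))

  # within 10% (median over seeds) at 0.2-cycle noise, 3 replicates
  err <- vapply(1:40, function(i) {
    ct <- simulateCtTable(foldChanges = c(ctl = 1, tr = 10), noiseSd = 0.2,
                          nReplicates = 3, seed = 500 + i)
    f <- ddCtFoldChange(ct, "CSP1", "actin", "ctl")
    abs(f$fold_change[f$sample_id == "tr"] - 10) / 10
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("replicate sd is propagated through the exponential", {
  ct <- rbind(
    makeCtTable(list(calib = c(CSP1 = 25, actin = 20))),
    data.frame(sample_id = "s1", gene_id = c("CSP1", "CSP1", "actin"),
               replicate = c(1L, 2L, 1L), ct = c(21.8, 22.2, 20),
               stringsAsFactors = FALSE))
  res <- ddCtFoldChange(ct, "CSP1", "actin", "calib")
  r <- res[res$sample_id == "s1", ]
  s <- sd(c(21.8, 22.2))  # reference has a single replicate, sd 0
  expect_equal(r$fold_lo, 2^-(r$delta_delta_ct + s))
  expect_equal(r$fold_hi, 2^-(r$delta_delta_ct - s))
  expect_gt(r$fold_hi, r$fold_change)
  expect_lt(r$fold_lo, r$fold_change)
})

test_that("summarizeReplicates computes per-group mean, sd and n", {
  res <- data.frame(fold_change = c(2, 2, 2, 1, 2, 3),
                    dose = c("low", "low", "low", "high", "high", "high"))
  summ <- summarizeReplicates(res, "dose")
  expect_equal(summ$mean[summ$dose == "low"], 2)
  expect_equal(summ$sd[summ$dose == "low"], 0)
  expect_equal(summ$mean[summ$dose == "high"], 2)
  expect_equal(summ$sd[summ$dose == "high"], 1)
  expect_identical(summ$n, c(3L, 3L))

  # empty input -> empty table
  empty <- summarizeReplicates(res[0, ], "dose")
  expect_identical(nrow(empty), 0L)

  # empty factor level is dropped with a warning
  res$dose <- factor(res$dose, levels = c("low", "high", "none"))
  expect_warning(summarizeReplicates(res, "dose"), "none")
})
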