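mk_tab <- function(m, groups) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  lfq_table(m, groups)
}

g33 <- c(b1 = "bait", b2 = "bait", b3 = "bait",
         c1 = "control", c2 = "control", c3 = "control")

test_that("valid-value filter keeps rows with enough bait measurements", {
  m <- 2^matrix(c(NA, NA, NA, 20, 21, 22,
                  25, NA, NA, 20, 21, 22,
                  25, 26, 27, 20, 21, 22), 3, byrow = TRUE,
                dimnames = list(c("allmiss", "one", "full"),
                                names(g33)))
  expect_message(f <- filter_valid(mk_tab(m, g33), "bait"), "removed 1/3")
  expect_setequal(rownames(f$intensities), c("one", "full"))
  expect_identical(attr(f, "removed"), "allmiss")
  # a single valid bait value is retained at the default threshold
  expect_true("one" %in% rownames(f$intensities))
  # degenerate: min_valid above group size empties the table
  expect_warning(
    expect_message(f0 <- filter_valid(mk_tab(m, g33), "bait", min_valid = 4)),
    "exceeds")
  expect_equal(nrow(f0$intensities), 0)
})

test_that("log2 transform maps values elementwise and rejects non-positives", {
  m <- matrix(c(1024, NA, 1, 8, 2, 4), 1,
              dimnames = list("P1", names(g33)))
  lt <- log2_transform(mk_tab(m, g33))
  expect_equal(unname(lt$intensities[1, ]), c(10, NA, 0, 3, 1, 2))
  m2 <- m; m2[1, 4] <- 0
  expect_error(log2_transform(mk_tab(m2, g33)), "P1.*c1")
})

test_that("imputation draws from the downshifted normal, column-wise, seeded", {
  set.seed(5)
  n <- 4000
  obs <- rnorm(n, 25, 2)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 25  # exact sample moments
  m <- cbind(b1 = obs, b2 = obs, b3 = obs, c1 = obs, c2 = obs, c3 = obs)
  rownames(m) <- sprintf("P%04d", seq_len(n))
  miss <- seq_len(2000)
  m[miss, "b1"] <- NA
  tab <- mk_tab(2^m, g33)
  tl <- log2_transform(tab)
  ti <- impute(tl, impute_params(seed = 11))
  imp <- ti$intensities[miss, "b1"]
  mu <- mean(obs[-miss]); s <- sd(obs[-miss])
  expect_equal(mean(imp), mu - 1.8 * s, tolerance = 0.05 / 21)
  expect_equal(sd(imp), 0.3 * s, tolerance = 0.02 / 0.6)
  # observed cells untouched; same seed reproduces; no missing left
  expect_identical(ti$intensities[-miss, ], tl$intensities[-miss, ])
  expect_identical(impute(tl, impute_params(seed = 11)), ti)
  expect_false(anyNA(ti$intensities))
  # imputed values sit below the observed column (downshift > 0)
  expect_lt(median(imp), mu)

  # column-order independence: permuting samples gives the same cell values
  perm <- c("c3", "b1", "c1", "b2", "b3", "c2")
  tp <- impute(log2_transform(mk_tab(2^m[, perm], g33[perm])),
               impute_params(seed = 11))
  expect_equal(tp$intensities[miss, "b1"], imp)

  # a complete table passes through unchanged
  full <- mk_tab(2^m[3001:3100, ], g33)
  expect_identical(impute(log2_transform(full)), log2_transform(full))

  # too few observed values in a column is an error
  m3 <- m[1:5, ]; m3[1:3, "b1"] <- NA; m3[4:5, "b1"] <- c(24, NA)
  expect_error(impute(log2_transform(mk_tab(2^m3, g33))), "b1")
})

test_that("t-test difference and p match the worked example and the t oracle", {
  m <- matrix(rep(c(25, 26, 27, 20, 21, 22), 2), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), names(g33)))
  m[2, ] <- c(23, 23, 23, 23, 23, 23)  # identical groups
  tab <- mk_tab(2^m, g33)
  res <- ttest_vs_control(log2_transform(tab), "bait")
  expect_equal(res$t_test_difference[1], 5.0)
  # independent closed-form oracle for the p-value, df = 4
  t_exp <- 5 / sqrt(1 * (2 / 3))
  expect_equal(res$p_value[1], oracle_t_p(t_exp, 4), tolerance = 1e-12)
  # and against stats::t.test as a second, independent implementation
  tt <- t.test(c(25, 26, 27), c(20, 21, 22), var.equal = TRUE)
  expect_equal(res$p_value[1], tt$p.value, tolerance = 1e-12)
  # identical groups: difference 0, p = 1 (degenerate zero variance)
  expect_equal(res$t_test_difference[2], 0)
  expect_equal(res$p_value[2], 1)
  # duplicate bait design: 2 bait vs 3 control runs on df = 3
  g23 <- g33[-1]
  res23 <- ttest_vs_control(log2_transform(mk_tab(2^m[, -1], g23)), "bait")
  tt23 <- t.test(c(26, 27), c(20, 21, 22), var.equal = TRUE)
  expect_equal(res23$p_value[1], tt23$p.value, tolerance = 1e-12)
  # zero variance with nonzero difference is flagged, not silently scored
  m2 <- m; m2[2, ] <- c(25, 25, 25, 20, 20, 20)
  expect_warning(res2 <- ttest_vs_control(log2_transform(mk_tab(2^m2, g33)),
                                          "bait"), "degenerate")
  expect_true(res2$degenerate[2] && is.na(res2$p_value[2]))
})

test_that("increment binning uses half-open intervals above a floor", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    t_test_difference = c(3, 0.5, 2, 7))
  b <- bin_increments(res, edges = c(1, 2, 4, 6))
  expect_equal(b$increment, c(2L, 0L, 2L, 4L))
  expect_equal(as.character(b$increment_label),
               c("[2,4)", "not enriched", "[2,4)", ">=6"))
  expect_error(bin_increments(res, edges = c(1, 1, 2)), "increasing")
})

test_that("component mapping joins by id or synonym and reports gaps", {
  res <- data.frame(id = c("Tb927.11.14340", "XPO1_alt", "Tb927.7.970",
                           "Tb927.0.0001"),
                    t_test_difference = c(5, 1, 3, 2),
                    p_value = c(1e-6, 0.2, 1e-4, 0.01))
  res <- bin_increments(res)
  comp <- map_components(res)
  expect_equal(comp$name[comp$id == "Tb927.11.14340"], "exportin 1")
  expect_equal(comp$status[comp$name == "exportin 1"], "quantified")
  expect_equal(comp$status[comp$name == "NMD3"], "quantified")
  # a component with no matching result is undetected
  expect_equal(comp$status[comp$name == "NUP158"], "undetected")
  expect_true(is.na(comp$t_test_difference[comp$name == "NUP158"]))
  # a result matching no component is appended as unassigned
  expect_equal(comp$status[comp$id == "Tb927.0.0001"], "unassigned")
  # synonyms resolve (XPO1 is listed for exportin 1 but already matched)
  expect_false("XPO1_alt" %in% comp$id[comp$status == "quantified"])
})

test_that("true effects are recovered and the null type-I rate is nominal", {
  sp <- lfq_sim_spec(n_proteins = 450,
                     true_effect = rep(c(0, 2, 5), each = 150), seed = 19)
  sim <- simulate_lfq_table(sp)
  expect_lt(mean(is.na(sim$table$intensities)), 0.30)
  fit <- suppressMessages(
    lfq_enrich(sim$table, "bait", components = NULL, seed = 19))
  eff <- sim$true_effect[match(fit$results$id,
                               rownames(sim$table$intensities))]
  for (e in c(0, 2, 5)) {
    bias <- mean(fit$results$t_test_difference[eff == e]) - e
    expect_lt(abs(bias), 0.3)
  }
  sp0 <- lfq_sim_spec(n_proteins = 2000, true_effect = 0,
                      dropout_midpoint = -Inf, seed = 20)
  fit0 <- suppressMessages(
    lfq_enrich(simulate_lfq_table(sp0)$table, "bait",
               components = NULL, seed = 20))
  expect_equal(mean(fit0$results$p_value < 0.05), 0.05, tolerance = 0.02 / 0.05)
})

test_that("the pipeline is deterministic end to end, byte for byte", {
  sp <- lfq_sim_spec(n_proteins = 120, true_effect = rep(c(0, 4), 60),
                     seed = 33)
  run <- function() {
    fit <- suppressMessages(
      lfq_enrich(simulate_lfq_table(sp)$table, "bait", seed = 33))
    f <- tempfile(fileext = ".tsv")
    write_enrichment_tsv(fit, f)
    on.exit(unlink(f))
    readBin(f, "raw", file.size(f))
  }
  expect_identical(run(), run())
})
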