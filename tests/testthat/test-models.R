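make_linear_table <- function(n_subj = 8, k = 6, a = 1, b = -0.1,
                              noise = 0, seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(n_subj), each = k)
  lev <- rep(seq_len(k), n_subj)
  intercepts <- rnorm(n_subj, 0, 0.2)
  data.frame(subject = factor(subj), level = lev,
             condition = paste0("c", lev),
             response = a + intercepts[subj] + b * lev +
               rnorm(n_subj * k, 0, noise))
}

test_that("noiseless linear data are recovered exactly; quadratic term vanishes", {
  tab <- make_linear_table(noise = 0, b = -0.07)
  lin <- suppressWarnings(fit_level_model(tab, "linear"))
  expect_equal(unname(lin$coefficients[".lc"]), -0.07, tolerance = 1e-6)
  quad <- suppressWarnings(fit_level_model(tab, "quadratic"))
  expect_lt(abs(quad$coefficients[["I(.lc^2)"]]), 1e-6)
})

test_that("fixed effects are invariant to permuting subject labels", {
  tab <- make_linear_table(noise = 0.1, seed = 2)
  f1 <- suppressWarnings(fit_level_model(tab, "linear"))
  perm <- sample(levels(tab$subject))
  tab2 <- tab
  tab2$subject <- factor(perm[as.integer(tab$subject)])
  f2 <- suppressWarnings(fit_level_model(tab2, "linear"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("likelihood-ratio test matches chi-squared reference points", {
  tab <- make_linear_table(noise = 0.1, seed = 3)
  lin <- suppressWarnings(fit_level_model(tab, "linear"))
  quad <- suppressWarnings(fit_level_model(tab, "quadratic"))
  lr <- lrt(lin, quad)
  expect_equal(lr$df, 1L)
  expect_equal(lr$chi2, 2 * (quad$logLik - lin$logLik), tolerance = 1e-10)
  # complex model never fits worse than its nested submodel
  expect_gte(quad$logLik, lin$logLik - 1e-6)
  # identical models: chi2 = 0, p = 1
  self <- lrt(lin, lin)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  # chi2 = 3.8415 at df 1 sits at p ~ 0.05
  expect_equal(stats::pchisq(3.8415, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-4)
})

test_that("nesting inequality holds across random datasets", {
  for (s in 1:10) {
    tab <- make_linear_table(noise = 0.3, seed = 100 + s)
    lin <- suppressWarnings(fit_level_model(tab, "linear"))
    quad <- suppressWarnings(fit_level_model(tab, "quadratic"))
    expect_gte(quad$logLik, lin$logLik - 1e-6)
  }
})

test_that("normalization by the clear condition behaves as documented", {
  tab <- data.frame(subject = rep(c("a", "b"), each = 6),
                    condition = rep(c("orig", paste0("voc", c(7, 5, 3, 2, 1))), 2),
                    tracking = c(2, 4, 6, 2, 2, 2, 1, 2, 3, 1, 1, 1),
                    activation = rep(c(2, 1), each = 6))
  out <- normalize_by_clear(tab, c("tracking", "activation"))
  expect_equal(nrow(out), 10L)  # 6 conditions in -> 5 vocoded rows out
  expect_false(any(out$condition == "orig"))
  # doubling a subject's raw scale leaves normalized values unchanged:
  # subject a is subject b scaled by 2 -> identical normalized profiles
  expect_equal(out$tracking_norm[out$subject == "a"],
               out$tracking_norm[out$subject == "b"])
  expect_true(all(out$activation_norm == 1))

  # measure equal to the clear value everywhere -> all ones
  tab$tracking <- 5
  out2 <- normalize_by_clear(tab, "tracking")
  expect_true(all(out2$tracking_norm == 1))

  # zero clear value -> subject excluded with a warning
  tab$tracking[tab$subject == "a" & tab$condition == "orig"] <- 0
  expect_warning(out3 <- normalize_by_clear(tab, "tracking"), "zero")
  expect_false("a" %in% out3$subject)
})

test_that("intelligibility models flag nonpositive activation and rank mechanisms", {
  cfg <- sim_config(n_subjects = 14, seed = 31)
  tab <- gen_intelligibility_table(cfg, "ratio")
  tab$activation_norm[1] <- -0.2
  expect_warning(im <- intelligibility_models(tab), "activation")
  expect_named(im$fits, c("null", "combined", "tracking", "activation"))
  expect_equal(nrow(im$comparison), 3L)
  # behavior generated from T/A: combined model explains it best
  expect_gt(im$comparison$logLik[im$comparison$model == "combined"],
            max(im$comparison$logLik[im$comparison$model != "combined"]))
  expect_lt(im$comparison$p_vs_null[im$comparison$model == "combined"], 0.05)
})
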