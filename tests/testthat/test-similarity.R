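test_that("cosine-squared similarity has its defining properties", {
  x <- c(1, 2, 3)
  expect_equal(cos_squared(x, x), 1)
  expect_equal(cos_squared(c(1, 0), c(0, 1)), 0)
  expect_equal(cos_squared(c(1, 1), c(1, 0)), 0.5)
  expect_error(cos_squared(c(0, 0), c(1, 1)), class = "plasmapls_error")
  expect_error(cos_squared(1:3, 1:4), class = "plasmapls_error")

  # property sweep: bounds, symmetry, scale invariance
  withr::with_seed(1, {
    for (i in 1:500) {
      a <- rnorm(8); b <- rnorm(8)
      v <- cos_squared(a, b)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, cos_squared(b, a))
      expect_equal(v, cos_squared(-2.5 * a, 0.3 * b))
    }
  })
})

test_that("similarity profiles respect masks and self-reference", {
  cfg <- small_config(seed = 2)
  pc <- preprocess_spectra(simulate_dataset(cfg)$calibration)
  axis <- wavenumbers(pc)
  ref <- drop(spectra_matrix(pc)[1, ])

  prof <- similarity_profile(pc, ref)
  expect_equal(prof$cos2[1], 1)       # a spectrum matches itself perfectly
  expect_true(all(prof$cos2 >= 0 & prof$cos2 <= 1))
  expect_equal(prof$mask[1], "full")

  # mask partition: selected and excluded cover the axis disjointly
  sel <- axis[axis <= 1700 & axis >= 1500]
  exc <- setdiff(axis, sel)
  expect_length(intersect(sel, exc), 0)
  expect_setequal(c(sel, exc), axis)
  p_sel <- similarity_profile(pc, ref, mask = sel, mask_label = "ga_selected")
  expect_equal(unique(p_sel$mask), "ga_selected")

  # mismatched reference is rejected
  expect_error(similarity_profile(pc, ref[-1]), class = "plasmapls_error")
  expect_error(similarity_profile(pc, ref, mask = c(123.4)),
               class = "plasmapls_error")
})

test_that("signal-region masks show a stronger similarity trend than noise regions", {
  # planted-signal spectra: a signal region driven by the mixing fraction
  # plus a pure-noise region, masks set to the planted regions
  withr::with_seed(3, {
    axis <- seq(1800, 900, length.out = 120)
    tt <- rep(seq(0, 48, 6), each = 4)
    alpha <- 0.7 * (1 - exp(-tt / 12))
    sig_idx <- 21:60
    band_a <- exp(-0.5 * ((axis - 1650) / 25)^2)
    band_b <- exp(-0.5 * ((axis - 1540) / 20)^2)
    X <- matrix(rnorm(length(tt) * length(axis), 0, 0.02),
                length(tt), length(axis))
    for (i in seq_along(tt)) {
      X[i, sig_idx] <- X[i, sig_idx] +
        (1 - alpha[i]) * band_a[sig_idx] + alpha[i] * band_b[sig_idx]
    }
    ds <- new_spectra(X, axis, sprintf("s%02d", seq_along(tt)), tt)
    ref <- band_b
  })
  p_sig <- similarity_profile(ds, ref, mask = axis[sig_idx])
  p_noise <- similarity_profile(ds, ref, mask = axis[-sig_idx])
  range_of <- function(p) {
    m <- tapply(p$cos2, p$pmi_h, mean)
    diff(range(m))
  }
  expect_gt(range_of(p_sig), range_of(p_noise))
})

test_that("one-way ANOVA matches the classical references", {
  withr::with_seed(4, {
    d <- data.frame(value = rnorm(30), group = rep(letters[1:3], each = 10))
  })
  an <- one_way_anova(d, value, group)
  ref <- anova(lm(value ~ group, data = d))   # independent route
  expect_equal(an$f, ref$`F value`[1])
  expect_equal(an$p, ref$`Pr(>F)`[1])
  expect_equal(c(an$df1, an$df2), ref$Df)

  # two groups: F equals the squared pooled t statistic
  d2 <- d[d$group != "c", ]
  an2 <- one_way_anova(d2, value, group)
  tt <- t.test(value ~ group, data = d2, var.equal = TRUE)
  expect_equal(an2$f, unname(tt$statistic)^2)
  expect_equal(an2$p, tt$p.value)

  # invariance under a global affine transform of the data
  d3 <- transform(d, value = 3.2 * value - 40)
  expect_equal(one_way_anova(d3, value, group)$f, an$f)

  # degenerate inputs are rejected explicitly
  dd <- data.frame(value = rep(1, 12), group = rep(1:3, each = 4))
  expect_error(one_way_anova(dd, value, group), "undefined",
               class = "plasmapls_error")
  expect_error(one_way_anova(data.frame(value = 1:3, group = c(1, 2, 2)),
                             value, group),
               class = "plasmapls_error")
})

test_that("post hoc switches between LSD and Tamhane by Levene's test", {
  withr::with_seed(5, {
    homo <- data.frame(value = rnorm(24),
                       group = rep(letters[1:3], each = 8))
    hetero <- data.frame(value = c(rnorm(8, sd = 1), rnorm(8, sd = 1),
                                   rnorm(8, sd = 5)),
                         group = rep(letters[1:3], each = 8))
  })
  ph_homo <- posthoc_pairwise(one_way_anova(homo, value, group))
  expect_equal(unique(ph_homo$method), "LSD")
  ph_het <- posthoc_pairwise(one_way_anova(hetero, value, group))
  expect_equal(unique(ph_het$method), "Tamhane-T2")

  # two identical groups: pairwise p ~ 1
  same <- data.frame(value = rep(c(1, 2, 3, 4), 2),
                     group = rep(c("a", "b"), each = 4))
  ph <- posthoc_pairwise(one_way_anova(same, value, group))
  expect_gte(ph$p[1], 0.99)
})

test_that("LSD p-values match pairwise pooled t tests", {
  withr::with_seed(6, {
    d <- data.frame(value = rnorm(30, mean = rep(c(0, 1, 2), each = 10)),
                    group = rep(letters[1:3], each = 10))
  })
  an <- one_way_anova(d, value, group)
  expect_gte(an$levene_p, 0.05)   # this seed is homoscedastic: LSD branch
  ph <- posthoc_pairwise(an)
  ref <- pairwise.t.test(d$value, d$group, p.adjust.method = "none",
                         pool.sd = TRUE)
  expect_equal(ph$p[ph$group1 == "a" & ph$group2 == "b"], ref$p.value["b", "a"])
  expect_equal(ph$p[ph$group1 == "b" & ph$group2 == "c"], ref$p.value["c", "b"])
})

test_that("A414 trend flags groups against the 0-h baseline", {
  trend <- a414_trend(simulate_a414(synth_config()))
  g <- trend$groups
  expect_equal(g$pmi_h, seq(0, 48, 6))
  expect_false(g$different_from_0h[g$pmi_h == 0])
  expect_true(all(g$different_from_0h[g$pmi_h >= 6]))

  # noiseless means reproduce the generator's A(t) exactly (zero-variance
  # groups cannot be ANOVA'd, so the means are checked on the table itself)
  quiet <- synth_config(a414_params = list(a0 = 0.05, gain = 1.2,
                                           late_dip = 0.03, noise_sd = 0))
  tbl <- simulate_a414(quiet)
  t_pts <- sort(unique(tbl$pmi_h))
  expect_equal(as.numeric(tapply(tbl$a414, tbl$pmi_h, mean)[as.character(t_pts)]),
               0.05 + 1.2 * mixing_fraction(t_pts, quiet) -
                 0.03 * pmax(0, t_pts - 42) / 6)

  # a 0-h baseline is required
  no0 <- simulate_a414(synth_config())
  expect_error(a414_trend(no0[no0$pmi_h > 0, ]), class = "plasmapls_error")
})

test_that("A414 flags are calibrated under the null (gain = 0)", {
  rates <- vapply(1:60, function(seed) {
    cfg <- synth_config(a414_params = list(a0 = 0.5, gain = 0, late_dip = 0,
                                           noise_sd = 0.02), seed = seed)
    g <- a414_trend(simulate_a414(cfg))$groups
    mean(g$different_from_0h[g$pmi_h > 0])
  }, numeric(1))
  expect_gt(mean(rates), 0.005)
  expect_lt(mean(rates), 0.12)
})
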