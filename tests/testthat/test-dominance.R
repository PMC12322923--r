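test_that("pattern classification counts strictly positive fractions", {
  five <- supply_record(c(pericallosa = 0.2, callosomarginalis = 0.2,
                          precentral = 0.2, central = 0.2,
                          postcentral = 0.2))
  expect_identical(classify_pattern(five)$count, 5L)

  three <- supply_record(c(pericallosa = 0.4, precentral = 0.35,
                           central = 0.25))
  p3 <- classify_pattern(three)
  expect_identical(p3$count, 3L)
  expect_identical(p3$composition, c("pericallosa", "precentral", "central"))

  sole <- supply_record(c(pericallosa = 1))
  expect_identical(classify_pattern(sole)$count, 1L)
  expect_error(classify_pattern(supply_record(numeric(0))), "zero")
})

test_that("pattern classification is invariant to absolute ROI size", {
  f <- c(pericallosa = 0.4, precentral = 0.35, central = 0.25)
  small <- supply_record(f, roi_voxels = 100L)
  large <- supply_record(f, roi_voxels = 100000L)
  expect_identical(classify_pattern(small)$composition,
                   classify_pattern(large)$composition)
})

test_that("dominance ratios hit the anchor values 1.0, 0.5, 0.0", {
  sole_peri <- supply_record(c(pericallosa = 0.4, precentral = 0.35,
                               central = 0.25))
  expect_identical(dominance_ratios(sole_peri)[["peri_callosomarginalis"]], 1)

  equal_aca <- supply_record(c(pericallosa = 0.2, callosomarginalis = 0.2,
                               precentral = 0.3, central = 0.3))
  expect_identical(dominance_ratios(equal_aca)[["peri_callosomarginalis"]],
                   0.5)

  no_peri <- supply_record(c(callosomarginalis = 0.4, precentral = 0.3,
                             central = 0.3))
  expect_identical(dominance_ratios(no_peri)[["peri_callosomarginalis"]], 0)
})

test_that("ratio definitions and undefined denominators", {
  f <- supply_record(c(pericallosa = 0.1, callosomarginalis = 0.3,
                       precentral = 0.2, central = 0.3, postcentral = 0.1))
  r <- dominance_ratios(f)
  expect_equal(r[["aca_mca"]], 0.4)
  expect_equal(r[["peri_callosomarginalis"]], 0.25)
  expect_equal(r[["central_precentral"]], 0.6)
  expect_equal(r[["postcentral_mca"]], 0.1 / 0.6)

  mca_only <- supply_record(c(precentral = 0.5, central = 0.5))
  expect_true(is.na(dominance_ratios(mca_only)[["peri_callosomarginalis"]]))

  # complementarity: ratio + counterpart ratio = 1 whenever defined
  expect_equal(r[["peri_callosomarginalis"]] +
                 f[["callosomarginalis"]] /
                 (f[["pericallosa"]] + f[["callosomarginalis"]]), 1)
})

test_that("dominance rating uses a closed equal-contribution interval", {
  expect_identical(as.character(rate_dominance(0.5, 0.33, 0.66)), "equal")
  expect_identical(as.character(rate_dominance(1, 0.33, 0.66)),
                   "numerator-dominant")
  expect_identical(as.character(rate_dominance(0, 0.33, 0.66)),
                   "denominator-dominant")
  # boundary values count as equal contribution
  expect_identical(as.character(rate_dominance(c(0.33, 0.66), 0.33, 0.66)),
                   c("equal", "equal"))
  expect_identical(as.character(rate_dominance(NA)), "undefined")
  expect_error(rate_dominance(1.2), "\\[0, 1\\]")
  expect_error(rate_dominance(0.5, 0.7, 0.6), "thresholds")
})

test_that("rating is monotone in the ratio with transitions only at thresholds", {
  ratios <- seq(0, 1, by = 0.01)
  r <- rate_dominance(ratios, 0.33, 0.66)
  num_order <- c("denominator-dominant" = 1, "equal" = 2,
                 "numerator-dominant" = 3)[as.character(r)]
  expect_true(all(diff(num_order) >= 0))
  changes <- ratios[which(diff(num_order) != 0) + 1]
  expect_true(all((changes >= 0.33 & changes <= 0.34) |
                    (changes > 0.66 & changes <= 0.67)))
})

test_that("sweep grid matches its published anchors", {
  grid <- build_sweep_grid()
  expect_identical(nrow(grid), 100L)
  expect_equal(grid$lower[1], 0.05)
  expect_equal(grid$upper[1], 0.95)
  expect_equal(grid$lower[100], 0.45)
  expect_equal(grid$upper[100], 0.55)
  expect_equal(grid$upper, 1 - grid$lower)
  expect_error(build_sweep_grid(low = 0.3, high = 0.6), "bounds")
  expect_error(build_sweep_grid(n = 1), "n must be")
})

test_that("sweep agreement scores against a reference and self-agrees at 1", {
  set.seed(21)
  ratios <- runif(38)
  grid <- build_sweep_grid(n = 25)
  # reference = the frequencies a chosen pair itself produces -> agreement 1
  probe <- rate_dominance(ratios, grid$lower[10], grid$upper[10])
  ref <- prop.table(table(factor(probe,
    levels = c("numerator-dominant", "equal", "denominator-dominant"))))
  sw <- sweep_agreement(ratios, grid, setNames(as.numeric(ref), names(ref)))
  expect_equal(sw$agreement[10], 1)
  expect_true(all(sw$agreement <= 1 + 1e-12))
  expect_equal(rowSums(sw$counts), rep(38, 25), ignore_attr = TRUE)

  # per-pair tables equal an independent re-rating
  for (i in c(1, 13, 25)) {
    rr <- cut(ratios, c(-Inf, grid$lower[i] - 1e-15, grid$upper[i], Inf),
              labels = c("denominator-dominant", "equal",
                         "numerator-dominant"))
    expect_equal(unname(sw$counts[i, ]),
                 as.integer(table(rr)[c("numerator-dominant", "equal",
                                        "denominator-dominant")]))
  }
})

test_that("all-equal ratios give agreement 1 with an all-equal reference", {
  sw <- sweep_agreement(rep(0.5, 10), build_sweep_grid(n = 10),
                        c(equal = 1))
  expect_true(all(sw$agreement == 1))
  expect_error(sweep_agreement(numeric(0), build_sweep_grid(), c(equal = 1)),
               "no ratios")
  expect_error(sweep_agreement(0.5, build_sweep_grid(), c(equal = 0.5)),
               "sum to 1")
})

test_that("undefined ratios are excluded from sweep frequencies but counted", {
  sw <- sweep_agreement(c(0.5, NA, 0.9, NA), build_sweep_grid(n = 5),
                        c(equal = 0.5, `numerator-dominant` = 0.5))
  expect_identical(sw$n_undefined, 2L)
  expect_identical(sw$n_rated, 2L)
  expect_equal(rowSums(sw$frequencies), rep(1, 5), ignore_attr = TRUE)
})

test_that("frequency tables report counts and one-decimal percentages", {
  pats <- c(rep(3L, 10), rep(4L, 19), rep(5L, 9))
  items <- lapply(pats, function(k) {
    comp <- names(vessel_labels())[seq_len(k)]
    structure(list(count = k, composition = comp), class = "vessel_pattern")
  })
  tab <- frequency_table(items)
  expect_equal(tab$count, c(10L, 19L, 9L))
  expect_equal(tab$percent, c(26.3, 50.0, 23.7))
  # permutation invariance
  tab2 <- frequency_table(items[sample(length(items))])
  expect_equal(tab, tab2)
  # single category
  expect_equal(frequency_table(items[1:3])$percent, 100)
  expect_error(frequency_table(list()), "no items")
  # dominance ratings
  r <- rate_dominance(c(0.1, 0.5, 0.5, 0.9))
  rt <- frequency_table(r)
  expect_equal(sum(rt$count), 4L)
})

test_that("inter-rater correlation matches the textbook Pearson formula", {
  expect_equal(interrater_correlation(1:5 / 10, 1:5 / 10)$r, 1)
  expect_equal(interrater_correlation(1:5, 11 - 2 * (1:5))$r, -1)
  set.seed(33)
  a <- runif(30); b <- 0.8 * a + rnorm(30, 0, 0.1)
  got <- interrater_correlation(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  t_stat <- r_direct * sqrt(28 / (1 - r_direct^2))
  expect_equal(got$p.value, 2 * pt(abs(t_stat), 28, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(interrater_correlation(rep(0.5, 5), 1:5), "variance")
  expect_error(interrater_correlation(1:2, 1:2), "at least 3")
})
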