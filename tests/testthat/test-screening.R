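make_summary <- function(cond_id, cf, tan, estar, n = 4) {
  do.call(rbind, lapply(seq_along(cond_id), function(i)
    data.frame(dose_uM = cond_id[i],
               cf_diff_uN = rep(cf[i], n),
               tan_delta = rep(tan[i], n),
               E_star_kPa = rep(estar[i], n))))
}

test_that("the three criteria evaluate against their thresholds", {
  aft <- make_summary(c(1, 2, 3), cf = c(3.5, 3.5, 0.5),
                      tan = c(0.39, 0.75, 0), estar = c(9, 9, 9))
  bef <- make_summary(c(1, 2, 3), cf = 0, tan = 0.5, estar = c(3.9, 2, 2))
  res <- evaluate_criteria(aft, criteria_config(), before = bef)
  expect_s3_class(res, "screening_result")
  # condition 1: all three pass (5.1 kPa increase, tan 0.39, diff 3.5)
  expect_true(res$pass_cf[1] && res$pass_tan[1] && res$pass_estar[1])
  # condition 2: loss factor 0.75 fails purity
  expect_false(res$pass_tan[2])
  # condition 3: elastic, no contraction: fails A whatever B says
  expect_false(res$pass_cf[3])
  expect_true(res$pass_tan[3])
  # missing pairing: criterion C not evaluable, not failed
  res2 <- evaluate_criteria(aft, criteria_config())
  expect_true(all(is.na(res2$pass_estar)))
})

test_that("one replicate above 0.4 demotes a condition under the all-replicates rule", {
  aft <- make_summary(1, cf = 5, tan = 0.3, estar = 9, n = 8)
  aft$tan_delta[5] <- 0.45
  res <- evaluate_criteria(aft, criteria_config())
  expect_false(res$pass_tan)
  expect_true(evaluate_criteria(aft,
    criteria_config(rule_tan = "majority"))$pass_tan)
})

test_that("the funnel reproduces the worked second-stage screen: 11 -> 9", {
  ref <- bioink_cf_survivors_reference()
  expect_equal(nrow(ref), 11)
  aft <- data.frame(alginate = ref$alginate, cacl2 = ref$cacl2,
                    diameter_um = ref$diameter_um,
                    cf_diff_uN = 5, tan_delta = ref$tan_delta,
                    E_star_kPa = 9)
  res <- evaluate_criteria(aft, criteria_config())
  fun <- screening_funnel(res)
  expect_equal(unname(fun$counts["after_cf"]), 11)
  expect_equal(unname(fun$counts["after_tan"]), 9)
  failed <- res[!res$pass_tan, ]
  expect_setequal(round(failed$mean_tan_delta, 3), c(0.75, 0.718))
  expect_setequal(paste(failed$alginate, failed$cacl2, failed$diameter_um),
                  c("0.8 0.5 300", "0.7 1 300"))
})

test_that("funnel counts never increase and the selected set ignores criterion order", {
  aft <- make_summary(1:6, cf = c(5, 5, 5, 1, 5, 5),
                      tan = c(0.2, 0.7, 0.2, 0.2, 0.3, 0.2),
                      estar = c(9, 9, 4, 9, 9, 9))
  bef <- make_summary(1:6, cf = 0, tan = 0.5, estar = rep(2, 6))
  res <- evaluate_criteria(aft, criteria_config(), before = bef)
  f1 <- screening_funnel(res, c("cf", "tan", "estar"))
  expect_true(all(diff(f1$counts) <= 0))
  for (ord in list(c("tan", "cf", "estar"), c("estar", "tan", "cf"))) {
    f2 <- screening_funnel(res, ord)
    expect_setequal(f2$selected, f1$selected)
  }
  # empty funnel when everything fails contraction
  res$pass_cf[] <- FALSE
  f0 <- screening_funnel(res)
  expect_equal(unname(f0$counts[-1]), c(0, 0, 0))
})

test_that("relaxing thresholds never shrinks survivor sets", {
  set.seed(31)
  aft <- make_summary(1:20, cf = runif(20, 0, 6), tan = runif(20, 0, 0.9),
                      estar = runif(20, 3, 12))
  bef <- make_summary(1:20, cf = 0, tan = 0.5, estar = rep(3, 20))
  strict <- criteria_config(tan_delta_max = 0.4,
                            cf_min_difference = 3e-6,
                            delta_Estar_min = 5e3)
  loose <- criteria_config(tan_delta_max = 0.6,
                           cf_min_difference = 2e-6,
                           delta_Estar_min = 3e3)
  s1 <- screening_funnel(evaluate_criteria(aft, strict, before = bef))
  s2 <- screening_funnel(evaluate_criteria(aft, loose, before = bef))
  expect_true(all(s1$selected %in% s2$selected))
})

test_that("dose threshold follows the monotone-prefix rule", {
  # reported outcomes after culture-period optimization: threshold 120 uM
  ref <- cocl2_reference_outcomes("optimized")
  dt <- dose_threshold(ref$dose_uM, ref$pass)
  expect_equal(dt$threshold, 120)
  expect_false(dt$non_monotone)
  # under the un-optimized schedule contraction fails above 80 uM
  ref0 <- cocl2_reference_outcomes("standard")
  expect_equal(dose_threshold(ref0$dose_uM, ref0$pass)$threshold, 80)
  # all pass: maximum dose
  expect_equal(dose_threshold(c(0, 50, 100), c(TRUE, TRUE, TRUE))$threshold,
               100)
  # non-monotone pattern flagged, prefix rule still applies
  dt2 <- dose_threshold(c(0, 20, 40), c(TRUE, FALSE, TRUE))
  expect_equal(dt2$threshold, 0)
  expect_true(dt2$non_monotone)
  # nothing passes
  expect_true(dose_threshold(c(0, 20), c(FALSE, FALSE))$below_minimum)
  # order-invariance
  o <- sample(nrow(ref))
  expect_equal(dose_threshold(ref$dose_uM[o], ref$pass[o])$threshold, 120)
})

test_that("sphere-forming conditions are excluded rather than failed", {
  g <- condition_grid("gelma12")
  pop <- generate_population(g, 2, seed = 5, stage = "cultured")
  s <- analyze_population(pop)
  res <- evaluate_criteria(s, criteria_config())
  expect_equal(nrow(res), 7)  # 12 minus the 5 sphere formers
  expect_false(any(res$combination %in% c(1, 2, 3, 5, 6)))
})
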