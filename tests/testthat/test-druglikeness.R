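test_that("Lipinski violations are counted per rule", {
  expect_equal(ro5_violations(data.frame(mwt = 400, hbd = 1, hba = 4, logp = 3.0)), 0L)
  # a large PPI inhibitor: only the size rule broken
  expect_equal(ro5_violations(data.frame(mwt = 813.43, hbd = 2, hba = 7, logp = 4.9)), 1L)
  expect_equal(ro5_violations(data.frame(mwt = 900, hbd = 6, hba = 12, logp = 7)), 4L)
  expect_equal(
    ro5_violations(data.frame(mwt = c(400, 900), hbd = c(1, 6), hba = c(4, 12), logp = c(3, 7))),
    c(0L, 4L)
  )
  expect_error(ro5_violations(data.frame(mwt = 400)), class = "ppidrugg_invalid")
})

test_that("Ro5-1 tolerates exactly one violation", {
  expect_true(is_druglike_ro5_minus_1(data.frame(mwt = 400, hbd = 1, hba = 4, logp = 3)))
  expect_true(is_druglike_ro5_minus_1(data.frame(mwt = 813, hbd = 2, hba = 7, logp = 4.9)))
  expect_false(is_druglike_ro5_minus_1(data.frame(mwt = 813, hbd = 2, hba = 7, logp = 6)))
})

test_that("QED matches an independent term-by-term desirability evaluation", {
  props <- data.frame(
    mwt = 450.5, hbd = 2, hba = 6, logp = 3.2, psa = 95.4,
    rotb = 7, arom_rings = 3, alerts = 1
  )
  # frozen values from an independent step-by-step computation of the
  # published ADS functions followed by the geometric mean
  expect_equal(qed_score(props), 0.5505124028, tolerance = 1e-8)
  expect_equal(qed_score(props, weights = "canonical"), 0.5370442768, tolerance = 1e-8)
  # term-by-term oracle via plogis instead of exp
  P <- qed_parameters()
  d_oracle <- sapply(seq_len(nrow(P)), function(k) {
    x <- props[[P$column[k]]]
    ads <- P$A[k] + P$B[k] * plogis((x - P$C[k] + P$D[k] / 2) / P$E[k]) *
      (1 - plogis((x - P$C[k] - P$D[k] / 2) / P$F[k]))
    ads / P$DMAX[k]
  })
  expect_equal(as.numeric(qed_desirabilities(props)), d_oracle, tolerance = 1e-10)
  expect_equal(qed_score(props), exp(mean(log(d_oracle))), tolerance = 1e-10)
})

test_that("QED is 1 at the desirability maxima and equals the geometric mean identity", {
  P <- qed_parameters()
  best <- lapply(seq_len(nrow(P)), function(k) {
    f <- function(x) {
      P$A[k] + P$B[k] / (1 + exp(-(x - P$C[k] + P$D[k] / 2) / P$E[k])) *
        (1 - 1 / (1 + exp(-(x - P$C[k] - P$D[k] / 2) / P$F[k])))
    }
    # the ADS peak sits near C; a tight bracket keeps optimize off the
    # flat tails
    optimize(f, c(P$C[k] - 15, P$C[k] + 15), maximum = TRUE)$maximum
  })
  props <- data.frame(
    mwt = best[[1]], logp = best[[2]], hba = best[[3]], hbd = best[[4]],
    psa = best[[5]], rotb = best[[6]], arom_rings = best[[7]], alerts = best[[8]]
  )
  expect_equal(qed_score(props), 1, tolerance = 1e-3)
  # all desirabilities equal c => unweighted QED equals c
  d <- qed_desirabilities(props)
  expect_equal(exp(mean(log(d))), prod(d)^(1 / 8), tolerance = 1e-10)
})

test_that("QED is monotone in each desirability and invariant to descriptor order", {
  lo <- data.frame(mwt = 800, hbd = 2, hba = 6, logp = 3.2, psa = 95, rotb = 7,
    arom_rings = 3, alerts = 1)
  hi <- lo
  hi$mwt <- 300 # strictly higher MW desirability, all else equal
  expect_gt(qed_score(hi), qed_score(lo))
  shuffled <- lo[, c("alerts", "psa", "mwt", "hba", "hbd", "logp", "arom_rings", "rotb")]
  expect_equal(qed_score(shuffled), qed_score(lo))
})

test_that("the Rule-of-Four profile uses strict inequalities", {
  expect_true(rule_of_four_profile(
    data.frame(mwt = 632, logp = 6.2, hba = 5, arom_rings = 5)
  )$rule_of_four)
  expect_false(rule_of_four_profile(
    data.frame(mwt = 353.8, logp = 2.7, hba = 3, arom_rings = 2)
  )$rule_of_four)
  expect_false(rule_of_four_profile(
    data.frame(mwt = 400, logp = 4, hba = 4, arom_rings = 4)
  )$rule_of_four)
})

test_that("audits report counts and one-decimal percentages", {
  tab <- make_property_table(8, c(6, 2, 0, 0, 0) / 8, seed = 3)
  audit <- audit_set(tab)
  expect_equal(audit$n, 8)
  expect_equal(audit$n_ro5, 6)
  expect_equal(audit$pct_ro5, 75.0)
  all_pass <- make_property_table(10, c(1, 0, 0, 0, 0), seed = 4)
  expect_equal(audit_set(all_pass)$pct_ro5, 100.0)
  expect_error(audit_set(all_pass[0, ]), class = "ppidrugg_invalid")
})

test_that("planted-violation audits match the generator manifest exactly", {
  tab <- make_property_table(60, c(0.3, 0.3, 0.2, 0.1, 0.1), seed = 11)
  manifest <- attr(tab, "manifest")
  expect_equal(ro5_violations(tab), manifest$planted_violations)
  audit <- audit_set(tab)
  expect_equal(audit$n_ro5, sum(manifest$planted_violations == 0))
  expect_equal(audit$n_ro5_minus_1, sum(manifest$planted_violations <= 1))
})

test_that("Ro5 passes are always a subset of Ro5-1 passes", {
  for (seed in 1:5) {
    tab <- make_property_table(40, c(0.2, 0.2, 0.2, 0.2, 0.2), seed = seed)
    rules <- druglikeness_rules(tab)
    expect_true(all(rules$pass_ro5_minus_1[rules$pass_ro5]))
    expect_true(all(rules$qed >= 0 & rules$qed <= 1))
    by <- rep(c("T1", "T2"), each = 20)
    audit <- audit_set(tab, by = by)
    expect_true(all(audit$pct_ro5 >= 0 & audit$pct_ro5 <= 100))
    expect_equal(audit$n_ro5, c(
      sum(rules$pass_ro5[1:20]), sum(rules$pass_ro5[21:40]), sum(rules$pass_ro5)
    ))
    expect_true(all(audit$n_ro5_minus_1 >= audit$n_ro5))
  }
})
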