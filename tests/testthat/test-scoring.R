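test_that("the feature scheme has the canonical category structure", {
  sch <- feature_scheme()
  expect_setequal(sch$consonant, c("b", "s", "d", "h", "k", "m", "n", "p",
                                   "sh", "t", "v", "z"))
  expect_equal(as.integer(sort(table(sch$voicing))), c(6L, 6L))
  expect_equal(as.integer(sort(table(sch$manner))), c(2L, 5L, 5L))
  expect_equal(as.integer(sort(table(sch$place))), c(3L, 4L, 5L))
})

test_that("confusion tabulation is linear and validates labels", {
  expect_equal(sum(tabulate_confusions(make_block_trials()[0, ])$cm[[1]]), 0)

  one_block <- make_block_trials()
  cm <- tabulate_confusions(one_block)$cm[[1]]
  expect_true(all(rowSums(cm) == 3))  # 12 CVs x 3 tokens

  doubled <- tabulate_confusions(dplyr::bind_rows(one_block, one_block))$cm[[1]]
  expect_equal(as.matrix(doubled), 2 * as.matrix(cm))

  bad <- one_block
  bad$response[5] <- "x"
  expect_error(tabulate_confusions(bad), "invalid response")

  vo_bad <- make_block_trials(modality = "VO", mask = "fabric")
  expect_error(tabulate_confusions(vo_bad), "visual-only")

  by_grp <- tabulate_confusions(
    dplyr::bind_rows(make_block_trials(mask = "none"),
                     make_block_trials(mask = "fabric")), by = "mask")
  expect_equal(nrow(by_grp), 2)
})

test_that("accuracy and feature transmission follow the feature table", {
  cons <- consonants()
  ident <- diag(36 / 12, 12)
  dimnames(ident) <- list(cons, cons)
  s <- score_confusion(ident)
  expect_equal(s$accuracy, 1)
  expect_equal(c(s$voicing, s$manner, s$place), c(1, 1, 1))

  # all /b/ answered /p/: voicing lost, manner and place kept
  bp <- matrix(0, 12, 12, dimnames = list(cons, cons))
  bp["b", "p"] <- 10
  s2 <- score_confusion(bp)
  expect_equal(s2$accuracy, 0)
  expect_equal(s2$voicing, 0)
  expect_equal(s2$manner, 1)
  expect_equal(s2$place, 1)

  # uniform responder: enumeration over all 144 target-response pairs
  unif <- matrix(1, 12, 12, dimnames = list(cons, cons))
  s3 <- score_confusion(unif)
  expect_equal(s3$accuracy, 1 / 12)
  expect_equal(s3$voicing, 0.5)
  expect_equal(s3$manner, 54 / 144)
  expect_equal(s3$place, 50 / 144)
  # independent oracle from the feature table itself
  sch <- feature_scheme()
  for (f in c("voicing", "manner", "place")) {
    expect_equal(s3[[f]], sum(outer(sch[[f]], sch[[f]], `==`)) / 144)
  }

  expect_error(score_confusion(matrix(0, 12, 12, dimnames = list(cons, cons))),
               "all zero")
})

test_that("feature transmission never falls below accuracy", {
  cons <- consonants()
  withr::with_seed(42, {
    for (i in 1:20) {
      cm <- matrix(rpois(144, 2), 12, 12, dimnames = list(cons, cons))
      if (sum(cm) == 0) next
      s <- score_confusion(cm)
      expect_gte(s$voicing, s$accuracy)
      expect_gte(s$manner, s$accuracy)
      expect_gte(s$place, s$accuracy)
    }
  })
})

test_that("the rationalized arcsine transform matches its closed form", {
  expect_equal(rau(18, 36), 50, tolerance = 1e-12)

  # direct evaluation of the two-term arcsine formula
  oracle <- function(x, n) {
    (146 / pi) * (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))) - 23
  }
  expect_equal(rau(0, 36), oracle(0, 36), tolerance = 1e-12)
  expect_lt(abs(rau(0, 36) - (-15.32)), 0.05)

  # symmetry to 100 and strict monotonicity
  for (n in c(10, 36, 72)) {
    x <- 0:n
    expect_lt(max(abs(rau(x, n) + rau(n - x, n) - 100)), 1e-9)
    expect_true(all(diff(rau(x, n)) > 0))
  }
  expect_error(rau(5, 0), "total")
  expect_error(rau(-1, 10), "total")
})

test_that("chance levels come from the squared category frequencies", {
  ch <- chance_levels()
  expect_equal(ch$accuracy, 1 / 12)
  expect_equal(ch$voicing, 0.5)
  expect_equal(ch$manner, 54 / 144)
  expect_equal(ch$place, 50 / 144)
})

test_that("score tables pool runs by counts and drop incomplete cells", {
  tr <- dplyr::bind_rows(
    make_block_trials(),
    dplyr::mutate(make_block_trials(), run = 2L)
  )
  sc <- score_trials(tr)
  expect_equal(sc$n_trials, 72)
  expect_equal(sc$proportion, 1)

  # pooled scoring equals trial-weighted pooling of per-run matrices
  tr2 <- tr
  tr2$response[tr2$run == 2] <- "m"  # run 2 all wrong except /m/ targets
  pooled <- score_trials(tr2, drop_incomplete = FALSE)
  cm1 <- tabulate_confusions(tr2[tr2$run == 1, ])$cm[[1]]
  cm2 <- tabulate_confusions(tr2[tr2$run == 2, ])$cm[[1]]
  s_pooled <- score_confusion(as.matrix(cm1) + as.matrix(cm2))
  expect_equal(pooled$proportion, s_pooled$accuracy)
  expect_equal(pooled$voicing, s_pooled$voicing)

  # incomplete condition dropped by default
  tr3 <- dplyr::bind_rows(tr, make_block_trials(mask = "fabric")[1:20, ])
  expect_equal(nrow(score_trials(tr3)), 1)
  expect_equal(nrow(score_trials(tr3, drop_incomplete = FALSE)), 2)
})

test_that("audiovisual benefit is the AV minus AO RAU difference", {
  sc <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    group = "CNH", mask = "none", snr_db = 0,
    modality = rep(c("AO", "AV"), 2),
    rau = c(60, 80, 55, 55)
  )
  b <- audiovisual_benefit(sc)
  expect_equal(b$benefit_rau[b$subject_id == "a"], 20)
  expect_equal(b$benefit_rau[b$subject_id == "b"], 0)

  # missing AV cell reported as NA, not dropped
  b2 <- audiovisual_benefit(sc[-2, ])
  expect_true(is.na(b2$benefit_rau[b2$subject_id == "a"]))

  expect_error(audiovisual_benefit(sc[sc$modality == "AO", ]),
               "lacks one of the modalities")
})

test_that("a listener with no extra visual channel shows ~zero AV benefit", {
  eff <- default_condition_effects()
  ao <- eff[eff$modality == "AO", ]
  av <- ao; av$modality <- "AV"  # AV identical to AO: no visual gain
  params <- listener_params(effects = dplyr::bind_rows(ao, av),
                            subject_sd = 0.2)
  des <- cohort_design(n_per_group = c(CNH = 8),
                       conditions = tibble::tibble(mask = "none",
                                                   modality = c("AO", "AV")))
  tr <- simulate_cohort(des, params, seed = 21)
  ben <- audiovisual_benefit(score_trials(tr))
  # per-subject benefit SD is ~8 RAU at 72 trials/cell; 3-sigma band on the mean
  expect_lt(abs(mean(ben$benefit_rau)), 3 * 8 / sqrt(nrow(ben)))
})
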