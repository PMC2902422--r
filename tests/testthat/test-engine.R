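test_that("prior adjustment scales affected causes and renormalizes", {
  prior <- c(a = 0.5, b = 0.3, c = 0.2)

  # all multipliers 1: identity
  prev <- va_prevalence(
    malaria = "low", hiv = "low",
    multiplier_low = 1, multiplier_high = 1,
    malaria_causes = "c", hiv_causes = "a"
  )
  expect_equal(va_adjust_prior(prior, prev), prior)

  # down-weighting cause c by 0.1: (0.5, 0.3, 0.02) renormalized
  prev <- va_prevalence(
    malaria = "low", hiv = "high",
    malaria_causes = "c", hiv_causes = "a"
  )
  expect_equal(
    va_adjust_prior(prior, prev),
    c(a = 0.5, b = 0.3, c = 0.02) / 0.82,
    tolerance = 1e-12
  )
  expect_equal(
    round(unname(va_adjust_prior(prior, prev)), 4),
    c(0.6098, 0.3659, 0.0244)
  )

  # low-malaria / high-HIV study setting on the default dictionary:
  # malaria down-weighted, HIV/AIDS unchanged relative to the rest
  adj <- va_adjust_prior(va_default_prior(), va_prevalence(malaria = "low", hiv = "high"))
  base <- va_default_prior()
  expect_lt(adj[["malaria"]] / adj[["hiv_aids"]],
            base[["malaria"]] / base[["hiv_aids"]])
  expect_equal(adj[["hiv_aids"]] / adj[["pneumonia_sepsis"]],
               base[["hiv_aids"]] / base[["pneumonia_sepsis"]])
  expect_equal(sum(adj), 1)

  expect_error(
    va_adjust_prior(prior, va_prevalence(malaria_causes = "nonexistent")),
    "nonexistent"
  )
})

test_that("complement likelihood is the prior-weighted off-cause average", {
  base <- toy_base()
  prior <- toy_prior()

  # direct-sum hand computation: (0.1*0.3 + 0.1*0.2) / 0.5
  expect_equal(
    va_complement_likelihood(base, prior, "i1", "a"), 0.1,
    tolerance = 1e-12
  )

  # two causes: P(I | !C1) = P(I | C2) exactly
  b2 <- base[, c("a", "b")]
  expect_equal(
    va_complement_likelihood(b2, c(a = 0.6, b = 0.4), "i2", "a"),
    b2["i2", "b"]
  )

  # constant indicator row: P(I | !Ck) = p for every k
  bc <- base
  bc["i1", ] <- 0.42
  for (ck in colnames(bc)) {
    expect_equal(va_complement_likelihood(bc, prior, "i1", ck), 0.42)
  }

  expect_error(
    va_complement_likelihood(base, c(a = 1 - 1e-15, b = 5e-16, c = 5e-16), "i1", "a"),
    "degenerate"
  )
})

test_that("posterior updating follows Bayes on reported indicators", {
  base <- toy_base()
  prior <- toy_prior()

  # no evidence: posterior = prior
  expect_equal(va_posterior(resp_with(base), base, prior), prior)

  # uninformative (constant-row) evidence: posterior = prior
  bc <- base
  bc["i1", ] <- 0.3
  expect_equal(
    va_posterior(resp_with(bc, yes = "i1"), bc, prior), prior,
    tolerance = 1e-12
  )

  # hand-computed single-indicator update
  expect_equal(
    va_posterior(resp_with(base, yes = "i1"), base, prior),
    c(a = 0.9, b = 0.06, c = 0.04),
    tolerance = 1e-12
  )

  # "no" responses do not update by default but do when enabled
  r <- resp_with(base, no = "i1")
  expect_equal(va_posterior(r, base, prior), prior)
  expect_equal(
    va_posterior(r, base, prior, update_negative = TRUE),
    oracle_posterior(r, base, prior, update_negative = TRUE),
    tolerance = 1e-12
  )

  # all causes annihilated -> uninterpretable
  bz <- base
  bz["i1", ] <- c(0, 0, 1e-300)
  bz["i2", ] <- c(0.5, 0.5, 0)
  expect_error(
    va_posterior(resp_with(bz, yes = c("i1", "i2")), bz, prior),
    class = "va_uninterpretable"
  )
})

test_that("posterior matches exhaustive joint-probability oracle", {
  withr::with_seed(101, {
    for (rep in 1:40) {
      m <- sample(2:4, 1)
      n <- sample(2:6, 1)
      base <- random_base(m, n)
      prior <- random_prior(m)
      resp <- setNames(
        sample(c("Y", "N", "."), n, replace = TRUE),
        rownames(base)
      )
      for (neg in c(FALSE, TRUE)) {
        expect_equal(
          va_posterior(resp, base, prior, update_negative = neg),
          oracle_posterior(resp, base, prior, update_negative = neg),
          tolerance = 1e-9
        )
      }
    }
  })
})

test_that("posterior is normalized, order-invariant and monotone", {
  withr::with_seed(202, {
    for (rep in 1:20) {
      base <- random_base(4, 6)
      prior <- random_prior(4)
      resp <- setNames(sample(c("Y", "."), 6, replace = TRUE), rownames(base))
      post <- va_posterior(resp, base, prior)
      expect_equal(sum(post), 1, tolerance = 1e-9)

      # permuting indicator rows (update order) leaves posterior unchanged
      perm <- sample(nrow(base))
      expect_equal(
        va_posterior(resp[perm], base[perm, ], prior), post,
        tolerance = 1e-12
      )

      # raising P(I|C_k) for an observed indicator never lowers cause k
      yes_ind <- names(resp)[resp == "Y"]
      if (length(yes_ind) > 0) {
        b2 <- base
        b2[yes_ind[1], 2] <- min(1, b2[yes_ind[1], 2] * 1.5)
        expect_gte(
          va_posterior(resp, b2, prior)[[2]] + 1e-12, post[[2]]
        )
      }
    }
  })
})

test_that("single-indicator update equals the two-hypothesis Bayes formula", {
  withr::with_seed(303, {
    for (rep in 1:25) {
      m <- sample(2:5, 1)
      base <- random_base(m, 3)
      prior <- random_prior(m)
      resp <- resp_with(base, yes = "i01")
      post <- va_posterior(resp, base, prior)
      for (ck in colnames(base)) {
        p_c <- prior[[ck]]
        p_i_c <- base["i01", ck]
        p_i_notc <- va_complement_likelihood(base, prior, "i01", ck)
        binary <- p_i_c * p_c / (p_i_c * p_c + p_i_notc * (1 - p_c))
        expect_equal(post[[ck]], binary, tolerance = 1e-9)
      }
    }
  })
})

test_that("cause selection applies the top and relative thresholds", {
  # degenerate posterior: single cause at 100%
  sel <- va_select_causes(c(a = 1, b = 0, c = 0))
  expect_equal(sel$cause, "a")
  expect_equal(sel$likelihood_pct, 100)

  # relative threshold keeps cause 2 (0.30 >= 0.275), drops cause 3
  sel <- va_select_causes(c(a = 0.55, b = 0.30, c = 0.15))
  expect_equal(sel$cause, c("a", "b"))
  expect_equal(sel$likelihood_pct, c(55, 30))
  expect_false(any(sel$indeterminate))

  # below tau_top: indeterminate
  sel <- va_select_causes(c(a = 0.35, b = 0.33, c = 0.32))
  expect_true(sel$indeterminate)
  expect_equal(sel$cause, "indeterminate")

  # at most three causes even if four qualify
  sel <- va_select_causes(c(a = 0.4, b = 0.21, c = 0.2, d = 0.19),
                          tau_rel = 0.2)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$rank, 1:3)

  # ties broken by cause order, likelihoods non-increasing
  sel <- va_select_causes(c(b = 0.25, a = 0.5, c = 0.25), tau_rel = 0.4)
  expect_equal(sel$cause, c("a", "b", "c"))
  expect_true(all(diff(sel$likelihood_pct) <= 0))
})

test_that("cohort interpretation is deterministic and failure-tolerant", {
  base <- toy_base()
  prior <- toy_prior()
  mk_cases <- function(i1, i2) {
    tibble::tibble(
      id = sprintf("c%d", seq_along(i1)),
      age_group = "18+ years", sex = "male", site = "site_a",
      i1 = i1, i2 = i2
    )
  }

  # empty cohort -> empty assignment table with the right columns
  empty <- va_interpret(mk_cases(character(0), character(0)), base, prior)
  expect_equal(nrow(empty), 0)
  expect_named(
    empty, c("id", "rank", "cause", "likelihood_pct", "indeterminate", "method")
  )

  # one case duplicated: identical assignments, input order preserved
  cases <- mk_cases(rep("Y", 5), rep(".", 5))
  asg <- va_interpret(cases, base, prior)
  expect_equal(unique(asg$cause), "a")
  expect_equal(unique(asg$likelihood_pct), 90)
  expect_equal(unique(asg$id), cases$id)
  expect_identical(asg, va_interpret(cases, base, prior))

  # an uninterpretable case warns and yields indeterminate, not an abort
  bz <- base
  bz["i1", ] <- c(0, 0, 0.5)
  bz["i2", ] <- c(0.5, 0.5, 0)
  cases <- mk_cases(c("Y", "Y"), c("N", "Y"))
  expect_warning(asg <- va_interpret(cases, bz, prior), "indeterminate")
  expect_false(asg$indeterminate[asg$id == "c1"])
  expect_true(asg$indeterminate[asg$id == "c2"])

  # missing indicator columns are reported
  expect_error(
    va_interpret(mk_cases("Y", "Y")[, -6], base, prior), "i2"
  )
})
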