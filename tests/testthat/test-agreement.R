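test_that("cross-tabulation counts pairs cell by cell", {
  # one case, both methods agree: single diagonal cell
  t <- va_cross_tabulate(
    tibble::tibble(id = "1", group = "malaria"),
    tibble::tibble(id = "1", group = "malaria")
  )
  expect_equal(sum(t), 1)
  expect_equal(t["malaria", "malaria"], 1L)

  # two cases with swapped labels: symmetric off-diagonal
  t <- va_cross_tabulate(
    tibble::tibble(id = c("1", "2"), group = c("malaria", "measles")),
    tibble::tibble(id = c("1", "2"), group = c("measles", "malaria"))
  )
  expect_equal(diag(t), c(malaria = 0L, measles = 0L))
  expect_equal(t["malaria", "measles"], 1L)
  expect_equal(t["measles", "malaria"], 1L)

  # six paired cases enumerated by hand
  a <- tibble::tibble(
    id = as.character(1:6),
    group = c("hiv_aids", "hiv_aids", "malaria", "injuries", "malaria", "indeterminate")
  )
  b <- tibble::tibble(
    id = as.character(1:6),
    group = c("hiv_aids", "malaria", "malaria", "hiv_aids", "injuries", "indeterminate")
  )
  t <- va_cross_tabulate(a, b)
  expect_equal(sum(t), 6)
  expect_equal(t["hiv_aids", "hiv_aids"], 1L)
  expect_equal(t["hiv_aids", "malaria"], 1L)
  expect_equal(t["malaria", "malaria"], 1L)
  expect_equal(t["injuries", "hiv_aids"], 1L)
  expect_equal(t["malaria", "injuries"], 1L)
  expect_equal(t["indeterminate", "indeterminate"], 1L)
  # indeterminate is kept as the last label on both axes
  expect_equal(rownames(t)[nrow(t)], "indeterminate")

  # mismatched id sets are an error naming the offenders
  expect_error(
    va_cross_tabulate(a, b[-2, ]),
    "do not match.*2"
  )
})

test_that("percent agreement reproduces stratum-level worked examples", {
  # overall: 630 of 1,823 deaths in direct agreement -> 34.56%
  overall <- as_xtab(matrix(c(630, 600, 593, 0), 2, byrow = TRUE))
  pa <- va_percent_agreement(overall)
  expect_equal(pa$n_agree, 630L)
  expect_equal(pa$n_total, 1823L)
  expect_equal(round(pa$percent, 2), 34.56)

  # under-5: 181 of 572 -> 31.64%
  under5 <- as_xtab(matrix(c(181, 200, 191, 0), 2, byrow = TRUE),
                    stratum = "under-5")
  pa <- va_percent_agreement(under5)
  expect_equal(round(pa$percent, 2), 31.64)
  expect_equal(pa$stratum, "under-5")

  # identical assignments: 100%
  g <- tibble::tibble(id = as.character(1:10), group = rep(c("x", "y"), 5))
  expect_equal(va_percent_agreement(va_cross_tabulate(g, g))$percent, 100)
})

test_that("excluding indeterminates recomputes n and n_agree consistently", {
  labels <- c("malaria", "hiv_aids", "indeterminate")
  m <- matrix(c(
    30, 5, 10,
    4, 25, 6,
    8, 7, 12
  ), 3, byrow = TRUE)
  t <- as_xtab(m, labels = labels)
  full <- va_percent_agreement(t)
  excl <- va_percent_agreement(t, exclude_indeterminate = TRUE)
  expect_equal(full$n_total, 107L)
  expect_equal(full$n_agree, 67L)
  expect_equal(excl$n_total, 64L)   # drops row 3 and column 3
  expect_equal(excl$n_agree, 55L)   # diagonal minus the (3,3) cell
  expect_equal(excl$percent, 100 * 55 / 64)

  # empty after exclusion is an error, not NaN
  only_ind <- as_xtab(matrix(c(0, 0, 0, 5), 2, byrow = TRUE),
                      labels = c("malaria", "indeterminate"))
  expect_error(
    va_percent_agreement(only_ind, exclude_indeterminate = TRUE),
    "no cases"
  )
})

test_that("kappa endpoints and closed-form examples are exact", {
  # perfect diagonal: kappa = 1
  k <- va_kappa(as_xtab(diag(c(10, 20, 30))))
  expect_equal(k$kappa, 1)
  expect_equal(k$po, 1)

  # hand-computed 2x2: po = 0.8, pe = 0.5, kappa = 0.6
  k <- va_kappa(as_xtab(matrix(c(40, 10, 10, 40), 2, byrow = TRUE)))
  expect_equal(k$po, 0.8)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.6)

  # chance-level: observed cells equal margin products -> kappa = 0
  k <- va_kappa(as_xtab(matrix(25, 2, 2)))
  expect_equal(k$kappa, 0)

  # undefined when all margin mass sits in one category
  expect_error(
    va_kappa(as_xtab(matrix(c(9, 0, 0, 0), 2, byrow = TRUE))),
    "undefined"
  )
})

test_that("kappa SE matches an independent large-sample implementation", {
  # expected values computed with statsmodels cohens_kappa (frozen)
  cases <- list(
    list(m = matrix(c(40, 10, 10, 40), 2, byrow = TRUE),
         kappa = 0.6, se = 0.08),
    list(m = matrix(c(20, 5, 3, 2, 30, 4, 6, 1, 29), 3, byrow = TRUE),
         kappa = 0.682971014493, se = 0.061167404812),
    list(m = matrix(c(50, 2, 3, 9, 4, 40, 2, 1, 7, 3, 25, 5, 1, 2, 8, 38),
                    4, byrow = TRUE),
         kappa = 0.683565609641, se = 0.040198736022)
  )
  for (cs in cases) {
    k <- va_kappa(as_xtab(cs$m))
    expect_equal(k$kappa, cs$kappa, tolerance = 1e-10)
    expect_equal(k$se, cs$se, tolerance = 1e-10)
    # CI is symmetric about kappa and contains it
    expect_equal(k$ci_low + k$ci_high, 2 * k$kappa, tolerance = 1e-12)
    expect_lt(k$ci_low, k$kappa)
  }
})

test_that("kappa is symmetric under transposition and matches the oracle", {
  withr::with_seed(404, {
    for (rep in 1:50) {
      d <- sample(2:6, 1)
      m <- matrix(rpois(d * d, 8) + 1, d)
      k <- va_kappa(as_xtab(m))
      kt <- va_kappa(as_xtab(t(m)))
      expect_equal(k$kappa, oracle_kappa(m), tolerance = 1e-12)
      expect_equal(k$kappa, kt$kappa, tolerance = 1e-12)
      expect_equal(k$po, kt$po)
      expect_equal(k$pe, kt$pe, tolerance = 1e-12)
      expect_gte(k$kappa, -1)
      expect_lte(k$kappa, 1)
    }
  })
})

test_that("rank-k agreement restricts to cases holding a k-th cause", {
  map <- va_default_map("interva")
  asg <- tibble::tibble(
    id = rep(c("c1", "c2", "c3", "c4", "c5"),
             times = c(2, 2, 1, 2, 1)),
    rank = c(1L, 2L, 1L, 2L, 1L, 1L, 2L, NA),
    cause = c(
      "hiv_aids", "pulmonary_tb",   # c1
      "malaria", "hiv_aids",        # c2
      "pneumonia_sepsis",           # c3 (single cause)
      "measles", "malaria",         # c4
      "indeterminate"               # c5
    ),
    likelihood_pct = c(60, 35, 55, 40, 90, 50, 30, NA),
    indeterminate = c(rep(FALSE, 7), TRUE),
    method = "model"
  )
  phys <- tibble::tibble(
    id = c("c1", "c2", "c3", "c4", "c5"),
    group = c("hiv_aids", "hiv_aids", "pneumonia", "malaria", "injuries")
  )

  # k = 1 without restriction is the standard pipeline over all cases:
  # c1, c3 agree at rank 1 -> 2/5
  r1 <- va_rank_agreement(phys, asg, map, k = 1, restrict = FALSE)
  expect_equal(r1$agreement$n_total, 5L)
  expect_equal(r1$agreement$n_agree, 2L)

  # k = 2 restricted to the three two-cause cases:
  # rank-2 groups are ptb / hiv / malaria vs physician hiv / hiv / malaria
  r2 <- va_rank_agreement(phys, asg, map, k = 2)
  expect_equal(r2$agreement$n_total, 3L)
  expect_equal(r2$agreement$n_agree, 2L)
  expect_equal(r2$kappa$n, 3)

  # every rank-2 cause matching its physician group -> 100% at k = 2
  asg_perfect <- dplyr::mutate(
    asg,
    cause = dplyr::case_when(
      .data$rank %in% 2L & .data$id == "c1" ~ "hiv_aids",
      .data$rank %in% 2L ~ "malaria",
      TRUE ~ .data$cause
    )
  )
  phys_m <- tibble::tibble(
    id = c("c1", "c2", "c4"), group = c("hiv_aids", "malaria", "malaria")
  )
  r <- va_rank_agreement(phys_m, asg_perfect, map, k = 2)
  expect_equal(r$agreement$percent, 100)
  expect_equal(r$kappa$kappa, 1)

  expect_error(va_rank_agreement(phys, asg, map, k = 3), "3 or more")
})
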