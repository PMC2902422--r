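# Shared fixtures and independent oracles, all built in code.

# toy 2-indicator x 3-cause base used across engine tests
toy_base <- function() {
  matrix(
    c(
      0.9, 0.1, 0.1,
      0.2, 0.8, 0.3
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("i1", "i2"), c("a", "b", "c"))
  )
}

toy_prior <- function() c(a = 0.5, b = 0.3, c = 0.2)

# random strictly-positive probability base
random_base <- function(n_causes, n_ind) {
  matrix(
    runif(n_ind * n_causes, min = 0.01, max = 0.99),
    nrow = n_ind,
    dimnames = list(
      sprintf("i%02d", seq_len(n_ind)),
      sprintf("c%02d", seq_len(n_causes))
    )
  )
}

random_prior <- function(n_causes) {
  p <- runif(n_causes, 0.05, 1)
  setNames(p / sum(p), sprintf("c%02d", seq_len(n_causes)))
}

# Independent posterior oracle: exhaustive joint-probability computation
# P(cause, observed pattern) / P(pattern) under conditional independence.
# Plain products, no log space, no shared code with the engine.
# resp: named character vector Y/N/.; "." contributes no factor and "N"
# contributes (1 - p) only when negative updating is on.
oracle_posterior <- function(resp, base, prior, update_negative = FALSE) {
  joint <- vapply(colnames(base), function(ck) {
    p <- prior[[ck]]
    for (ij in rownames(base)) {
      if (resp[[ij]] == "Y") {
        p <- p * base[ij, ck]
      } else if (resp[[ij]] == "N" && update_negative) {
        p <- p * (1 - base[ij, ck])
      }
    }
    p
  }, numeric(1))
  joint / sum(joint)
}

# Independent textbook kappa: margins and diagonal only.
oracle_kappa <- function(t) {
  n <- sum(t)
  po <- sum(diag(t)) / n
  pe <- sum((rowSums(t) / n) * (colSums(t) / n))
  (po - pe) / (1 - pe)
}

# contingency table fixture from a plain count matrix
as_xtab <- function(m, stratum = "overall", labels = NULL) {
  if (is.null(labels)) {
    labels <- sprintf("g%02d", seq_len(nrow(m)))
  }
  structure(
    matrix(as.integer(m), nrow(m), dimnames = list(a = labels, b = labels)),
    class = c("va_xtab", "matrix"), stratum = stratum
  )
}

# paired (id, group) tibbles realizing a given contingency table
groups_from_xtab <- function(m, labels = NULL) {
  if (is.null(labels)) {
    labels <- sprintf("g%02d", seq_len(nrow(m)))
  }
  a <- character(0)
  b <- character(0)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      a <- c(a, rep(labels[i], m[i, j]))
      b <- c(b, rep(labels[j], m[i, j]))
    }
  }
  ids <- sprintf("id%05d", seq_along(a))
  list(
    a = tibble::tibble(id = ids, group = a),
    b = tibble::tibble(id = ids, group = b)
  )
}

# full response vector with every indicator unknown except those given
resp_with <- function(base, yes = character(0), no = character(0)) {
  r <- setNames(rep(".", nrow(base)), rownames(base))
  r[yes] <- "Y"
  r[no] <- "N"
  r
}
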