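# Brute-force oracle for the data-dependent threshold: evaluate the FDP
# estimate on every candidate and take the smallest qualifying one.
brute_threshold <- function(kappa, tau, alpha, m_copies) {
  cands <- sort(unique(tau[tau > 0]))
  ok <- vapply(cands, function(t) {
    (1 / m_copies + sum(kappa >= 1 & tau >= t) / m_copies) /
      max(1, sum(kappa == 0 & tau >= t)) <= alpha
  }, logical(1))
  if (any(ok)) min(cands[ok]) else Inf
}

fake_stats <- function(kappa, tau, delta = ifelse(kappa == 0, tau, 0)) {
  tibble::tibble(
    gene_id = paste0("g", seq_along(kappa)),
    z = sqrt(abs(tau)), t_obs = abs(tau), kappa = kappa, tau = tau,
    delta = delta
  )
}

test_that("importance scores are elementwise squares", {
  z <- c(-3, 0, 1.5)
  zk <- matrix(c(0, 1, -2, 0.5, 0, 2), 3, 2)
  st <- knockoff_stats(z, zk)
  expect_equal(st$t_obs, z^2)
  expect_equal(attr(st, "t_knock"), zk^2, ignore_attr = TRUE)
})

test_that("kappa, tau and delta match hand-computed cases", {
  # original clearly largest: kappa 0, tau = 9 - median(1..5) = 6
  st <- knockoff_stats(3, matrix(sqrt(1:5), 1))
  expect_equal(st$kappa, 0L)
  expect_equal(st$tau, 6)
  expect_equal(st$delta, 6)

  # a knockoff attains the max: delta must be zero
  st2 <- knockoff_stats(1, matrix(sqrt(c(4, 0, 0, 0, 0)), 1))
  expect_equal(st2$kappa, 1L)
  expect_equal(st2$delta, 0)
  # symmetric tau: largest score 4 minus median of remaining (1,0,0,0,0)
  expect_equal(st2$tau, 4)

  # M = 1 single-knockoff case
  st3 <- knockoff_stats(sqrt(5), matrix(sqrt(2), 1))
  expect_equal(st3$kappa, 0L)
  expect_equal(st3$tau, 3)
  expect_equal(st3$delta, 3)

  # exact tie goes to the knockoff and zeroes delta
  st4 <- knockoff_stats(2, matrix(c(2, 1), 1))
  expect_equal(st4$kappa, 1L)
  expect_equal(st4$delta, 0)
})

test_that("tau is a symmetric function of the copies", {
  withr::with_seed(17, {
    z <- rnorm(6)
    zk <- matrix(rnorm(6 * 5), 6, 5)
    base <- knockoff_stats(z, zk)
    perm <- knockoff_stats(z, zk[, c(3, 1, 5, 2, 4)])
    expect_equal(base$tau, perm$tau)
    expect_equal(base$delta, perm$delta)
  })
})

test_that("threshold matches the worked M = 1 example and its selection", {
  st <- fake_stats(kappa = c(0, 0, 0, 1), tau = c(3, 2, 1, 0.5))
  expect_equal(knockoff_threshold(st, alpha = 0.5, M = 1), 1)
  sel <- knockoff_select(st, alpha = 0.5, M = 1)
  expect_equal(sel$stats$gene_id[sel$stats$selected], c("g1", "g2", "g3"))

  # all originals win with small tau spread: every gene selectable
  st2 <- fake_stats(kappa = rep(0L, 10), tau = seq(0.1, 1, by = 0.1))
  expect_equal(knockoff_threshold(st2, alpha = 0.05, M = 5), 0.1)

  # all knockoffs win: threshold infinite, empty selection
  st3 <- fake_stats(kappa = c(1L, 2L), tau = c(1, 2))
  expect_equal(knockoff_threshold(st3, alpha = 0.2, M = 5), Inf)
  sel3 <- knockoff_select(st3, alpha = 0.2, M = 5)
  expect_equal(sum(sel3$stats$selected), 0)

  # single gene, generous alpha: (1/5)/1 = 0.2 <= 0.9 -> selected
  st4 <- fake_stats(kappa = 0L, tau = 5)
  sel4 <- knockoff_select(st4, alpha = 0.9, M = 5)
  expect_true(sel4$stats$selected)

  expect_error(knockoff_threshold(st, alpha = 1.5, M = 1), "alpha")
})

test_that("threshold and selection match brute-force enumeration on random instances", {
  withr::with_seed(202, {
    for (i in 1:100) {
      d <- sample(3:40, 1)
      m_copies <- sample(c(1, 3, 5), 1)
      alpha <- runif(1, 0.05, 0.5)
      z <- rnorm(d, 0, 1) + sample(c(0, 3), d, replace = TRUE)
      zk <- matrix(rnorm(d * m_copies), d, m_copies)
      st <- knockoff_stats(z, zk)
      t_hat <- knockoff_threshold(st, alpha, m_copies)
      expect_identical(t_hat, brute_threshold(st$kappa, st$tau, alpha, m_copies))
      sel <- knockoff_select(st, alpha, m_copies)
      expect_identical(
        sel$stats$selected,
        st$kappa == 0L & st$tau >= t_hat
      )
      # selection via delta and via (kappa, tau) coincide
      expect_identical(
        sel$stats$selected,
        st$delta >= t_hat & st$kappa == 0L
      )
    }
  })
})

test_that("selections are monotone in alpha", {
  withr::with_seed(77, {
    z <- rnorm(30) + rep(c(0, 2), 15)
    zk <- matrix(rnorm(30 * 5), 30, 5)
    st <- knockoff_stats(z, zk)
    sizes <- vapply(
      c(0.01, 0.05, 0.1, 0.2, 0.5),
      function(a) sum(knockoff_select(st, a, 5)$stats$selected),
      numeric(1)
    )
    expect_true(all(diff(sizes) >= 0))
  })
})

test_that("M = 1 filter matches an independent single-knockoff implementation", {
  # classic knockoff+ on W = T - Ttilde, written independently
  knockoff_plus <- function(t_obs, t_knock, alpha) {
    w <- t_obs - t_knock
    cands <- sort(unique(abs(w[w != 0])))
    th <- Inf
    for (t in cands) {
      if ((1 + sum(w <= -t)) / max(1, sum(w >= t)) <= alpha) {
        th <- t
        break
      }
    }
    which(w >= th)
  }
  withr::with_seed(55, {
    for (i in 1:20) {
      d <- 50
      z <- rnorm(d) + sample(c(0, 3), d, replace = TRUE)
      zk <- matrix(rnorm(d), d, 1)
      st <- knockoff_stats(z, zk)
      sel <- knockoff_select(st, alpha = 0.25, M = 1)
      expect_identical(
        which(sel$stats$selected),
        knockoff_plus(z^2, zk[, 1]^2, 0.25)
      )
    }
  })
})

test_that("evaluate_selection computes mFDR and TPP contributions", {
  ev <- evaluate_selection(c("a", "b"), causal = "a", alpha = 0.05)
  expect_equal(ev$mfdr, 1 / (2 + 20))
  expect_equal(ev$tpp, 1)

  ev2 <- evaluate_selection(character(), causal = "a", alpha = 0.05)
  expect_equal(ev2$mfdr, 0)
  expect_equal(ev2$tpp, 0)

  # selections entirely inside H1 contribute no false discoveries
  ev3 <- evaluate_selection(c("a", "b"), causal = c("a", "b", "c"), alpha = 0.1)
  expect_equal(ev3$mfdr, 0)
  expect_equal(ev3$tpp, 2 / 3)

  # empty truth: TPP undefined
  ev4 <- evaluate_selection("a", causal = character(), alpha = 0.05)
  expect_true(is.na(ev4$tpp))
})

test_that("tidy, glance and autoplot work on a selection", {
  st <- fake_stats(kappa = c(0, 0, 1), tau = c(3, 2, 1))
  sel <- knockoff_select(st, alpha = 0.5, M = 1)
  expect_s3_class(tidy(sel), "tbl_df")
  g <- glance(sel)
  expect_equal(g$n_selected, sum(sel$stats$selected))
  p <- autoplot(sel)
  expect_s3_class(p, "ggplot")
})
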