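# Loss family: closed-form values, reduction identities, gradients,
# curves, batch-mean structure.

random_batch <- function(n = 16) {
  list(p = runif(n, 0.01, 0.99), y = rbinom(n, 1, 0.5))
}

test_that("hand-derived loss values match the closed forms", {
  eps <- 1e-7
  expect_lt(bce(c(1 - eps, eps), c(1, 0)), 1e-6)
  expect_equal(bce(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 1, w = 2), 2 * log(2), tolerance = 1e-12)
  expect_equal(rwwce(0.5, 1, w_mcfn = 2), 2 * log(2), tolerance = 1e-12)
  expect_equal(rwwce(0.5, 0, w_mcfp = 3), 3 * log(2), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, 1, gamma = 2), 0.01 * -log(0.9),
               tolerance = 1e-10)
  expect_equal(asl(0.5, 1, gamma_pos = 2, gamma_neg = 0, margin = 0),
               0.25 * log(2), tolerance = 1e-12)
  # probability shifting removes very-easy negatives entirely
  expect_equal(asl(0.05, 0, gamma_pos = 0, gamma_neg = 4, margin = 0.1), 0)
  # PEN-BCE single-positive simplification: -log p + alpha max(0, p_fn - p)^2
  expect_equal(pen_bce(0.25, 1, loss_params(1, 0, 0.5, 0.2)),
               -log(0.25) + 0.0625, tolerance = 1e-12)
  expect_equal(pen_bce(0.25, 1, loss_params(1, 0, 0.5, 0.2)), 1.4488,
               tolerance = 1e-4)
  expect_equal(pen_bce(0.6, 0, loss_params(0, 5, 0.5, 0.2)),
               -log(0.4) + 5 * 0.16, tolerance = 1e-12)
  expect_equal(pen_bce(0.6, 0, loss_params(0, 5, 0.5, 0.2)), 1.7163,
               tolerance = 1e-4)
  # hinge inactive: PEN-BCE equals BCE exactly
  expect_identical(pen_bce(0.7, 1, loss_params(3, 3, 0.5, 0.2)) == bce(0.7, 1),
                   TRUE)
})

test_that("every variant reduces to BCE at its neutral parameters", {
  set.seed(33)
  for (i in 1:200) {
    b <- random_batch()
    base <- bce(b$p, b$y)
    expect_equal(weighted_bce(b$p, b$y, w = 1), base, tolerance = 1e-12)
    expect_equal(rwwce(b$p, b$y, 1, 1), base, tolerance = 1e-12)
    expect_equal(asl(b$p, b$y, 0, 0, 0), base, tolerance = 1e-12)
    expect_equal(pen_bce(b$p, b$y, loss_params(0, 0, 0.5, 0.2)), base,
                 tolerance = 1e-12)
    # focal at gamma 0 is cross-entropy on p_t (= BCE for 0/1 labels)
    expect_equal(focal_loss(b$p, b$y, gamma = 0), base, tolerance = 1e-12)
  }
})

test_that("PEN-BCE dominates BCE pointwise, with equality iff hinges inactive", {
  set.seed(9)
  pars <- loss_params(2, 3, 0.6, 0.3)
  for (i in 1:50) {
    b <- random_batch(1)
    d <- pen_bce(b$p, b$y, pars) - bce(b$p, b$y)
    active <- (b$y == 1 && b$p < pars$p_fn) || (b$y == 0 && b$p > pars$p_fp)
    expect_gte(d, 0)
    expect_identical(d > 1e-15, active)
  }
})

test_that("analytic gradients match central finite differences off the hinges", {
  set.seed(17)
  pars <- loss_params(1.5, 4, 0.5, 0.2)
  fd <- function(f, p, y) {
    h <- 1e-6
    vapply(seq_along(p), function(i) {
      pp <- p; pm <- p
      pp[i] <- p[i] + h; pm[i] <- p[i] - h
      (f(pp, y) - f(pm, y)) / (2 * h)
    }, 0)
  }
  cases <- list(
    list(f = bce, g = bce_grad),
    list(f = function(p, y) weighted_bce(p, y, 2.5),
         g = function(p, y) weighted_bce_grad(p, y, 2.5)),
    list(f = function(p, y) focal_loss(p, y, 2),
         g = function(p, y) focal_loss_grad(p, y, 2)),
    list(f = function(p, y) asl(p, y, 1, 4, 0.05),
         g = function(p, y) asl_grad(p, y, 1, 4, 0.05)),
    list(f = function(p, y) rwwce(p, y, 2, 3),
         g = function(p, y) rwwce_grad(p, y, 2, 3)),
    list(f = function(p, y) pen_bce(p, y, pars),
         g = function(p, y) pen_bce_grad(p, y, pars))
  )
  for (cs in cases) {
    for (rep in 1:5) {
      b <- random_batch(8)
      # keep clear of the hinge/margin kinks and the clip boundary
      b$p <- pmin(0.97, pmax(0.03, b$p))
      b$p[abs(b$p - 0.5) < 0.02] <- 0.55
      b$p[abs(b$p - 0.2) < 0.02] <- 0.25
      b$p[abs(b$p - 0.05) < 0.02] <- 0.08
      expect_lt(max(abs(cs$g(b$p, b$y) - fd(cs$f, b$p, b$y))), 1e-6)
    }
  }
  # subgradient 0 exactly at the hinge
  g_at_hinge <- pen_bce_grad(c(0.5, 0.2), c(1, 0), loss_params(1, 5, 0.5, 0.2))
  expect_equal(g_at_hinge, bce_grad(c(0.5, 0.2), c(1, 0)))
})

test_that("losses are size-weighted means over concatenated batches", {
  set.seed(41)
  pars <- loss_params()
  for (i in 1:20) {
    a <- random_batch(7); b <- random_batch(13)
    whole <- pen_bce(c(a$p, b$p), c(a$y, b$y), pars)
    parts <- (7 * pen_bce(a$p, a$y, pars) + 13 * pen_bce(b$p, b$y, pars)) / 20
    expect_equal(whole, parts, tolerance = 1e-12)
  }
})

test_that("loss curves expose the FN penalty structure", {
  grid <- seq(0.05, 0.95, by = 0.05)
  c_bce <- loss_curve("bce", y_fixed = 1, p_grid = grid)
  c0 <- loss_curve("pen_bce", y_fixed = 1, p_grid = grid,
                   params = loss_params(0, 0, 0.5, 0.2))
  expect_equal(c0$loss, c_bce$loss, tolerance = 1e-12)
  c1 <- loss_curve("pen_bce", y_fixed = 1, p_grid = grid,
                   params = loss_params(1, 0, 0.5, 0.2))
  c5 <- loss_curve("pen_bce", y_fixed = 1, p_grid = grid,
                   params = loss_params(5, 0, 0.5, 0.2))
  expect_true(all(c1$loss >= c_bce$loss))
  expect_equal(c1$loss[grid >= 0.5], c_bce$loss[grid >= 0.5])
  # alpha scaling: difference at p = 0.1 is (5 - 1) * (0.5 - 0.1)^2
  at <- which(abs(grid - 0.1) < 1e-9)
  expect_equal(c5$loss[at] - c1$loss[at], 4 * 0.4^2, tolerance = 1e-12)
  # monotone non-increasing in p for y = 1
  expect_true(all(diff(c5$loss) <= 1e-12))
})

test_that("the ablation hyper-parameter grid has the nine published rows", {
  g <- pen_bce_param_grid()
  expect_identical(nrow(g), 9L)
  expect_identical(names(g), c("alpha", "beta", "p_fn", "p_fp"))
  expect_true(any(g$alpha == 1 & g$beta == 5 & g$p_fn == 0.5 & g$p_fp == 0.2))
  # the package default is that best row
  expect_equal(unclass(loss_params())[c("alpha", "beta", "p_fn", "p_fp")],
               as.list(g[g$alpha == 1 & g$beta == 5 & g$p_fn == 0.5 &
                         g$p_fp == 0.2, ]),
               ignore_attr = TRUE)
})

test_that("invalid batches are rejected", {
  expect_error(bce(c(0.5, 0.5), 1), class = "ctsurv_bad_batch")
  expect_error(bce(0.5, 2), class = "ctsurv_bad_batch")
  expect_error(loss_params(alpha = -1))
})
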