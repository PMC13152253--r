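test_that("Wald ratios divide outcome by exposure with first-order SE", {
  expect_equal(wald_ratio(0.10, 0.01, 0.02, 0.01),
               tibble::tibble(estimate = 0.2, se = 0.1))
  expect_equal(wald_ratio(0.10, 0.01, 0, 0.01)$estimate, 0)
  expect_equal(wald_ratio(-0.10, 0.01, 0.02, 0.01),
               tibble::tibble(estimate = -0.2, se = 0.1))
  expect_error(wald_ratio(0, 0.01, 0.02, 0.01), "undefined")
})

test_that("IVW matches the hand-computed two-instrument example", {
  h <- make_harmonized(bx = c(1, 1), by = c(0.5, 0.3), sy = c(0.1, 0.1))
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, 0.4)
  expect_equal(fit$q, 2.0)
  # fixed SE = 1/sqrt(sum w bx^2) = 1/sqrt(200); MRE inflates by sqrt(Q/1)
  expect_equal(fit$se, sqrt(2) / sqrt(200))
  expect_equal(fit$se, 0.1, tolerance = 1e-12)
  expect_equal(fit$q_df, 1L)
})

test_that("IVW degenerates correctly", {
  # identical Wald ratios: estimate equals the ratio, Q = 0, MRE SE = fixed SE
  h <- make_harmonized(bx = c(1, 2, 4), by = c(0.3, 0.6, 1.2),
                       sy = c(0.1, 0.2, 0.1))
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, 0.3)
  expect_equal(fit$q, 0)
  expect_equal(fit$se, 1 / sqrt(sum(c(1, 2, 4)^2 / c(0.1, 0.2, 0.1)^2)))
  expect_equal(fit$q_pvalue, 1)
  # single instrument reduces to the Wald ratio, with a warning
  h1 <- make_harmonized(bx = 0.1, by = 0.02, sx = 0.01, sy = 0.01)
  expect_warning(fit1 <- mr_ivw(h1), "single instrument")
  expect_equal(fit1$estimate, 0.2)
  expect_equal(fit1$se, 0.1)
  expect_equal(fit1$method, "wald_ratio")
})

test_that("IVW, Egger and Q agree with an independent WLS oracle", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      n <- 20
      bx <- rnorm(n, 0.08, 0.03)
      by <- 0.1 + 0.4 * bx + rnorm(n, 0, 0.02)
      sy <- runif(n, 0.01, 0.05)
      h <- make_harmonized(bx, by, sy = sy)
      w <- 1 / sy^2

      o_ivw <- wls_oracle(bx, by, w, intercept = FALSE)
      fit <- mr_ivw(h)
      expect_equal(fit$estimate, unname(o_ivw$coef), tolerance = 1e-10)
      expect_equal(fit$q, o_ivw$rss, tolerance = 1e-10)
      expect_equal(fit$se, unname(o_ivw$se_unit) * max(1, o_ivw$sigma),
                   tolerance = 1e-10)

      # Egger re-orients instruments to positive exposure betas first;
      # apply the same orientation to the oracle's inputs
      s <- sign(bx)
      o_eg <- wls_oracle(bx * s, by * s, w, intercept = TRUE)
      eg <- mr_egger(h)
      expect_equal(eg$intercept, unname(o_eg$coef[1]), tolerance = 1e-10)
      expect_equal(eg$estimate, unname(o_eg$coef[2]), tolerance = 1e-10)
      expect_equal(eg$se, unname(o_eg$se_unit[2]) * max(1, o_eg$sigma),
                   tolerance = 1e-10)
      expect_equal(eg$intercept_se, unname(o_eg$se_unit[1]) * max(1, o_eg$sigma),
                   tolerance = 1e-10)
      expect_equal(eg$q, o_eg$rss, tolerance = 1e-10)

      expect_equal(cochran_q(h, fit$estimate)$q, o_ivw$rss, tolerance = 1e-10)
    }
  })
})

test_that("Egger reproduces exact fits", {
  h <- make_harmonized(bx = c(1, 2, 3), by = c(0.5, 1.0, 1.5))
  eg <- mr_egger(h)
  expect_equal(eg$estimate, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  h2 <- make_harmonized(bx = c(1, 2, 3), by = 0.1 + 0.3 * c(1, 2, 3))
  eg2 <- mr_egger(h2)
  expect_equal(eg2$estimate, 0.3, tolerance = 1e-12)
  expect_equal(eg2$intercept, 0.1, tolerance = 1e-12)
  expect_error(mr_egger(make_harmonized(bx = c(1, 2), by = c(1, 2))), "3 instruments")
})

test_that("weighted median interpolates mid-cumulative weights at one half", {
  # equal weights on ratios (0.1, 0.2, 0.3): s = (1/6, 3/6, 5/6), estimate 0.2
  h <- make_harmonized(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
                       sy = c(0.1, 0.1, 0.1))
  fit <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(fit$estimate, 0.2)
  # all ratios equal: estimate is that ratio and the bootstrap SE is small
  hc <- make_harmonized(bx = c(1, 2, 3), by = 0.25 * c(1, 2, 3),
                        sy = c(0.01, 0.01, 0.01), sx = c(1e-6, 1e-6, 1e-6))
  fitc <- mr_weighted_median(hc, n_boot = 200, seed = 1)
  expect_equal(fitc$estimate, 0.25)
  expect_lt(fitc$se, 0.05)
  # weight concentrating on one instrument pulls the estimate to its ratio
  hw <- make_harmonized(bx = c(1, 1, 1), by = c(0.1, 0.5, 0.9),
                        sy = c(1, 0.001, 1))
  fitw <- mr_weighted_median(hw, n_boot = 10, seed = 1)
  expect_equal(fitw$estimate, 0.5, tolerance = 1e-3)
  # hand-computed unequal-weight interpolation oracle
  bx <- c(1, 1, 1, 1); by <- c(0.1, 0.2, 0.4, 0.8); sy <- c(0.1, 0.2, 0.1, 0.2)
  w <- bx^2 / sy^2
  s <- (cumsum(w) - w / 2) / sum(w)
  expected <- stats::approx(s, by, xout = 0.5)$y
  hh <- make_harmonized(bx, by, sy = sy)
  expect_equal(mr_weighted_median(hh, n_boot = 10, seed = 1)$estimate, expected)
})

test_that("mode estimators find the majority cluster via the kernel argmax", {
  h <- make_harmonized(bx = rep(1, 4), by = c(0.2, 0.2, 0.2, 0.9),
                       sy = rep(0.05, 4))
  fit <- mr_mode(h, n_boot = 50, seed = 1)
  expect_lt(abs(fit$estimate - 0.2), abs(fit$estimate - 0.9))
  r <- c(0.2, 0.2, 0.2, 0.9)
  bw <- 0.9 * sd(r) * 4^(-1 / 5) # mad is 0, so the sd fallback applies
  grid_step <- (diff(range(r)) + 6 * bw) / 4095
  expect_lt(abs(fit$estimate - density_mode_oracle(r, bw = bw)), 3 * grid_step)
  # all ratios equal
  hc <- make_harmonized(bx = c(1, 2, 4), by = 0.3 * c(1, 2, 4))
  expect_equal(mr_mode(hc, n_boot = 10, seed = 1)$estimate, 0.3)
  # weighted mode follows the heavily weighted cluster
  hw <- make_harmonized(bx = rep(1, 6), by = c(0.1, 0.12, 0.14, 0.5, 0.52, 0.54),
                        sy = c(1, 1, 1, 0.01, 0.01, 0.01))
  fw <- mr_mode(hw, weighted = TRUE, n_boot = 10, seed = 1)
  expect_gt(fw$estimate, 0.4)
  fs <- mr_mode(hw, weighted = FALSE, n_boot = 10, seed = 1)
  rs <- c(0.1, 0.12, 0.14, 0.5, 0.52, 0.54)
  expect_lt(abs(fs$estimate -
                  density_mode_oracle(rs, bw = silverman_bw_oracle(rs))), 2e-3)
})

test_that("random-set mode estimates match the fine-grid density oracle", {
  withr::with_seed(33, {
    bx <- rnorm(30, 0.1, 0.02)
    by <- 0.3 * bx + rnorm(30, 0, 0.01)
    sy <- runif(30, 0.005, 0.02)
    h <- make_harmonized(bx, by, sy = sy)
    r <- by / bx
    bw <- silverman_bw_oracle(r)
    tol <- (diff(range(r)) + 6 * bw) / 4095 * 3
    expect_lt(abs(mr_mode(h, n_boot = 10, seed = 1)$estimate -
                    density_mode_oracle(r, bw = bw)), tol)
    w <- bx^2 / sy^2
    expect_lt(abs(mr_mode(h, weighted = TRUE, n_boot = 10, seed = 1)$estimate -
                    density_mode_oracle(r, w = w, bw = bw)), tol)
  })
})

test_that("Cochran's Q scales as expected and is zero at a perfect fit", {
  h <- make_harmonized(bx = c(1, 1), by = c(0.5, 0.3), sy = c(0.1, 0.1))
  q <- cochran_q(h, 0.4)
  expect_equal(q$q, 2.0)
  expect_equal(q$df, 1L)
  # doubling outcome SEs quarters Q
  h2 <- make_harmonized(bx = c(1, 1), by = c(0.5, 0.3), sy = c(0.2, 0.2))
  expect_equal(cochran_q(h2, 0.4)$q, 0.5)
  # perfect fit
  hp <- make_harmonized(bx = c(1, 2), by = c(0.4, 0.8))
  qp <- cochran_q(hp, 0.4)
  expect_equal(qp$q, 0)
  expect_equal(qp$pvalue, 1)
})

test_that("log-odds estimates convert to odds ratios with a scale guard", {
  expect_equal(beta_to_or(0, 0.1)$or, 1.0)
  expect_equal(beta_to_or(-log(2), 0.1)$or, 0.5)
  # printed-style reporting: beta = ln(1.75) with the CI rebuilt from its SE
  se <- (log(1.92) - log(1.59)) / (2 * 1.96)
  conv <- beta_to_or(log(1.75), se)
  expect_equal(conv$or, 1.75)
  expect_equal(round(conv$ci_low, 2), 1.59)
  expect_equal(round(conv$ci_high, 2), 1.92)
  expect_error(beta_to_or(0.1, 0.05, scale = "sd"), "log-odds")
})

test_that("all estimators are invariant to joint per-variant sign flips", {
  withr::with_seed(44, {
    bx <- rnorm(12, 0.1, 0.03)
    by <- 0.3 * bx + rnorm(12, 0, 0.01)
    sy <- runif(12, 0.005, 0.02)
    flip <- sample(c(-1, 1), 12, TRUE)
    h <- make_harmonized(bx, by, sy = sy)
    hf <- make_harmonized(bx * flip, by * flip, sy = sy)
    expect_equal(mr_ivw(h)$estimate, mr_ivw(hf)$estimate)
    expect_equal(mr_egger(h)$estimate, mr_egger(hf)$estimate)
    expect_equal(mr_egger(h)$intercept, mr_egger(hf)$intercept)
    expect_equal(mr_weighted_median(h, n_boot = 5, seed = 1)$estimate,
                 mr_weighted_median(hf, n_boot = 5, seed = 1)$estimate)
    expect_equal(mr_mode(h, n_boot = 5, seed = 1)$estimate,
                 mr_mode(hf, n_boot = 5, seed = 1)$estimate)
  })
})

test_that("estimates respect their theoretical ranges and SE orderings", {
  withr::with_seed(55, {
    bx <- rnorm(15, 0.1, 0.03)
    by <- 0.2 * bx + rnorm(15, 0, 0.02)
    sy <- runif(15, 0.01, 0.03)
    h <- make_harmonized(bx, by, sy = sy)
    r <- by / bx
    wm <- mr_weighted_median(h, n_boot = 5, seed = 1)
    expect_gte(wm$estimate, min(r))
    expect_lte(wm$estimate, max(r))
    md <- mr_mode(h, n_boot = 5, seed = 1)
    bw <- silverman_bw_oracle(r)
    expect_gte(md$estimate, min(r) - bw)
    expect_lte(md$estimate, max(r) + bw)
    fit <- mr_ivw(h)
    se_fixed <- 1 / sqrt(sum(bx^2 / sy^2))
    expect_gte(fit$se, se_fixed)
    expect_gte(fit$q, 0)
    expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
  })
})

test_that("the panel runs every method and degrades gracefully", {
  withr::with_seed(66, {
    bx <- rnorm(10, 0.1, 0.02)
    by <- 0.25 * bx + rnorm(10, 0, 0.01)
    h <- make_harmonized(bx, by)
    panel <- mr_panel(h, n_boot = 30, seed = 2)
    td <- tidy(panel)
    expect_setequal(td$method, c("ivw_mre", "egger", "weighted_median",
                                 "simple_mode", "weighted_mode"))
    expect_true(all(!is.na(td$estimate)))
    g <- glance(panel)
    expect_equal(g$n_snp, 10L)
    expect_false(is.na(g$egger_intercept))
    # 3 instruments: the full panel still runs
    h3 <- make_harmonized(bx[1:3], by[1:3])
    expect_true(all(!is.na(tidy(mr_panel(h3, n_boot = 20, seed = 2))$estimate)))
    # 1 instrument: only the Wald ratio, the rest absent with reasons
    h1 <- make_harmonized(bx[1], by[1])
    td1 <- tidy(mr_panel(h1, n_boot = 20, seed = 2))
    expect_equal(td1$method[!is.na(td1$estimate)], "wald_ratio")
    expect_true(all(!is.na(td1$note[td1$method != "wald_ratio"])))
  })
})
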