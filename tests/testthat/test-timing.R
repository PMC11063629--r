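test_that("WGD call follows the strict ploidy/LOH decision line", {
  expect_false(call_wgd(2.0, 0.0))
  expect_true(call_wgd(3.8, 0.3))               # 3.8 > 2.3
  expect_false(call_wgd(2.9 - 2 * 0.25, 0.25))  # boundary is strict
  expect_true(call_wgd(2.9 - 2 * 0.25 + 1e-9, 0.25))
  expect_error(call_wgd(2, 1.2), "loh_fraction")
  expect_error(call_wgd(0, 0.1))
})

test_that("route multiplicity maps are monotone bijections of [0,1]", {
  pis <- seq(0, 1, 0.05)
  # gain_2+1 saturates at 1/2: the un-gained minor allele always keeps
  # contributing multiplicity-1 SNVs, so p(1) = 1/(3-1)
  tops <- c("gain_2+1" = 0.5, "gain_2+0" = 1, "wgd_2+2" = 1)
  for (route in names(tops)) {
    p <- route_mult2_prob(pis, route)
    expect_equal(p[1], 0)
    expect_equal(p[length(p)], unname(tops[route]))
    expect_true(all(diff(p) > 0))
  }
  expect_equal(route_mult2_prob(0.6, "gain_2+1"), 0.6 / 2.4)
  expect_error(route_mult2_prob(0.5, "unknown"), "unknown route")
})

test_that("route likelihood peaks at the algebraic MLE", {
  # n2 = 0: maximized at pi = 0
  ll0 <- route_likelihood(list(n1 = 50, n2 = 0), "gain_2+1")
  pis <- seq(0.001, 0.999, 0.001)
  expect_equal(pis[which.max(ll0(pis))], 0.001)
  # f = 0.5 inverts to pi = 1 for gain_2+1
  ll5 <- route_likelihood(list(n1 = 200, n2 = 200), "gain_2+1")
  expect_equal(pis[which.max(ll5(pis))], 0.999)
  # f = 0.25 inverts to pi = 3f/(1+f) = 0.6
  ll25 <- route_likelihood(list(n1 = 300, n2 = 100), "gain_2+1")
  expect_equal(pis[which.max(ll25(pis))], 0.6, tolerance = 0.01)
  # profile maximum matches the forward simulator's empirical fraction
  cfg <- evolution_sim_config(
    list(list(segment_id = "s", chrom = "chr1", start_bp = 0, end_bp = 1e6,
              route = "gain_2+0", true_pi = 0.45)),
    n_snvs_per_segment = 30000, seed = 13)
  m <- simulate_clonal_snvs(cfg)$multiplicity
  ll <- route_likelihood(list(n1 = m$n1, n2 = m$n2), "gain_2+0")
  expect_equal(pis[which.max(ll(pis))], 0.45, tolerance = 0.01)
  expect_error(route_likelihood(list(n1 = 0, n2 = 0), "gain_2+1"))
})

test_that("MCMC posterior agrees with grid quadrature and spec defaults", {
  # posterior mean > 0.9 when the multiplicity fraction implies pi ~ 1
  post <- sample_gain_timing(list(n1 = 100, n2 = 100), "gain_2+1", seed = 1)
  expect_gt(post$mean, 0.9)
  expect_equal(post$chains, 30)
  expect_equal(post$steps, 2000)
  expect_equal(post$burnin, 1000)
  expect_length(post$samples, 30 * 1000)
  expect_true(all(post$samples >= 0 & post$samples <= 1))
  expect_lt(post$psrf, 1.1)

  # f = 0.25 case: mean tracks quadrature near the algebraic MLE 0.6
  p25 <- sample_gain_timing(list(n1 = 300, n2 = 100), "gain_2+1", seed = 2)
  g25 <- grid_gain_timing(list(n1 = 300, n2 = 100), "gain_2+1")
  expect_equal(p25$mean, g25$mean, tolerance = 0.01)
  expect_equal(g25$mean, 0.6, tolerance = 0.02)

  # quadrature oracle on random configurations
  set.seed(9)
  for (i in 1:8) {
    n <- sample(20:600, 1)
    n2 <- rbinom(1, n, runif(1, 0.05, 0.9))
    route <- sample(c("gain_2+1", "gain_2+0", "wgd_2+2"), 1)
    cc <- list(n1 = n - n2, n2 = n2)
    post <- sample_gain_timing(cc, route, seed = 100 + i)
    g <- grid_gain_timing(cc, route)
    expect_lt(abs(post$mean - g$mean), 0.01)
    expect_lt(abs(post$ci90[1] - g$ci90[1]), 0.012)
    expect_lt(abs(post$ci90[2] - g$ci90[2]), 0.012)
  }
  expect_error(sample_gain_timing(list(n1 = 0, n2 = 0), "gain_2+1"),
               "zero total")
})

test_that("joint WGD timing sharpens and averages single-segment evidence", {
  cfg <- evolution_sim_config(
    list(list(segment_id = "a", chrom = "chr1", start_bp = 0, end_bp = 1e6,
              route = "wgd_2+2", true_pi = 0.4),
         list(segment_id = "b", chrom = "chr2", start_bp = 0, end_bp = 1e6,
              route = "gain_2+0", true_pi = 0.4)),
    n_snvs_per_segment = 500, seed = 17)
  m <- simulate_clonal_snvs(cfg)$multiplicity
  cl <- list(list(n1 = m$n1[1], n2 = m$n2[1], route = "wgd_2+2"),
             list(n1 = m$n1[2], n2 = m$n2[2], route = "gain_2+0"))
  single_a <- sample_gain_timing(cl[[1]], "wgd_2+2", seed = 3)
  single_b <- sample_gain_timing(cl[[2]], "gain_2+0", seed = 4)
  joint <- time_wgd(cl, seed = 5)
  wa <- diff(single_a$ci90); wb <- diff(single_b$ci90)
  expect_lt(diff(joint$ci90), min(wa, wb))         # strictly narrower
  expect_lt(abs(joint$mean - 0.4), 0.05)

  # single segment: identical posterior target as sample_gain_timing
  j1 <- time_wgd(cl[1], seed = 3)
  expect_equal(j1$samples, single_a$samples)

  # discordant segments: joint mean between the two
  g2 <- grid_gain_timing(loglik = function(pi)
    route_likelihood(list(n1 = 400, n2 = 100), "wgd_2+2")(pi) +
      route_likelihood(list(n1 = 60, n2 = 200), "wgd_2+2")(pi))
  m_lo <- grid_gain_timing(list(n1 = 400, n2 = 100), "wgd_2+2")$mean
  m_hi <- grid_gain_timing(list(n1 = 60, n2 = 200), "wgd_2+2")$mean
  expect_gt(g2$mean, m_lo)
  expect_lt(g2$mean, m_hi)
  jd <- time_wgd(list(list(n1 = 400, n2 = 100, route = "wgd_2+2"),
                      list(n1 = 60, n2 = 200, route = "wgd_2+2")), seed = 6)
  expect_equal(jd$mean, g2$mean, tolerance = 0.01)
  expect_error(time_wgd(list()), "no eligible")
})

test_that("pre/post-WGD route classification recovers simulated truth", {
  sim_wgd_ctx <- function(wgd_time, extra_route, extra_pi, seed) {
    cfg <- evolution_sim_config(
      list(list(segment_id = "w1", chrom = "chr1", start_bp = 0, end_bp = 1e6,
                route = "wgd_2+2", true_pi = wgd_time),
           list(segment_id = "w2", chrom = "chr2", start_bp = 0, end_bp = 1e6,
                route = "gain_2+0", true_pi = wgd_time),
           list(segment_id = "seg", chrom = "chr3", start_bp = 0, end_bp = 1e6,
                route = extra_route, true_pi = extra_pi)),
      n_snvs_per_segment = 500, true_wgd_time = wgd_time, seed = seed)
    m <- simulate_clonal_snvs(cfg)$multiplicity
    wgd <- time_wgd(list(list(n1 = m$n1[1], n2 = m$n2[1], route = "wgd_2+2"),
                         list(n1 = m$n1[2], n2 = m$n2[2], route = "gain_2+0")),
                    seed = seed)
    list(counts = list(n1 = m$n1[m$segment_id == "seg"],
                       n2 = m$n2[m$segment_id == "seg"]), wgd = wgd)
  }
  # post-WGD gain, early WGD: post route probability >= 0.8
  ctx <- sim_wgd_ctx(0.3, "post_wgd", 0.7, seed = 21)
  r <- classify_gain_route(list(major_cn = 3), ctx$counts, ctx$wgd)
  expect_gte(r$p_post, 0.8)
  expect_equal(r$p_pre + r$p_post, 1)
  expect_lt(abs(r$timing$mean - 0.7), 0.15)
  # pre-WGD gain, late WGD: pre route probability >= 0.8
  ctx2 <- sim_wgd_ctx(0.8, "pre_wgd", 0.2, seed = 22)
  r2 <- classify_gain_route(list(major_cn = 3), ctx2$counts, ctx2$wgd)
  expect_gte(r2$p_pre, 0.8)
  # symmetric prior: equal similarities give probability 0.5 each
  expect_equal(bhattacharyya(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  expect_error(classify_gain_route(list(major_cn = 3), list(n1 = 5, n2 = 5),
                                   NULL, wgd = FALSE), "WGD tumors")
  expect_error(classify_gain_route(list(major_cn = 2), list(n1 = 5, n2 = 5),
                                   list(samples = runif(10))))
})

test_that("eligibility filter applies the printed thresholds inclusively", {
  segs <- data.frame(
    segment_id = sprintf("s%d", 1:6),
    major_cn = c(2, 2, 3, 3, 4, 2),
    minor_cn = c(1, 3, 1, 1, 2, 1),
    n_snvs = c(9, 50, 50, 10, 50, 10))
  # non-WGD: major up to 2
  keep <- filter_timeable_segments(segs, wgd = FALSE)
  expect_setequal(keep$segment_id, "s6")
  # WGD: major up to 4
  keepw <- filter_timeable_segments(segs, wgd = TRUE)
  expect_setequal(keepw$segment_id, c("s3", "s4", "s5", "s6"))
  # idempotent
  expect_identical(filter_timeable_segments(keepw, TRUE), keepw)
})

test_that("PDX refinement reclassifies exactly the clonal-absent events", {
  tl <- tumor_timeline("PT", data.frame(
    event = c("e1", "e2", "e3"), type = "gain",
    clonality = c("clonal", "clonal", "subclonal")))
  out <- refine_clonality_with_pdx(tl, pdx_events = "e2")
  expect_equal(out$events$clonality, c("subclonal", "clonal", "subclonal"))
  # idempotent
  expect_identical(refine_clonality_with_pdx(out, "e2")$events, out$events)
})

test_that("league model scores, skips and ranks as specified", {
  # strict identical order with non-overlapping supports: ranks fixed
  times <- matrix(rep(c(0.1, 0.5, 0.9), each = 6), nrow = 6,
                  dimnames = list(NULL, c("a", "b", "c")))
  tls <- point_mass_timelines(times)
  lr <- league_rank(tls, n_iter = 100, seed = 2)
  expect_true(all(lr$ranks[, "a"] == 1))
  expect_true(all(lr$ranks[, "b"] == 2))
  expect_true(all(lr$ranks[, "c"] == 3))
  expect_equal(unname(lr$prevalence), rep(1, 3))

  # event sharing no tumor with any other: score stays 0
  t1 <- tumor_timeline("t1", data.frame(event = c("a", "b"), type = "gain",
                                        clonality = "clonal"),
                       posteriors = list(a = 0.2, b = 0.8))
  t2 <- tumor_timeline("t2", data.frame(event = "lonely", type = "gain",
                                        clonality = "clonal"),
                       posteriors = list(lonely = 0.5))
  lr2 <- league_rank(list(t1, t2), n_iter = 20, seed = 3)
  expect_equal(unname(lr2$mean_score["lonely"]), 0)

  # identical timing distributions: symmetric mean scores
  sym <- lapply(1:30, function(t)
    tumor_timeline(paste0("t", t),
                   data.frame(event = c("x", "y"), type = "gain",
                              clonality = "clonal"),
                   posteriors = list(x = runif(20), y = runif(20))))
  set.seed(1)
  lr3 <- league_rank(sym, n_iter = 100, seed = 4)
  d <- lr3$ranks[, "x"] - lr3$ranks[, "y"]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * max(se, 1e-9))

  # untimed events fall back to the recorded order
  t3 <- tumor_timeline("t3", data.frame(event = c("u", "v"), type = "gain",
                                        clonality = "clonal"),
                       order = c(u = 1, v = 2))
  lr4 <- league_rank(list(t3), n_iter = 10, seed = 5)
  expect_true(all(lr4$ranks[, "u"] == 1))
  expect_error(league_rank(list(t2)), "2 events")
})
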