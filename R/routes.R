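# Multiplicity-2 probability for major-CN 3/4 segments of WGD tumors as a
# function of the WGD time t_w and the gain time (or, for the
# underdetermined major-4 post-WGD case, the average s of the two gain
# times). Derived from the per-copy accrual model in a LOH (minor CN 0)
# context, counting multiplicity >= 2 mutations as n2; the pre-WGD major-3
# route assumes one copy is lost immediately after the WGD:
#   major 3, pre-WGD gain  (t_g <= t_w): p = t_w / (3 - t_g - t_w)
#   major 3, post-WGD gain (t_g >= t_w): p = t_g / (3 - t_g - t_w)
#   major 4, pre-WGD gain  (t_g <= t_w): p = (2 t_w - t_g) / (4 - t_g - 2 t_w)
#   major 4, post-WGD gains, average s >= t_w:
#                                        p = (2 s - t_w) / (4 - t_w - 2 s)
wgd_route_prob <- function(t_wgd, t_gain, major_cn, pre) {
  if (major_cn == 3) {
    num <- if (pre) t_wgd else t_gain
    return(num / (3 - t_gain - t_wgd))
  }
  if (major_cn == 4) {
    if (pre) return((2 * t_wgd - t_gain) / (4 - t_gain - 2 * t_wgd))
    return((2 * t_gain - t_wgd) / (4 - t_wgd - 2 * t_gain))
  }
  stop("route classification applies to major_cn 3 or 4")
}

#' Bhattacharyya coefficient between two histograms
#'
#' @param p,q non-negative weight vectors over the same bins (normalized
#'   internally).
#' @return overlap coefficient in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  sum(sqrt(p * q))
}

hist_weights <- function(samples, nbins, weights = NULL) {
  br <- seq(0, 1, length.out = nbins + 1L)
  idx <- pmin(pmax(findInterval(samples, br, rightmost.closed = TRUE), 1L), nbins)
  if (is.null(weights)) weights <- rep(1, length(samples))
  w <- vapply(seq_len(nbins), function(b) sum(weights[idx == b]), 0)
  w / sum(w)
}

#' Classify a gained segment as pre- or post-WGD and time the gain
#'
#' For a major-CN 3 or 4 segment of a WGD tumor, both route hypotheses
#' (gain before vs after the WGD) start with equal prior probability 0.5.
#' Under each route, a joint grid posterior over (WGD time, gain time) on
#' the route's ordering region is computed from the multiplicity counts;
#' its WGD-time marginal is the segment-implied WGD timing distribution,
#' whose similarity to the sample-wide WGD posterior (Bhattacharyya
#' coefficient over `nbins` equal bins, or the overlap coefficient) weights
#' the route. For major-CN 4 post-WGD segments the timed quantity is the
#' average of the two post-WGD gain times (the individual times are
#' underdetermined).
#'
#' @param segment list/row with `major_cn` (3 or 4).
#' @param counts list with `n1`, `n2`.
#' @param wgd_posterior the sample-wide `timing_posterior` from
#'   [time_wgd()].
#' @param wgd logical; the tumor's WGD status (must be `TRUE`).
#' @param nbins histogram bins for the similarity.
#' @param dgrid grid resolution over each time axis.
#' @param similarity `"bhattacharyya"` or `"overlap"`.
#' @param n_samples draws returned in the gain-timing posterior.
#' @param seed seed for those draws.
#' @return list with `p_pre`, `p_post`, `timing` (a `timing_posterior` for
#'   the gain time, mixed over routes) and per-route implied WGD
#'   histograms.
#' @export
classify_gain_route <- function(segment, counts, wgd_posterior, wgd = TRUE,
                                nbins = 100L, dgrid = 0.01,
                                similarity = c("bhattacharyya", "overlap"),
                                n_samples = 3000L, seed = 1L) {
  if (!isTRUE(wgd)) stop("route classification applies to WGD tumors only")
  similarity <- match.arg(similarity)
  major <- segment$major_cn
  n <- counts$n1 + counts$n2
  stopifnot(major %in% c(3, 4), n >= 1)

  tw <- seq(dgrid / 2, 1 - dgrid / 2, by = dgrid)
  grid <- expand.grid(t_wgd = tw, t_gain = tw)
  sample_hist <- hist_weights(wgd_posterior$samples, nbins)

  route_fit <- function(pre) {
    keep <- if (pre) grid$t_gain <= grid$t_wgd else grid$t_gain >= grid$t_wgd
    g <- grid[keep, ]
    p <- pmin(pmax(wgd_route_prob(g$t_wgd, g$t_gain, major, pre), 1e-12),
              1 - 1e-12)
    lw <- dbinom(counts$n2, n, p, log = TRUE)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    wgd_hist <- hist_weights(g$t_wgd, nbins, w)
    sim <- if (similarity == "bhattacharyya") {
      bhattacharyya(wgd_hist, sample_hist)
    } else {
      sum(pmin(wgd_hist / sum(wgd_hist), sample_hist / sum(sample_hist)))
    }
    list(grid = g, w = w, wgd_hist = wgd_hist, sim = sim)
  }
  fit_pre <- route_fit(TRUE)
  fit_post <- route_fit(FALSE)
  wts <- c(pre = 0.5 * fit_pre$sim, post = 0.5 * fit_post$sim)
  if (sum(wts) == 0) wts <- c(pre = 0.5, post = 0.5) else wts <- wts / sum(wts)

  set.seed(stage_seed(seed, "route_draws"))
  n_pre <- rbinom(1, n_samples, wts["pre"])
  draw <- function(fit, k) {
    if (k == 0) return(numeric(0))
    idx <- sample.int(nrow(fit$grid), k, replace = TRUE, prob = fit$w)
    fit$grid$t_gain[idx]
  }
  samples <- c(draw(fit_pre, n_pre), draw(fit_post, n_samples - n_pre))
  list(p_pre = unname(wts["pre"]), p_post = unname(wts["post"]),
       timing = timing_posterior(samples, chains = 1L,
                                 steps = n_samples, burnin = 0L),
       implied_wgd_pre = fit_pre$wgd_hist,
       implied_wgd_post = fit_post$wgd_hist)
}

#' Eligibility filter for timeable gained segments
#'
#' Keeps segments with at least 10 SNVs, minor copy number of at most two,
#' and major copy number up to four in WGD tumors (two in non-WGD tumors).
#' Idempotent.
#'
#' @param segments data.frame with `major_cn`, `minor_cn`, `n_snvs`.
#' @param wgd logical WGD status of the tumor.
#' @param min_snvs,max_minor_cn filter constants as printed.
#' @return the eligible subset, same columns.
#' @export
filter_timeable_segments <- function(segments, wgd, min_snvs = 10L,
                                     max_minor_cn = 2L) {
  max_major <- if (isTRUE(wgd)) 4L else 2L
  keep <- segments$n_snvs >= min_snvs &
    segments$minor_cn <= max_minor_cn &
    segments$major_cn <= max_major &
    segments$major_cn >= segments$minor_cn
  segments[keep, , drop = FALSE]
}

#' Reclassify primary-tumor events absent from the matched PDX
#'
#' An event called clonal in the primary tumor but not found in the PDX is
#' reclassified as subclonal (it was likely absent from the cells that
#' seeded the xenograft); all other events are unchanged. Idempotent.
#'
#' @param pt_timeline a [tumor_timeline()] for the primary tumor.
#' @param pdx_events character vector of event ids observed in the PDX.
#' @return the refined `tumor_timeline`.
#' @export
refine_clonality_with_pdx <- function(pt_timeline, pdx_events) {
  stopifnot(inherits(pt_timeline, "tumor_timeline"))
  ev <- pt_timeline$events
  flip <- ev$clonality == "clonal" & !ev$event %in% pdx_events
  ev$clonality[flip] <- "subclonal"
  pt_timeline$events <- ev
  pt_timeline
}
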