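ROUTES <- c("gain_2+1", "gain_2+0", "wgd_2+2", "pre_wgd", "post_wgd")

#' Configuration for the mutation-accrual simulator
#'
#' Each segment carries an allele-specific copy-number history ("route")
#' with a known event time `true_pi` in mutation time. Routes:
#' \describe{
#'   \item{gain_2+1}{single gain of one allele at `true_pi`; minor allele 1.}
#'   \item{gain_2+0}{single gain with LOH of the other allele.}
#'   \item{wgd_2+2}{whole-genome doubling of both alleles at `true_pi`.}
#'   \item{pre_wgd}{major CN 3 (LOH): gain at `true_pi`, then WGD at
#'     `true_wgd_time` (`true_pi <= true_wgd_time`) followed by an
#'     immediate loss of one copy.}
#'   \item{post_wgd}{major CN 3 (LOH): WGD at `true_wgd_time`, then a gain
#'     of one copy at `true_pi` (`true_pi >= true_wgd_time`).}
#' }
#'
#' @param segments list of `list(segment_id=, chrom=, start_bp=, end_bp=,
#'   route=, true_pi=)`; intervals must not overlap within a chromosome.
#' @param n_snvs_per_segment clonal SNVs simulated per segment.
#' @param clone_tree list of `list(clone_id=, parent_id= (NA for the root),
#'   samples= character subset of PT_bulk/PDX_bulk/SCS12/SCS34)`.
#' @param true_wgd_time mutation-time of the WGD for pre/post-WGD routes.
#' @param fn_rate per-sample false-negative rate for the presence table
#'   (0 = noise-free).
#' @param seed integer seed.
#' @return an `evolution_sim_config` object.
#' @export
evolution_sim_config <- function(segments, n_snvs_per_segment = 500L,
                                 clone_tree = list(
                                   list(clone_id = "clonal", parent_id = NA,
                                        samples = c("PT_bulk", "PDX_bulk",
                                                    "SCS12", "SCS34"))),
                                 true_wgd_time = 0.5,
                                 fn_rate = 0,
                                 seed = 1L) {
  for (s in segments) {
    if (!s$route %in% ROUTES)
      stop("unknown route label: ", s$route)
    if (s$true_pi < 0 || s$true_pi > 1) stop("true_pi must lie in [0,1]")
    if (s$route == "pre_wgd" && s$true_pi > true_wgd_time)
      stop("pre_wgd requires true_pi <= true_wgd_time")
    if (s$route == "post_wgd" && s$true_pi < true_wgd_time)
      stop("post_wgd requires true_pi >= true_wgd_time")
  }
  # non-overlap per chromosome
  seg_df <- do.call(rbind, lapply(segments, function(s)
    data.frame(chrom = s$chrom, start_bp = s$start_bp, end_bp = s$end_bp)))
  for (ch in unique(seg_df$chrom)) {
    d <- seg_df[seg_df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start_bp), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start_bp[-1] < d$end_bp[-nrow(d)]))
      stop("overlapping segments on ", ch)
  }
  roots <- vapply(clone_tree, function(cl) is.na(cl$parent_id), TRUE)
  if (sum(roots) != 1) stop("clone_tree must have exactly one root clone")
  structure(list(segments = segments,
                 n_snvs_per_segment = as.integer(n_snvs_per_segment),
                 clone_tree = clone_tree, true_wgd_time = true_wgd_time,
                 fn_rate = fn_rate, seed = as.integer(seed)),
            class = "evolution_sim_config")
}

# Lineage branches of the per-copy accrual model. Mutations arise at unit
# rate per copy per unit mutation time; a branch is a lineage interval over
# which every mutation ends at the same final multiplicity. Returned as
# (length, multiplicity) rows; branch probabilities are proportional to
# length. Multiplicities >= 2 are collapsed into the reported n2.
route_branches <- function(route, pi, wgd_time = NA) {
  switch(route,
    "gain_2+1" = rbind(c(pi, 2), c(1 - pi, 1), c(1 - pi, 1), c(1, 1)),
    "gain_2+0" = rbind(c(pi, 2), c(1 - pi, 1), c(1 - pi, 1)),
    "wgd_2+2"  = rbind(c(pi, 2), c(pi, 2),
                       c(1 - pi, 1), c(1 - pi, 1), c(1 - pi, 1), c(1 - pi, 1)),
    # gain at pi, WGD at wgd_time (pi <= wgd_time), immediate loss of one of
    # the four copies; major CN 3, minor 0. Pre-gain mutations -> mult 3;
    # [pi, wgd) on the lineage whose duplicate is lost -> mult 1, on the
    # surviving lineage -> mult 2; later mutations -> mult 1.
    "pre_wgd"  = rbind(c(pi, 3), c(wgd_time - pi, 1), c(wgd_time - pi, 2),
                       c(1 - wgd_time, 1), c(1 - wgd_time, 1), c(1 - wgd_time, 1)),
    # WGD at wgd_time, gain of one post-WGD copy at pi (pi >= wgd_time);
    # major CN 3, minor 0. [wgd, pi) on the copy later duplicated -> mult 2;
    # the sibling copy accrues mult-1 mutations over [wgd, 1].
    "post_wgd" = rbind(c(wgd_time, 3), c(pi - wgd_time, 2), c(1 - wgd_time, 1),
                       c(1 - pi, 1), c(1 - pi, 1)),
    stop("unknown route label: ", route))
}

#' Simulate clonal SNV multiplicities and presence patterns
#'
#' For each segment, SNV times and lineages are drawn from the per-copy
#' accrual process of the segment's route (each lineage branch picked with
#' probability proportional to its time length) and the resulting
#' multiplicity recorded; `n2` counts SNVs at multiplicity two or more.
#' Each SNV is attached to a clone of the clone tree (the root receives the
#' segment SNVs; additional clones receive private presence-pattern SNVs),
#' and presence per sample follows the union of sample memberships over the
#' clone's subtree.
#'
#' @param config an [evolution_sim_config()].
#' @param n_snvs_per_clone private SNVs simulated per non-root clone for the
#'   presence table.
#' @return list with `multiplicity` (segment_id, chrom, start_bp, end_bp,
#'   route, n1, n2), `presence` (snv table with the four sample columns,
#'   TLOD, indel flag, genotyped-cell count), and `truth`.
#' @export
simulate_clonal_snvs <- function(config, n_snvs_per_clone = 50L) {
  stopifnot(inherits(config, "evolution_sim_config"))
  set.seed(config$seed)
  n <- config$n_snvs_per_segment

  mult_rows <- list()
  truth_seg <- list()
  for (s in config$segments) {
    br <- route_branches(s$route, s$true_pi, config$true_wgd_time)
    len <- pmax(br[, 1], 0)
    mult <- br[, 2]
    pick <- sample.int(nrow(br), n, replace = TRUE, prob = len)
    m <- mult[pick]
    mult_rows[[s$segment_id]] <- data.frame(
      segment_id = s$segment_id, chrom = s$chrom, start_bp = s$start_bp,
      end_bp = s$end_bp, route = s$route,
      n1 = sum(m == 1), n2 = sum(m >= 2), stringsAsFactors = FALSE)
    truth_seg[[s$segment_id]] <- data.frame(
      segment_id = s$segment_id, route = s$route, true_pi = s$true_pi,
      true_wgd_time = if (s$route %in% c("pre_wgd", "post_wgd"))
        config$true_wgd_time else NA_real_,
      stringsAsFactors = FALSE)
  }
  multiplicity <- do.call(rbind, mult_rows)
  rownames(multiplicity) <- NULL

  # presence table: subtree membership of the SNV's clone
  ids <- vapply(config$clone_tree, `[[`, "", "clone_id")
  parents <- vapply(config$clone_tree, function(cl)
    if (is.na(cl$parent_id)) NA_character_ else cl$parent_id, "")
  samples_of <- setNames(lapply(config$clone_tree, `[[`, "samples"), ids)
  subtree_samples <- function(id) {
    kids <- ids[!is.na(parents) & parents == id]
    Reduce(union, lapply(kids, subtree_samples), samples_of[[id]])
  }
  all_samples <- c("PT_bulk", "PDX_bulk", "SCS12", "SCS34")
  snv_clone <- rep(ids, each = max(1L, n_snvs_per_clone))
  clone_pattern <- t(vapply(ids, function(id)
    as.integer(all_samples %in% subtree_samples(id)), integer(4)))
  presence <- as.data.frame(clone_pattern[match(snv_clone, ids), , drop = FALSE])
  names(presence) <- all_samples
  if (config$fn_rate > 0) {
    flip <- matrix(runif(length(as.matrix(presence))) < config$fn_rate,
                   nrow = nrow(presence))
    presence[presence == 1 & flip] <- 0L
  }
  presence <- cbind(data.frame(snv_id = sprintf("snv%05d", seq_along(snv_clone)),
                               stringsAsFactors = FALSE),
                    presence,
                    data.frame(TLOD = round(rlnorm(length(snv_clone), log(60), 0.3), 2),
                               is_indel = FALSE,
                               n_cells_genotyped = 20L + rpois(length(snv_clone), 30)))
  truth <- list(segments = do.call(rbind, truth_seg),
                snv_clone = setNames(snv_clone, presence$snv_id),
                true_wgd_time = config$true_wgd_time)
  rownames(truth$segments) <- NULL
  list(multiplicity = multiplicity, presence = presence, truth = truth)
}

#' Per-tumor event timeline
#'
#' @param tumor_id tumor identifier.
#' @param events data.frame with columns `event`, `type` (loss / gain /
#'   WGD / driver_SNV) and `clonality` (clonal / subclonal).
#' @param posteriors named list of numeric timing-posterior sample vectors
#'   (values in `[0,1]`), one entry per timed event; events without an
#'   entry are untimed.
#' @param order optional named numeric vector giving a recorded relative
#'   order (smaller = earlier) for untimed events.
#' @return a `tumor_timeline` object.
#' @export
tumor_timeline <- function(tumor_id, events, posteriors = list(), order = NULL) {
  events <- as.data.frame(events)
  stopifnot(all(c("event", "type", "clonality") %in% names(events)))
  if (anyDuplicated(events$event))
    stop("event ids must be unique within a tumor")
  bad <- setdiff(names(posteriors), events$event)
  if (length(bad)) stop("posterior for unknown event: ", bad[1])
  structure(list(tumor_id = tumor_id, events = events,
                 posteriors = posteriors, order = order),
            class = "tumor_timeline")
}

#' Simulate a cohort of per-tumor event timelines
#'
#' Each tumor contains each event independently with probability
#' `1 - dropout`; a present event's timing samples are centered on the
#' event's true rank position, mapped to `(rank - 0.5) / n_events` in
#' `[0,1]`, plus Gaussian noise truncated to `[0,1]`.
#'
#' @param true_order character vector of event ids, earliest first.
#' @param n_tumors number of tumors.
#' @param timing_noise_sd standard deviation of the timing noise.
#' @param dropout per-event missing probability in `[0,1)`.
#' @param n_samples posterior samples stored per present event.
#' @param seed integer seed.
#' @return list of [tumor_timeline()] objects.
#' @export
simulate_cohort_timelines <- function(true_order, n_tumors,
                                      timing_noise_sd = 0.05, dropout = 0,
                                      n_samples = 100L, seed = 1L) {
  if (length(true_order) < 2) stop("at least 2 events are required")
  if (dropout >= 1) stop("dropout = 1 leaves no data")
  set.seed(seed)
  centers <- (seq_along(true_order) - 0.5) / length(true_order)
  names(centers) <- true_order
  lapply(seq_len(n_tumors), function(t) {
    present <- true_order[runif(length(true_order)) >= dropout]
    post <- lapply(centers[present], function(ct) {
      pmin(1, pmax(0, ct + rnorm(n_samples, 0, timing_noise_sd)))
    })
    tumor_timeline(
      tumor_id = sprintf("tumor%02d", t),
      events = data.frame(event = present,
                          type = rep("gain", length(present)),
                          clonality = rep("clonal", length(present)),
                          stringsAsFactors = FALSE),
      posteriors = post)
  })
}
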