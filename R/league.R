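#' League-model aggregation of event order across tumors
#'
#' Round-robin scoring of genomic events. Per repetition every event starts
#' at score zero; for each unordered pair of events one tumor containing
#' both is drawn uniformly (pairs shared by no tumor are skipped), one
#' timing sample per event is drawn from that tumor's posterior, and the
#' earlier event gains one point while the later loses one. Events without
#' timing posteriors are compared through the tumor's recorded relative
#' order when available; pairs that cannot be distinguished (no order
#' information, or exactly equal draws) leave both scores unchanged. After
#' all pairs, events are ranked by descending score with ties sharing the
#' averaged rank. The repetition is run `n_iter` times to obtain a rank
#' distribution.
#'
#' @param timelines list of [tumor_timeline()] objects.
#' @param n_iter repetitions (default 100).
#' @param seed integer seed.
#' @return a `league_ranking`: list with `ranks` (n_iter x events matrix),
#'   `mean_score`, `mean_rank` and `prevalence` (fraction of tumors
#'   containing each event).
#' @export
league_rank <- function(timelines, n_iter = 100L, seed = 1L) {
  stopifnot(length(timelines) >= 1)
  events <- sort(unique(unlist(lapply(timelines, function(t) t$events$event))))
  if (length(events) < 2) stop("at least 2 events are required")
  set.seed(stage_seed(seed, "league"))

  has_event <- vapply(timelines, function(t) events %in% t$events$event,
                      logical(length(events)))
  has_event <- matrix(has_event, nrow = length(events),
                      dimnames = list(events, NULL))
  prevalence <- rowMeans(has_event)
  pairs <- combn(length(events), 2)

  draw_time <- function(tl, ev) {
    ps <- tl$posteriors[[ev]]
    if (!is.null(ps)) return(ps[sample.int(length(ps), 1L)])
    NA_real_
  }
  recorded_order <- function(tl, ev) {
    if (!is.null(tl$order) && ev %in% names(tl$order)) return(tl$order[[ev]])
    NA_real_
  }

  ranks <- matrix(NA_real_, nrow = n_iter, ncol = length(events),
                  dimnames = list(NULL, events))
  scores_acc <- numeric(length(events))
  for (it in seq_len(n_iter)) {
    score <- setNames(numeric(length(events)), events)
    for (pc in seq_len(ncol(pairs))) {
      i <- pairs[1, pc]; j <- pairs[2, pc]
      shared <- which(has_event[i, ] & has_event[j, ])
      if (!length(shared)) next
      tl <- timelines[[shared[sample.int(length(shared), 1L)]]]
      ei <- events[i]; ej <- events[j]
      ti <- draw_time(tl, ei); tj <- draw_time(tl, ej)
      if (is.na(ti) || is.na(tj)) {
        ti <- recorded_order(tl, ei); tj <- recorded_order(tl, ej)
      }
      if (is.na(ti) || is.na(tj) || ti == tj) next
      if (ti < tj) {
        score[ei] <- score[ei] + 1; score[ej] <- score[ej] - 1
      } else {
        score[ej] <- score[ej] + 1; score[ei] <- score[ei] - 1
      }
    }
    ranks[it, ] <- rank(-score, ties.method = "average")
    scores_acc <- scores_acc + score
  }
  structure(list(ranks = ranks,
                 mean_score = scores_acc / n_iter,
                 mean_rank = colMeans(ranks),
                 prevalence = prevalence),
            class = "league_ranking")
}

#' @export
print.league_ranking <- function(x, ...) {
  ord <- order(x$mean_rank)
  cat("<league_ranking>\n")
  print(data.frame(event = colnames(x$ranks)[ord],
                   mean_rank = round(x$mean_rank[ord], 2),
                   mean_score = round(x$mean_score[ord], 2),
                   prevalence = round(x$prevalence[ord], 2),
                   row.names = NULL))
  invisible(x)
}
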