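#' HMM parameters for 3-state copy-number segmentation
#'
#' Emission means are `{-delta, 0, +delta}` (loss / neutral / gain) on the
#' winsorized Z scale with a shared standard deviation `sigma`; the
#' transition matrix keeps the current state with probability `1 - 2*tau`
#' and switches to each other state with probability `tau`. When `sigma` is
#' `NULL` it is estimated as the median per-bin standard deviation across
#' meta-cells.
#'
#' @param delta emission-mean offset of the loss/gain states.
#' @param sigma shared emission standard deviation, or `NULL` to estimate.
#' @param tau per-step switch probability to each other state.
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(delta = 0.5, sigma = NULL, tau = 1e-3) {
  stopifnot(delta > 0, tau > 0, tau < 0.5)
  structure(list(delta = delta, sigma = sigma, tau = tau),
            class = "hmm_params")
}

# Emission scale for the joint (product over meta-cells) likelihood.
# Meta-cells of one community share sampled cells and are therefore
# strongly correlated, so the joint evidence for a bin behaves like
# n_meta * zbar^2 rather than a sum of independent terms; calibrating
# sigma as sqrt(n_meta) times a robust sd of the per-bin mean Z makes the
# joint log-likelihood ratio well-scaled in both the correlated and the
# independent regime (for independent meta-cells sqrt(n) * sd(zbar) is
# simply the per-meta-cell sd).
estimate_sigma <- function(z) {
  zbar <- rowMeans(z)
  s <- sqrt(ncol(z)) * stats::mad(zbar, center = median(zbar))
  if (is.finite(s) && s > 0) return(s)
  s <- sd(as.vector(z))
  if (is.finite(s) && s > 0) s else 1
}

#' Decode a shared copy-number state path from community meta-cells
#'
#' One state path is decoded per community by maximum likelihood (Viterbi),
#' restarting with a uniform initial state at each chromosome. The emission
#' probability of a bin under a state is the product over meta-cells of
#' Normal densities with the state's mean, i.e. the meta-cells share the
#' path but emit independently.
#'
#' @param z numeric matrix of processed Z-scores, bins x meta-cells.
#' @param chrom chromosome of each bin (genome-ordered).
#' @param params an [hmm_params()].
#' @return factor of per-bin states, levels `loss`, `neutral`, `gain`.
#' @export
hmm_segment <- function(z, chrom, params = hmm_params()) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("non-finite Z values")
  stopifnot(nrow(z) == length(chrom))
  sigma <- if (is.null(params$sigma)) estimate_sigma(z) else params$sigma
  mu <- c(loss = -params$delta, neutral = 0, gain = params$delta)
  # bins x 3 joint log-emissions (sum over meta-cells)
  ll <- vapply(mu, function(m) rowSums(dnorm(z, mean = m, sd = sigma, log = TRUE)),
               numeric(nrow(z)))
  if (nrow(z) == 1L) ll <- matrix(ll, nrow = 1, dimnames = list(NULL, names(mu)))
  log_stay <- log(1 - 2 * params$tau)
  log_switch <- log(params$tau)
  states <- integer(nrow(z))
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    states[rows] <- viterbi_chrom(ll[rows, , drop = FALSE], log_stay, log_switch)
  }
  factor(c("loss", "neutral", "gain")[states],
         levels = c("loss", "neutral", "gain"))
}

viterbi_chrom <- function(ll, log_stay, log_switch) {
  n <- nrow(ll)
  delta <- matrix(-Inf, n, 3)
  psi <- matrix(0L, n, 3)
  delta[1, ] <- log(1 / 3) + ll[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:3) {
        trans <- delta[t - 1, ] + ifelse(1:3 == s, log_stay, log_switch)
        psi[t, s] <- which.max(trans)
        delta[t, s] <- trans[psi[t, s]] + ll[t, s]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Set short non-neutral runs to neutral
#'
#' Every maximal loss/gain run of the input path shorter than
#' `min_seg_bins` bins is set to neutral in a single left-to-right pass;
#' runs that only become adjacent through that filtering are not merged and
#' re-filtered. Runs never extend across chromosomes.
#'
#' @param path factor/character state path (`loss`/`neutral`/`gain`).
#' @param chrom chromosome of each bin; `NULL` treats the path as one
#'   chromosome.
#' @param min_seg_bins minimum run length retained (default 5).
#' @return filtered path (same type contract as input, as factor).
#' @export
filter_short_segments <- function(path, chrom = NULL, min_seg_bins = 5L) {
  p <- as.character(path)
  if (is.null(chrom)) chrom <- rep("chr", length(p))
  out <- p
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    r <- rle(p[rows])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] != "neutral" && r$lengths[i] < min_seg_bins) {
        out[rows[starts[i]:ends[i]]] <- "neutral"
      }
    }
  }
  factor(out, levels = c("loss", "neutral", "gain"))
}

#' Tile a state path into segments
#'
#' @param path per-bin state factor.
#' @param bins bin annotation data.frame (`chrom`, `start`, `end`).
#' @return data.frame of segments: `chrom`, `first_bin`, `last_bin`
#'   (inclusive, genome-ordered global bin indices), `state`, `n_bins`,
#'   `start`, `end` (bp, 0-based half-open).
#' @export
path_to_segments <- function(path, bins) {
  p <- as.character(path)
  segs <- list()
  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    r <- rle(p[rows])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs[[ch]] <- data.frame(
      chrom = ch,
      first_bin = rows[starts], last_bin = rows[ends],
      state = r$values, n_bins = r$lengths,
      start = bins$start[rows[starts]], end = bins$end[rows[ends]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
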