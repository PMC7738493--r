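# Pair scaffolding shared by the clustering profiles: unordered pair
# indices, cortical distances and 75-um distance-bin assignment.
.pair_bins <- function(x_um, y_um, bin_um = 75, max_dist = NULL) {
  n <- length(x_um)
  if (n < 2L) stop("need at least 2 cells")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  d <- sqrt((x_um[i] - x_um[j])^2 + (y_um[i] - y_um[j])^2)
  if (is.null(max_dist)) max_dist <- max(d)
  keep <- d <= max_dist
  bin <- floor(d[keep] / bin_um)  # half-open [k*bin, (k+1)*bin)
  list(i = i[keep], j = j[keep], d = d[keep], bin = bin,
       bins = 0:max(bin), bin_um = bin_um)
}

.tier <- function(p) {
  ifelse(is.na(p), "untested",
         ifelse(p < 0.001, "p<0.001", ifelse(p < 0.01, "p<0.01", "ns")))
}

#' Pairwise similarity versus cortical distance
#'
#' Bins all unordered cell pairs by cortical distance (75 um half-open
#' bins) and computes the Pearson correlation coefficient between the
#' paired parameter values within each bin, with a parametric p-value
#' (or a position-shuffle p-value if `method = "shuffle"`). Bins with
#' fewer than 3 pairs are flagged and not tested.
#'
#' @param values Numeric parameter per cell.
#' @param x_um,y_um Cortical positions, um.
#' @param bin_um Distance bin width, um (75 by default).
#' @param method `"pearson"` (parametric p) or `"shuffle"`.
#' @param n_shuffles,seed Shuffle settings when `method = "shuffle"`.
#' @param max_dist Optional cap on pair distance, um.
#' @return A data.frame of class `clustering_profile`: `bin_lo`,
#'   `bin_hi` (um), `n_pairs`, `r`, `p`, `tier` (`ns`, `p<0.01`,
#'   `p<0.001`, `untested`), `tested`.
#' @export
pairwise_profile <- function(values, x_um, y_um, bin_um = 75,
                             method = c("pearson", "shuffle"),
                             n_shuffles = 1000L, seed = 1L,
                             max_dist = NULL) {
  method <- match.arg(method)
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("need at least 2 cells with finite values")
  values <- values[ok]; x_um <- x_um[ok]; y_um <- y_um[ok]
  pb <- .pair_bins(x_um, y_um, bin_um, max_dist)

  stat_fun <- function(v) {
    vapply(pb$bins, function(b) {
      sel <- pb$bin == b
      if (sum(sel) < 3L) return(NA_real_)
      suppressWarnings(stats::cor(v[pb$i[sel]], v[pb$j[sel]]))
    }, numeric(1))
  }
  r <- stat_fun(values)
  n_pairs <- vapply(pb$bins, function(b) sum(pb$bin == b), integer(1))

  if (method == "pearson") {
    p <- vapply(seq_along(pb$bins), function(k) {
      if (is.na(r[k]) || n_pairs[k] < 3L) return(NA_real_)
      rr <- max(-1 + 1e-12, min(1 - 1e-12, r[k]))
      df <- n_pairs[k] - 2L
      tt <- rr * sqrt(df / (1 - rr^2))
      2 * stats::pt(-abs(tt), df)
    }, numeric(1))
  } else {
    p <- .shuffle_p(values, pb, stat_fun, r, n_shuffles, seed)
  }
  structure(data.frame(bin_lo = pb$bins * bin_um,
                       bin_hi = (pb$bins + 1) * bin_um,
                       n_pairs = n_pairs, r = r, p = p, tier = .tier(p),
                       tested = !is.na(p)),
            class = c("clustering_profile", "data.frame"))
}

#' Circular orientation clustering versus cortical distance
#'
#' Within each 75-um distance bin computes the circular pair statistic
#' `r = Re < exp(2i * (ORI_i - ORI_j)) >`, i.e. the mean of
#' `cos(2 * delta)` over pairs: 1 when paired orientations always agree,
#' approaching 0 for independent orientations. Significance per bin is
#' a one-sided position-shuffle test.
#'
#' @param ori Preferred orientations, degrees in \[0, 180).
#' @inheritParams pairwise_profile
#' @return A `clustering_profile` data.frame (see [pairwise_profile()]).
#' @export
circular_ori_profile <- function(ori, x_um, y_um, bin_um = 75,
                                 n_shuffles = 1000L, seed = 1L,
                                 max_dist = NULL) {
  if (any(ori < 0 | ori >= 180)) stop("'ori' must lie in [0, 180)")
  pb <- .pair_bins(x_um, y_um, bin_um, max_dist)
  stat_fun <- function(v) {
    vapply(pb$bins, function(b) {
      sel <- pb$bin == b
      if (sum(sel) < 3L) return(NA_real_)
      mean(cos(2 * (v[pb$i[sel]] - v[pb$j[sel]]) * pi / 180))
    }, numeric(1))
  }
  r <- stat_fun(ori)
  n_pairs <- vapply(pb$bins, function(b) sum(pb$bin == b), integer(1))
  p <- .shuffle_p(ori, pb, stat_fun, r, n_shuffles, seed)
  structure(data.frame(bin_lo = pb$bins * bin_um,
                       bin_hi = (pb$bins + 1) * bin_um,
                       n_pairs = n_pairs, r = r, p = p, tier = .tier(p),
                       tested = !is.na(p)),
            class = c("clustering_profile", "data.frame"))
}

# One-sided exceedance p per bin under position shuffling (values are
# permuted across the fixed positions), with add-one smoothing.
.shuffle_p <- function(values, pb, stat_fun, observed, n_shuffles, seed,
                       add_one = TRUE) {
  rng <- .local_rng(seed)
  n <- length(values)
  exceed <- rep(0L, length(observed))
  valid <- rep(0L, length(observed))
  for (s in seq_len(n_shuffles)) {
    v <- values[rng$sample(n)]
    rs <- stat_fun(v)
    cmp <- rs >= observed
    upd <- !is.na(cmp)
    exceed[upd] <- exceed[upd] + cmp[upd]
    valid[upd] <- valid[upd] + 1L
  }
  p <- if (add_one) (1 + exceed) / (1 + valid) else exceed / valid
  p[is.na(observed) | valid == 0L] <- NA_real_
  p
}

#' Position-shuffle significance for a clustering profile
#'
#' Recomputes a distance-binned pair statistic under `n_shuffles` random
#' permutations of the neuron locations (equivalently, of the values
#' across the fixed positions) and returns the one-sided exceedance
#' proportion per bin: the fraction of shuffles yielding clustering at
#' least as strong as observed, with add-one smoothing by default (so the
#' smallest attainable p is `1/(n_shuffles + 1)`).
#'
#' @param values Numeric parameter per cell (orientations in degrees when
#'   `stat = "circular"`).
#' @param x_um,y_um Cortical positions, um.
#' @param stat `"pearson"` or `"circular"` pair statistic.
#' @param bin_um Bin width, um.
#' @param n_shuffles Number of permutations (1000 by default).
#' @param seed Integer seed.
#' @param add_one Use add-one smoothing (default TRUE).
#' @return List: `observed` (per-bin statistic), `p` (per-bin one-sided
#'   p), `bin_lo`, `bin_hi`, `n_pairs`.
#' @export
shuffle_significance <- function(values, x_um, y_um,
                                 stat = c("pearson", "circular"),
                                 bin_um = 75, n_shuffles = 1000L,
                                 seed = 1L, add_one = TRUE) {
  stat <- match.arg(stat)
  pb <- .pair_bins(x_um, y_um, bin_um)
  stat_fun <- if (stat == "pearson") {
    function(v) vapply(pb$bins, function(b) {
      sel <- pb$bin == b
      if (sum(sel) < 3L) return(NA_real_)
      suppressWarnings(stats::cor(v[pb$i[sel]], v[pb$j[sel]]))
    }, numeric(1))
  } else {
    function(v) vapply(pb$bins, function(b) {
      sel <- pb$bin == b
      if (sum(sel) < 3L) return(NA_real_)
      mean(cos(2 * (v[pb$i[sel]] - v[pb$j[sel]]) * pi / 180))
    }, numeric(1))
  }
  observed <- stat_fun(values)
  p <- .shuffle_p(values, pb, stat_fun, observed, n_shuffles, seed, add_one)
  list(observed = observed, p = p, bin_lo = pb$bins * bin_um,
       bin_hi = (pb$bins + 1) * bin_um,
       n_pairs = vapply(pb$bins, function(b) sum(pb$bin == b), integer(1)))
}
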