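# Reconstruction comparison statistics: per-dwell Euclidean distances,
# k = 2 reproducibility, interobserver reference averaging, and paired
# significance tests (exact Wilcoxon signed-rank, paired t).
#
# Reconstructions are exchanged as "dwell maps": named lists keyed by
# channel id, each an n x 3 matrix of dwell positions (distal first).
# Matching is strictly by (channel, dwell index) -- the afterloader channel
# link removes any assignment ambiguity, so nearest-neighbour matching is
# deliberately absent.

#' Coerce a reconstruction into a dwell map
#'
#' Accepts a list of `"reconstructed_needle"` or [dwell_set()] objects, the
#' output of [plan_dwells()], or an already-named list of n x 3 matrices.
#'
#' @param recon A reconstruction in any of the supported forms.
#' @return A named list of n x 3 matrices, keyed by channel id (ascending).
#' @export
as_dwell_map <- function(recon) {
  if (is.list(recon) && !is.null(names(recon)) &&
      all(vapply(recon, is.matrix, logical(1))))
    return(recon[order(as.integer(names(recon)))])
  out <- list()
  for (el in recon) {
    if (inherits(el, "reconstructed_needle")) {
      out[[as.character(el$channel_id)]] <- el$dwells$positions
    } else if (inherits(el, "dwell_set")) {
      out[[as.character(el$channel_id)]] <- el$positions
    } else if (is.list(el) && !is.null(el$dwells)) {
      out[[as.character(el$channel_id)]] <- el$dwells$positions
    } else if (is.matrix(el)) {
      out[[as.character(length(out) + 1)]] <- el
    } else stop("unrecognized reconstruction element")
  }
  out[order(as.integer(names(out)))]
}

check_same_structure <- function(maps) {
  ids <- names(maps[[1]])
  for (m in maps[-1]) {
    if (!identical(names(m), ids))
      stop("reconstructions have different channels: ",
           paste(ids, collapse = ","), " vs ",
           paste(names(m), collapse = ","))
    for (ch in ids)
      if (nrow(m[[ch]]) != nrow(maps[[1]][[ch]]))
        stop("channel ", ch, ": dwell counts differ (",
             nrow(maps[[1]][[ch]]), " vs ", nrow(m[[ch]]), ")")
  }
  invisible(TRUE)
}

#' Per-dwell Euclidean distances between two reconstructions
#'
#' @param recon_a,recon_b Reconstructions (see [as_dwell_map()]) with the
#'   same channels and per-channel dwell counts.
#' @param dwell_times Optional list keyed by channel of dwell times (s), for
#'   time-weighted displays; never used in the statistics.
#' @return A data frame of class `"dwell_match"`: `channel`, `dwell_index`
#'   (0-based, distal first), per-axis deviations `dx dy dz` (a minus b),
#'   `ed` (mm) and optional `dwell_time`.
#' @export
match_and_ed <- function(recon_a, recon_b, dwell_times = NULL) {
  a <- as_dwell_map(recon_a); b <- as_dwell_map(recon_b)
  check_same_structure(list(a, b))
  rows <- lapply(names(a), function(ch) {
    d <- a[[ch]] - b[[ch]]
    df <- data.frame(channel = as.integer(ch),
                     dwell_index = seq_len(nrow(d)) - 1L,
                     dx = d[, 1], dy = d[, 2], dz = d[, 3],
                     ed = sqrt(rowSums(d^2)))
    if (!is.null(dwell_times)) df$dwell_time <- dwell_times[[ch]]
    df
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dwell_match", class(out))
  out
}

#' Summary of an agreement comparison
#'
#' Mean and 2 SD of the per-dwell Euclidean distances and per-axis
#' deviations, plus median and range as conventionally reported.
#'
#' @param matches A `"dwell_match"` data frame from [match_and_ed()].
#' @return A list of class `"agreement_report"`.
#' @export
agreement_report <- function(matches) {
  per_axis <- sapply(c("dx", "dy", "dz"), function(a)
    c(mean = mean(matches[[a]]), two_sd = 2 * stats::sd(matches[[a]])))
  structure(list(
    mean_ed = mean(matches$ed),
    ed_2sd = 2 * stats::sd(matches$ed),
    median_ed = stats::median(matches$ed),
    range_ed = range(matches$ed),
    per_axis = per_axis,
    n = nrow(matches)), class = "agreement_report")
}

#' k = 2 reproducibility of repeated reconstructions
#'
#' For every dwell, deviations of each repeat from the across-repeat mean
#' position are pooled; per-axis k2 is twice the pooled within-dwell
#' standard deviation (sum of squares over `n_dwells * (n_repeats - 1)`
#' degrees of freedom, the unbiased within-group estimate).  Radial k2 is
#' twice the standard deviation of the pooled Euclidean deviations from the
#' per-dwell mean.
#'
#' @param repeats List of >= 2 reconstructions of the same implant.
#' @return A list of class `"reproducibility_report"`: `k2` (named x/y/z,
#'   mm), `radial_k2` (mm), `n_repeats`, `n_dwells`.
#' @export
reproducibility_k2 <- function(repeats) {
  if (length(repeats) < 2) stop("need >= 2 repeated reconstructions")
  maps <- lapply(repeats, as_dwell_map)
  check_same_structure(maps)
  stacks <- lapply(maps, function(m) do.call(rbind, m))  # (dwells) x 3
  arr <- simplify2array(stacks)                          # d x 3 x r
  mu <- apply(arr, c(1, 2), mean)
  dev <- sweep(arr, c(1, 2), mu)                         # deviations
  r <- length(repeats); d <- nrow(mu)
  df <- d * (r - 1)
  k2 <- 2 * sqrt(apply(dev^2, 2, sum) / df)
  names(k2) <- c("x", "y", "z")
  radial <- sqrt(apply(dev^2, c(1, 3), sum))             # d x r distances
  structure(list(k2 = k2, radial_k2 = 2 * stats::sd(as.numeric(radial)),
                 n_repeats = r, n_dwells = d),
            class = "reproducibility_report")
}

#' Average several observers' reconstructions into a reference
#'
#' The reference is the per-dwell coordinate-wise mean; the interobserver
#' spread is the k = 2 statistic of the observer deviations.
#'
#' @param recons List of structurally identical reconstructions (typically
#'   three observers).
#' @return A list: `average` (dwell map), `spread` (a
#'   `"reproducibility_report"`).
#' @export
reference_average <- function(recons) {
  if (length(recons) < 2) stop("need >= 2 observer reconstructions")
  maps <- lapply(recons, as_dwell_map)
  check_same_structure(maps)
  avg <- maps[[1]]
  for (ch in names(avg)) {
    acc <- Reduce(`+`, lapply(maps, `[[`, ch))
    avg[[ch]] <- acc / length(maps)
  }
  list(average = avg, spread = reproducibility_k2(recons))
}

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Zeros are dropped (with a flag); ties are handled by midranks.  For
#' n <= `exact_max` the null distribution of the signed-rank sum is obtained
#' by exact enumeration over all 2^n sign assignments (computed by the
#' distribution-counting convolution, which also covers tied ranks); for
#' larger n a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param d Paired differences.
#' @param exact_max Largest n for exact enumeration.
#' @return A list: `p` (two-sided), `statistic` (W+), `n` (nonzero pairs),
#'   `exact`, `all_zero` flag.
#' @export
signed_rank_test <- function(d, exact_max = 25) {
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("signed-rank test needs >= 2 paired differences")
  nz <- d[d != 0]
  if (!length(nz))
    return(list(p = 1, statistic = 0, n = 0, exact = TRUE, all_zero = TRUE))
  n <- length(nz)
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  if (n <= exact_max) {
    # integer grid: double the ranks so midranks (x.5) become integers
    r2 <- as.integer(round(2 * r))
    # f[k+1] = number of sign vectors with doubled W+ = k
    f <- numeric(sum(r2) + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):length(f)] <- g[(ri + 1):length(f)] + f[1:(length(f) - ri)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[1:(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(p = p, statistic = w, n = n, exact = TRUE,
                all_zero = FALSE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(p = min(1, 2 * stats::pnorm(-abs(z))), statistic = w, n = n,
       exact = FALSE, all_zero = FALSE)
}

#' Paired significance tests for comparison deltas
#'
#' Two-sided exact Wilcoxon signed-rank (for dose-metric deltas) and
#' two-sided paired Student t (for axis deviations), as conventionally
#' reported together.
#'
#' @param d Paired differences (n >= 5 recommended; n >= 2 required).
#' @return A list: `p_signed_rank`, `p_t`, `n`, `all_zero`.
#' @export
paired_tests <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("paired tests need >= 2 differences")
  sr <- signed_rank_test(d)
  pt <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
  list(p_signed_rank = sr$p, p_t = pt, n = length(d),
       all_zero = sr$all_zero)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d dwells: ED %.2f (+/- %.2f) mm, median %.2f (%.2f - %.2f) mm\n",
              x$n, x$mean_ed, x$ed_2sd, x$median_ed, x$range_ed[1],
              x$range_ed[2]))
  for (a in colnames(x$per_axis))
    cat(sprintf("  %s: %.2f (+/- %.2f) mm\n", sub("d", "", a),
                x$per_axis["mean", a], x$per_axis["two_sd", a]))
  invisible(x)
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("reproducibility (k = 2) over %d repeats x %d dwells:\n",
              x$n_repeats, x$n_dwells))
  cat(sprintf("  per-axis: x %.3f, y %.3f, z %.3f mm; radial %.3f mm\n",
              x$k2["x"], x$k2["y"], x$k2["z"], x$radial_k2))
  invisible(x)
}
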