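# Conversion of continuous densitometry-style time profiles to on/off
# profiles: background subtraction followed by Kapur maximum-entropy
# thresholding.  Profiles are plain data.frames with columns `node`, `t`,
# and `value` (continuous) or `bit` (binary).

check_profile <- function(profile) {
  req <- c("node", "t", "value")
  if (!all(req %in% names(profile)))
    stop("profile needs columns ", paste(req, collapse = ", "))
  if (any(!is.finite(profile$value)))
    stop("profile contains non-finite intensities")
  if (any(profile$value < 0))
    stop("profile contains negative intensities")
  for (n in unique(profile$node)) {
    tt <- profile$t[profile$node == n]
    if (length(tt) < 2L)
      stop("profile for '", n, "' has fewer than 2 samples")
    if (any(diff(tt) <= 0))
      stop("minutes must be strictly increasing for '", n, "'")
  }
  invisible(profile)
}

#' Subtract the background level of an intensity profile
#'
#' Subtracts each node's minimum intensity (the lane background), flooring
#' at 0.  Ranks are preserved: this is a monotone shift per node.
#'
#' @param profile data.frame with columns `node`, `t`, `value`.
#' @return the profile with background-subtracted `value`.
#' @export
subtract_background <- function(profile) {
  check_profile(profile)
  for (n in unique(profile$node)) {
    i <- profile$node == n
    profile$value[i] <- pmax(profile$value[i] - min(profile$value[i]), 0)
  }
  profile
}

#' Kapur maximum-entropy threshold
#'
#' Computes the binarization threshold that maximizes the sum of the
#' Shannon entropies of the background (<= threshold) and foreground
#' (> threshold) classes, over a histogram of the min-max-normalized
#' values.  Ties are broken toward the lower threshold by default.
#' The criterion is invariant under positive affine rescaling of the
#' input.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param bins histogram bin count (default 256).
#' @param ties `"lower"` (default) or `"upper"`: which maximizer to return
#'   when several bins attain the maximum entropy sum.
#' @return the threshold, on the original value scale (a bin boundary;
#'   classify by `value > threshold`).
#' @examples
#' max_entropy_threshold(c(rep(0.1, 50), rep(0.9, 50)))
#' @export
max_entropy_threshold <- function(values, bins = 256L,
                                  ties = c("lower", "upper")) {
  ties <- match.arg(ties)
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  lo <- min(values); hi <- max(values)
  if (hi == lo)
    stop("all values are identical: no threshold separates two classes")
  x <- (values - lo) / (hi - lo)
  # bin k covers ((k-1)/bins, k/bins]; value 0 goes to bin 1
  bin <- pmin(pmax(ceiling(x * bins), 1L), bins)
  p <- tabulate(bin, nbins = bins) / length(values)
  scores <- entropy_sum_curve(p)
  best <- if (ties == "lower") which.max(scores) else {
    mx <- max(scores); max(which(scores == mx))
  }
  lo + (hi - lo) * best / bins
}

# entropy sum H_background + H_foreground for every split after bin T,
# T = 1..bins-1; -Inf where a class is empty.  0 * log 0 taken as 0.
entropy_sum_curve <- function(p) {
  bins <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Ptot <- P[bins]; Stot <- S[bins]
  T <- seq_len(bins - 1L)
  Pb <- P[T]; Pf <- Ptot - Pb
  hb <- ifelse(Pb > 0, log(Pb) - S[T] / Pb, -Inf)
  hf <- ifelse(Pf > 0, log(Pf) - (Stot - S[T]) / Pf, -Inf)
  hb + hf
}

#' Binarize an intensity profile
#'
#' Background subtraction ([subtract_background()]) followed by Kapur
#' maximum-entropy thresholding per node; a sample is on when its
#' subtracted value exceeds the node's threshold.
#'
#' @inheritParams subtract_background
#' @inheritParams max_entropy_threshold
#' @return data.frame with columns `node`, `t`, `bit`.
#' @export
binarize_profile <- function(profile, bins = 256L,
                             ties = c("lower", "upper")) {
  ties <- match.arg(ties)
  profile <- subtract_background(profile)
  out <- lapply(unique(profile$node), function(n) {
    sub <- profile[profile$node == n, ]
    thr <- max_entropy_threshold(sub$value, bins = bins, ties = ties)
    data.frame(node = n, t = sub$t, bit = as.integer(sub$value > thr))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write profile CSVs
#'
#' Continuous profiles have columns `node,t,value`; binary profiles
#' `node,t,bit`.
#'
#' @param path file path.
#' @export
read_profiles <- function(path) utils::read.csv(path)

#' @rdname read_profiles
#' @param profile data.frame.
#' @export
write_profiles <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
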