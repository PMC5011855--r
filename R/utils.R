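#' Round half away from zero
#'
#' Base R rounds half-to-even; published clinical tables round half-up.
#' A tiny epsilon guards against binary representation of exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# abbreviations used in the cohort CSV column names
.scale_abbr <- c(
  total = "total", symptoms = "sym", functional = "fun", mental = "men",
  activities = "act", impact = "imp"
)

score_col <- function(instrument, scale, timepoint) {
  paste0(instrument, "_", .scale_abbr[[scale]], "_", timepoint)
}

match_instrument <- function(instrument) {
  rlang::arg_match0(tolower(instrument), c("ccq", "cat", "sgrq"))
}

match_scale <- function(scale) {
  rlang::arg_match0(scale, names(.scale_abbr))
}

# Moments of a normal clipped (not truncated: mass piles at the bounds)
# to [lo, hi]. Closed form via the standard normal cdf/pdf.
clipped_normal_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  ez <- a * pa + (da - db) + b * (1 - pb)
  ez2 <- a^2 * pa + b^2 * (1 - pb) + (pb - pa) + a * da - b * db
  m <- mu + sigma * ez
  v <- sigma^2 * (ez2 - ez^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Find (mu, sigma) such that the clipped-normal mean/sd hit the targets.
# Fixed-point iteration, at most `max_iter` rounds, 1% relative tolerance.
calibrate_clipped_normal <- function(target_mean, target_sd, lo, hi,
                                     max_iter = 20, tol = 0.01) {
  mu <- target_mean; sigma <- target_sd
  for (i in seq_len(max_iter)) {
    m <- clipped_normal_moments(mu, sigma, lo, hi)
    if (abs(m$mean - target_mean) <= tol * max(abs(target_mean), target_sd) &&
        abs(m$sd - target_sd) <= tol * target_sd) break
    mu <- mu + (target_mean - m$mean)
    sigma <- sigma * target_sd / max(m$sd, 1e-8)
  }
  list(mu = mu, sigma = sigma)
}

# Allocate n into categories with the given probabilities by largest
# remainder, so realized strata sizes match the targets as closely as an
# integer partition allows.
allocate_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  cnt
}
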