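#' Penetrance with a Wilson score interval
#'
#' Penetrance is the fraction of scored animals showing the phenotype. The
#' Wilson score interval is used because screen penetrances often sit near
#' 0% or 100%, where the Wald interval degenerates.
#'
#' @param k Affected count(s).
#' @param n Scored count(s), >= 1.
#' @param level Confidence level. Default 0.95.
#' @return Tibble: `k`, `n`, `proportion` (percent), `display` (percent
#'   rounded half-up to one decimal, the conventional reporting format),
#'   `ci_low`, `ci_high` (percent).
#' @examples
#' penetrance(85, 91)
#' @export
penetrance <- function(k, n, level = 0.95) {
  if (any(n < 1)) abort("n must be >= 1")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  ci <- wilson_interval(k, n, level)
  tibble(k = k, n = n, proportion = 100 * k / n,
         display = round_half_up(100 * k / n, 1),
         ci_low = 100 * ci$low, ci_high = 100 * ci$high)
}

# Wilson score interval on the proportion scale
wilson_interval <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Compare two penetrance results
#'
#' Difference of proportions with the Newcombe hybrid-score interval (built
#' from the two groups' Wilson limits) and a two-sided Fisher exact p-value
#' from the 2x2 table.
#'
#' @param a,b One-row tibbles from [penetrance()].
#' @param level Confidence level for the difference interval.
#' @return One-row tibble: `diff` (percent, a minus b), `ci_low`, `ci_high`
#'   (percent), `p_value`.
#' @export
compare_penetrance <- function(a, b, level = 0.95) {
  p1 <- a$k / a$n
  p2 <- b$k / b$n
  w1 <- wilson_interval(a$k, a$n, level)
  w2 <- wilson_interval(b$k, b$n, level)
  d <- p1 - p2
  lo <- d - sqrt((p1 - w1$low)^2 + (w2$high - p2)^2)
  hi <- d + sqrt((w1$high - p1)^2 + (p2 - w2$low)^2)
  tab <- matrix(c(a$k, a$n - a$k, b$k, b$n - b$k), nrow = 2)
  p <- fisher.test(tab)$p.value
  tibble(diff = 100 * d, ci_low = 100 * lo, ci_high = 100 * hi, p_value = p)
}

#' Check a reported percentage against its denominator
#'
#' Published penetrance tables print a percentage and an n; this checker
#' asks whether any integer count k in 0..n yields the printed percentage
#' after rounding half-up to one decimal — and recovers k when it is
#' unique. Rows with no consistent k are arithmetically inconsistent as
#' printed.
#'
#' @param percent Printed percentage(s), one decimal.
#' @param n Printed denominator(s).
#' @return Tibble: `percent`, `n`, `consistent`, `k` (the unique consistent
#'   count, NA if none or ambiguous), `n_matches`.
#' @examples
#' check_reported_percent(c(93.4, 80.1), c(91, 108))
#' @export
check_reported_percent <- function(percent, n) {
  res <- map2(percent, n, function(p, nn) {
    ks <- 0:nn
    hit <- ks[round_half_up(100 * ks / nn, 1) == p]
    tibble(percent = p, n = nn, consistent = length(hit) > 0,
           k = if (length(hit) == 1) hit else NA_integer_,
           n_matches = length(hit))
  })
  bind_rows(res)
}

#' Estimate nuclear ploidy from integrated DNA-stain intensity
#'
#' Endoreduplicating nuclei carry 2^j-fold the diploid DNA content. Each
#' nucleus's integrated intensity I is normalized to the mean intensity of
#' the reference (2N, e.g. neuronal) nuclei: `ploidy = 2 * I / mean(I_ref)`,
#' then assigned to the nearest power-of-two class `2^round(log2(ploidy/2))
#' * 2` (ties to the even exponent). Estimates are scale-invariant in the
#' intensity units.
#'
#' @param nuclei Data frame with columns `nucleus_id`, `intensity`
#'   (positive), `is_reference` (logical; at least one `TRUE`).
#' @return Tibble: `nucleus_id`, `intensity`, `is_reference`, `ploidy`
#'   (continuous), `ploidy_class` (numeric, e.g. 8 for "8N"), `class_label`.
#' @examples
#' estimate_ploidy(data.frame(nucleus_id = c("r1", "a"),
#'                            intensity = c(10, 160),
#'                            is_reference = c(TRUE, FALSE)))
#' @export
estimate_ploidy <- function(nuclei) {
  nuclei <- as_tibble(nuclei)
  if (!any(nuclei$is_reference)) abort("need at least one reference nucleus")
  if (any(nuclei$intensity <= 0)) abort("intensities must be positive")
  iref <- mean(nuclei$intensity[nuclei$is_reference])
  ploidy <- 2 * nuclei$intensity / iref
  cls <- 2^round(log2(ploidy / 2)) * 2
  mutate(nuclei, ploidy = ploidy, ploidy_class = cls,
         class_label = paste0(format(cls, trim = TRUE, scientific = FALSE), "N"))
}
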