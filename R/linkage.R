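#' Mapping-strain allele frequencies at the markers
#'
#' Computes the observed mapping-strain allele fraction
#' `f = map_count / (ref_count + map_count)` at every marker whose total
#' depth reaches `min_depth`; shallower markers are excluded and counted.
#' In a pool of phenotype-selected homozygous mutant F2s, `f` is depressed
#' toward 0 near the causal locus and sits near 0.5 elsewhere.
#'
#' @param counts Allele-count tibble (`chrom`, `pos`, `ref_count`,
#'   `map_count`), e.g. from [simulate_pool_readcounts()] or
#'   [read_pool_vcf()].
#' @param min_depth Minimum total depth per marker. Default 5, enough to
#'   suppress error-driven outliers at near-zero coverage.
#' @return A `freq_profile` tibble: `chrom`, `pos`, `depth`, `observed`
#'   (with attribute `n_below_depth`). Use [fit_profile()] to add the
#'   smoothed curve.
#' @export
marker_allele_frequencies <- function(counts, min_depth = 5) {
  counts <- as_tibble(counts)
  depth <- counts$ref_count + counts$map_count
  keep <- depth >= min_depth
  if (!any(keep)) abort("no marker passes the depth filter on any chromosome")
  dp <- depth[keep]
  out <- tibble(chrom = counts$chrom[keep], pos = counts$pos[keep],
                depth = dp, observed = counts$map_count[keep] / dp)
  out <- sort_by_chrom_pos(out)
  attr(out, "n_below_depth") <- sum(!keep)
  class(out) <- c("freq_profile", class(out))
  out
}

#' Tricube-weighted local polynomial (Loess) smoother
#'
#' First-principles Loess: for each point `x[i]`, the `ceiling(span * n)`
#' nearest neighbours by `|x - x[i]|` receive tricube weights
#' `w = (1 - (d/dmax)^3)^3`, a weighted least-squares polynomial of the
#' configured degree is fitted, and the fit is evaluated at `x[i]`. No
#' robustness iterations. Duplicate-x degeneracies (all weights zero or a
#' singular design) fall back to the weighted/plain local mean.
#'
#' @param x Numeric predictor (sorted internally if not).
#' @param y Numeric response, same length.
#' @param span Fraction of points in each local fit, in `(0, 1]`. Default
#'   0.3.
#' @param degree Local polynomial degree, 0 or 1. Default 1.
#' @return Fitted values at the input `x`, in input order; finite
#'   everywhere.
#' @examples
#' x <- seq(0, 10, length.out = 50)
#' loess_fit(x, sin(x) + rnorm(50, sd = 0.1))
#' @export
loess_fit <- function(x, y, span = 0.3, degree = 1) {
  stopifnot(length(x) == length(y), degree %in% c(0, 1))
  if (span <= 0 || span > 1) abort("span must be in (0, 1]")
  n <- length(x)
  if (n < degree + 1) abort("need at least degree + 1 points")
  q <- ceiling(span * n)
  if (q < degree + 1) {
    abort("span * n too small for the requested degree")
  }
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    nb <- order(d)[seq_len(q)]
    dmax <- max(d[nb])
    w <- if (dmax == 0) rep(1, q) else pmax(0, (1 - (d[nb] / dmax)^3))^3
    xw <- x[nb]
    yw <- y[nb]
    if (sum(w) == 0) {  # unreachable with tricube unless all d equal dmax = 0
      fitted[i] <- mean(yw)
      next
    }
    if (degree == 0) {
      fitted[i] <- sum(w * yw) / sum(w)
    } else {
      sw <- sum(w)
      xbar <- sum(w * xw) / sw
      ybar <- sum(w * yw) / sw
      sxx <- sum(w * (xw - xbar)^2)
      if (sxx <= 0) {
        fitted[i] <- ybar
      } else {
        beta <- sum(w * (xw - xbar) * (yw - ybar)) / sxx
        fitted[i] <- ybar + beta * (x[i] - xbar)
      }
    }
  }
  fitted
}

#' Fit the per-chromosome Loess curve of a frequency profile
#'
#' Applies [loess_fit()] independently within each chromosome, on observed
#' frequency versus physical position (unweighted by depth).
#'
#' @param profile A `freq_profile` from [marker_allele_frequencies()].
#' @inheritParams loess_fit
#' @return The profile tibble with a `fitted` column added.
#' @export
fit_profile <- function(profile, span = 0.3, degree = 1) {
  out <- profile |>
    group_by(.data$chrom) |>
    mutate(fitted = loess_fit(.data$pos, .data$observed, span = span,
                              degree = degree)) |>
    ungroup()
  class(out) <- c("freq_profile", class(tibble()))
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  out
}

#' Call the linked chromosome
#'
#' The linked chromosome is the one whose fitted frequency curve dips
#' lowest, provided that minimum falls below `link_threshold` (default
#' 0.25, the midpoint between the causal expectation 0 and the unlinked
#' expectation 0.5). Ties are broken by chromosome order with a warning.
#'
#' @param profile A fitted `freq_profile` (see [fit_profile()]).
#' @param link_threshold Frequency below which a chromosome can be called
#'   linked.
#' @return A `linkage_call` object: tibble of per-chromosome minima
#'   (`chrom`, `min_fitted`, `argmin_pos`, `linked`) with the called
#'   chromosome flagged.
#' @export
call_linked_chromosome <- function(profile, link_threshold = 0.25) {
  if (!"fitted" %in% names(profile)) {
    abort("profile has no fitted curve; run fit_profile() first")
  }
  per <- profile |>
    group_by(.data$chrom) |>
    summarise(min_fitted = min(.data$fitted),
              argmin_pos = .data$pos[which.min(.data$fitted)],
              .groups = "drop")
  # keep chromosome order as in the profile, not alphabetical
  per <- per[match(unique(profile$chrom), per$chrom), ]
  per$linked <- FALSE
  best <- min(per$min_fitted)
  if (best < link_threshold) {
    hits <- which(per$min_fitted == best)
    if (length(hits) > 1) {
      warn("tie in minimum fitted frequency; taking the first chromosome")
    }
    per$linked[hits[1]] <- TRUE
  }
  structure(per, class = c("linkage_call", class(tibble())),
            threshold = link_threshold)
}

#' Candidate interval around the linkage minimum
#'
#' The maximal contiguous run of markers whose fitted frequency lies below
#' `interval_threshold` and which contains the curve's argmin; endpoints are
#' the outermost such marker positions. Never empty: it always contains at
#' least the argmin marker.
#'
#' @param profile A fitted `freq_profile`.
#' @param call A `linkage_call` from [call_linked_chromosome()].
#' @param interval_threshold Frequency ceiling for interval membership.
#'   Default 0.25.
#' @return One-row tibble: `chrom`, `start`, `end`, `min_fitted`.
#' @export
candidate_interval <- function(profile, call, interval_threshold = 0.25) {
  if (!any(call$linked)) abort("no linked chromosome; cannot form an interval")
  ch <- call$chrom[call$linked][1]
  p <- filter(profile, .data$chrom == ch)
  p <- p[order(p$pos), ]
  lo <- p$fitted < interval_threshold
  am <- which.min(p$fitted)
  lo[am] <- TRUE  # the argmin marker always belongs
  runs <- rle(lo)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values & starts <= am & am <= ends)
  tibble(chrom = ch, start = p$pos[starts[k]], end = p$pos[ends[k]],
         min_fitted = p$fitted[am])
}

#' Write a candidate interval as BED
#'
#' BED is 0-based half-open; the 1-based closed interval `[start, end]`
#' becomes `start-1 .. end`.
#'
#' @param interval One-row tibble from [candidate_interval()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_bed <- function(interval, path) {
  writeLines(paste(interval$chrom, format(interval$start - 1, scientific = FALSE),
                   format(interval$end, scientific = FALSE),
                   "candidate_interval", sep = "\t"), path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.linkage_call <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.linkage_call <- function(x, ...) {
  linked <- any(x$linked)
  tibble(linked = linked,
         chrom = if (linked) x$chrom[x$linked][1] else NA_character_,
         min_fitted = min(x$min_fitted),
         threshold = attr(x, "threshold"))
}

#' Plot a frequency profile with its Loess curve
#'
#' One panel per chromosome: observed mapping-strain allele frequency per
#' marker (points) with the fitted curve (line) and the 0.5 unlinked
#' expectation (dashed).
#'
#' @param object A `freq_profile`, fitted or not.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.freq_profile <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$observed)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "mapping-strain allele frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if ("fitted" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "#d55e00", linewidth = 0.9)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
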