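# Mosaic quantification: allele-fraction estimation, detection against a
# sequencing-error null, and depth x fraction sensitivity grids.

#' Raw mosaic allele fraction
#'
#' The headline estimate is the raw read fraction `alt_count / depth`; the
#' error-corrected estimate ([corrected_fraction()]) is a secondary field.
#'
#' @param count A `site_read_count`.
#' @return `alt_count / depth`, exactly.
#' @export
raw_fraction <- function(count) {
  stopifnot(inherits(count, "site_read_count"))
  count$alt_count / count$depth
}

#' Error-corrected mosaic fraction estimate
#'
#' Inverts the forward model `p_obs = f (1 - eps_total) + (1 - f) eps_target`
#' at the observed read fraction and clamps to \[0, 1\]:
#' `f_hat = (k/D - eps_target) / (1 - eps_total - eps_target)`.
#'
#' @param count A `site_read_count`.
#' @param em An `error_model`.
#' @return The corrected fraction estimate in \[0, 1\].
#' @export
corrected_fraction <- function(count, em = error_model()) {
  stopifnot(inherits(count, "site_read_count"))
  denom <- 1 - em$eps_total - em$eps_target
  if (denom <= 0)
    abort_invalid("eps_total + eps_target must be < 1")
  f <- (count$alt_count / count$depth - em$eps_target) / denom
  min(max(f, 0), 1)
}

#' Exact one-sided binomial upper tail
#'
#' `P(K >= k | D, p)` for `K ~ Binom(D, p)` — the p-value of observing at
#' least `k` mutant reads under an error-rate null.
#'
#' @param k Observed count, `0 <= k <= D`.
#' @param D Number of trials (depth).
#' @param p Success probability.
#' @return The exact upper-tail probability.
#' @examples
#' binomial_tail(3, 200, 0.001 / 3)
#' @export
binomial_tail <- function(k, D, p) {
  if (!is.numeric(k) || !is.numeric(D) || k < 0 || k > D)
    abort_invalid("k must satisfy 0 <= k <= D")
  check_prob(p, "p")
  pbinom(k - 1, D, p, lower.tail = FALSE)
}

# Smallest alt count that satisfies all three detection conditions at a
# given depth. Each condition is an upper set in k, so the rule reduces to
# a single threshold.
detection_k_threshold <- function(depth, em, config) {
  k_alpha <- qbinom(1 - config$alpha, depth, em$eps_target)
  while (binomial_tail(k_alpha, depth, em$eps_target) >= config$alpha)
    k_alpha <- k_alpha + 1L
  max(config$k_min, k_alpha, ceiling(config$lod_fraction * depth))
}

#' Call a mosaic variant from one site's read counts
#'
#' Detection requires all of: `alt_count >= k_min`; a one-sided exact
#' binomial p-value below `alpha` against the null that mutant-supporting
#' reads arise purely from sequencing error at rate `eps_target`; and a raw
#' fraction at or above the limit of detection `lod_fraction`.
#'
#' @param count A `site_read_count`.
#' @param em An `error_model`.
#' @param config A `detection_config`.
#' @return A `mosaic_call`: `raw_fraction`, `corrected_fraction`,
#'   `ci_low`/`ci_high` (95% Clopper-Pearson on the raw fraction),
#'   `p_value`, `detected`, plus the inputs.
#' @examples
#' detect_mosaic(site_read_count(depth = 10000, alt_count = 265))
#' @export
detect_mosaic <- function(count, em = error_model(),
                          config = detection_config()) {
  stopifnot(inherits(count, "site_read_count"),
            inherits(em, "error_model"),
            inherits(config, "detection_config"))
  raw <- raw_fraction(count)
  p <- binomial_tail(count$alt_count, count$depth, em$eps_target)
  ci <- confidence_interval(count, level = 0.95)
  detected <- count$alt_count >= config$k_min &&
    p < config$alpha && raw >= config$lod_fraction
  structure(list(
    sample_label = count$sample_label, chrom = count$chrom, pos = count$pos,
    ref = count$ref, alt = count$alt,
    depth = count$depth, alt_count = count$alt_count,
    raw_fraction = raw,
    corrected_fraction = corrected_fraction(count, em),
    ci_low = ci[[1]], ci_high = ci[[2]], p_value = p,
    detected = detected), class = "mosaic_call")
}

#' @export
print.mosaic_call <- function(x, ...) {
  cat(sprintf(
    "<mosaic_call> %s  k/D = %d/%d  raw = %.4g  corrected = %.4g\n  95%% CI [%.4g, %.4g]  p = %.3g  detected: %s\n",
    x$sample_label, x$alt_count, x$depth, x$raw_fraction,
    x$corrected_fraction, x$ci_low, x$ci_high, x$p_value, x$detected))
  invisible(x)
}

#' Call mosaic variants over a pileup table
#'
#' Applies [detect_mosaic()] to each row of a pileup data.frame (as read by
#' [read_pileup_tsv()]).
#'
#' @param pileup Data.frame with columns
#'   `sample, chrom, pos, ref, alt, depth, alt_count`.
#' @param em An `error_model`.
#' @param config A `detection_config`.
#' @return A calls data.frame, one row per site: coordinates plus
#'   `raw_fraction, corrected_fraction, ci_low, ci_high, p_value, detected`.
#' @export
quantify_pileup <- function(pileup, em = error_model(),
                            config = detection_config()) {
  rows <- lapply(seq_len(nrow(pileup)), function(i) {
    r <- pileup[i, ]
    call <- detect_mosaic(
      site_read_count(depth = r$depth, alt_count = r$alt_count,
                      sample_label = r$sample, chrom = r$chrom, pos = r$pos,
                      ref = r$ref, alt = r$alt), em, config)
    data.frame(sample = r$sample, chrom = r$chrom, pos = r$pos, ref = r$ref,
               alt = r$alt, depth = r$depth, alt_count = r$alt_count,
               raw_fraction = call$raw_fraction,
               corrected_fraction = call$corrected_fraction,
               ci_low = call$ci_low, ci_high = call$ci_high,
               p_value = call$p_value, detected = call$detected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact detection power at a given mosaic fraction and depth
#'
#' The probability that a pileup drawn at the forward-model read probability
#' satisfies the full detection rule, computed from the exact binomial tail
#' above the detection threshold (no simulation).
#'
#' @param true_fraction Mutant molecule fraction in \[0, 1\].
#' @param depth Read depth (>= 1).
#' @param em An `error_model`.
#' @param config A `detection_config`.
#' @return Detection probability in \[0, 1\].
#' @examples
#' analytic_power(0.03, 200)
#' @export
analytic_power <- function(true_fraction, depth, em = error_model(),
                           config = detection_config()) {
  if (!is.numeric(depth) || depth < 1)
    abort_invalid("depth must be a positive integer")
  k_star <- detection_k_threshold(depth, em, config)
  if (k_star > depth) return(0)
  p_obs <- expected_alt_fraction(true_fraction, em)
  binomial_tail(k_star, depth, p_obs)
}

#' Monte-Carlo sensitivity grid over fractions and depths
#'
#' For every (fraction, depth) cell, simulates `n_reps` pileups at the
#' forward-model read probability, applies the detection rule, and records
#' the empirical power; a cell is flagged detectable when power reaches
#' `power_threshold`.
#'
#' @param fractions Mutant fractions (non-empty, each in \[0, 1\]).
#' @param depths Read depths (non-empty, each >= 1).
#' @param em An `error_model`.
#' @param config A `detection_config` (`n_reps` replicates per cell).
#' @param seed Integer seed; the grid is deterministic given the seed.
#' @return A `sensitivity_grid`: `fractions`, `depths`, `power` and
#'   `detectable` matrices (rows = fractions, columns = depths), `n_reps`.
#' @examples
#' g <- sensitivity_grid(c(0.03, 0.001), c(200, 500), seed = 1)
#' g$detectable
#' @export
sensitivity_grid <- function(fractions, depths, em = error_model(),
                             config = detection_config(), seed = 1L) {
  if (!length(fractions) || !length(depths))
    abort_invalid("fractions and depths must be non-empty")
  vapply(fractions, check_prob, numeric(1), name = "fraction")
  if (any(depths < 1)) abort_invalid("depths must be >= 1")
  local_seed(seed)
  power <- matrix(NA_real_, length(fractions), length(depths),
                  dimnames = list(fraction = as.character(fractions),
                                  depth = as.character(depths)))
  for (j in seq_along(depths)) {
    D <- as.integer(depths[j])
    k_star <- detection_k_threshold(D, em, config)
    for (i in seq_along(fractions)) {
      k <- rbinom(config$n_reps, D, expected_alt_fraction(fractions[i], em))
      power[i, j] <- mean(k >= k_star)
    }
  }
  structure(list(fractions = as.numeric(fractions),
                 depths = as.integer(depths), power = power,
                 detectable = power >= config$power_threshold,
                 n_reps = config$n_reps,
                 power_threshold = config$power_threshold),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("<sensitivity_grid>", x$n_reps, "reps/cell; detectable at power >=",
      x$power_threshold, "\n")
  print(round(x$power, 3))
  invisible(x)
}

#' Flatten a sensitivity grid to a long table
#'
#' @param x A `sensitivity_grid`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return Data.frame with columns `fraction, depth, power, detectable`.
#' @export
as.data.frame.sensitivity_grid <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(fraction = rep(x$fractions, times = length(x$depths)),
             depth = rep(x$depths, each = length(x$fractions)),
             power = as.vector(x$power),
             detectable = as.vector(x$detectable))
}

#' Exact Clopper-Pearson interval on the raw fraction
#'
#' Conservative two-sided binomial interval from beta quantiles; preferred
#' over asymptotic intervals because mosaic counts sit near the error floor.
#'
#' @param count A `site_read_count`.
#' @param level Confidence level in (0, 1). Default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
confidence_interval <- function(count, level = 0.95) {
  stopifnot(inherits(count, "site_read_count"))
  if (!is.numeric(level) || level <= 0 || level >= 1)
    abort_invalid("level must be in (0, 1)")
  k <- count$alt_count; D <- count$depth
  a <- 1 - level
  low <- if (k == 0) 0 else qbeta(a / 2, k, D - k + 1)
  high <- if (k == D) 1 else qbeta(1 - a / 2, k + 1, D - k)
  c(low = low, high = high)
}
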