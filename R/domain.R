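# Domain objects shared by all stages. Plain data.frames hold tabular
# substrates (SNP panels, pileups, STR genotypes); small S3 lists hold the
# structured results (calls, origin, risk, plan).

#' Sequencing error model
#'
#' Two per-base error rates drive both simulation and estimation:
#' `eps_total`, the probability that a sequenced base is miscalled as any
#' wrong base, and `eps_target`, the probability that a true non-mutant base
#' is read as the one specific mutant allele. With substitution errors
#' spread roughly evenly over the three wrong bases, `eps_target` defaults
#' to `eps_total / 3`.
#'
#' @param eps_total Per-base miscall probability (any wrong base).
#'   Default 0.001, a typical short-read substitution rate.
#' @param eps_target Probability of miscalling towards the specific mutant
#'   allele. Default `eps_total / 3`.
#' @return An object of class `error_model`.
#' @examples
#' error_model()
#' error_model(eps_total = 0.002)
#' @export
error_model <- function(eps_total = 0.001, eps_target = eps_total / 3) {
  if (!is.numeric(eps_total) || eps_total < 0 || eps_total >= 0.1)
    abort_invalid("eps_total must be in [0, 0.1), got ", eps_total)
  if (!is.numeric(eps_target) || eps_target < 0 || eps_target > eps_total)
    abort_invalid("eps_target must satisfy 0 <= eps_target <= eps_total")
  structure(list(eps_total = as.numeric(eps_total),
                 eps_target = as.numeric(eps_target)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> eps_total =", x$eps_total,
      " eps_target =", x$eps_target, "\n")
  invisible(x)
}

#' Detection thresholds for mosaic calling
#'
#' A site is called detected when all three conditions hold: at least
#' `k_min` mutant reads, a one-sided exact binomial p-value below `alpha`
#' against the error null `Binom(depth, eps_target)`, and a raw fraction of
#' at least `lod_fraction`. On a power grid, a (fraction, depth) cell is
#' flagged detectable when empirical power reaches `power_threshold`.
#'
#' @param alpha Significance level of the one-sided binomial test
#'   (strict inequality, p < alpha). Default 0.01.
#' @param k_min Minimum number of mutant-supporting reads. Default 3.
#' @param lod_fraction Minimum raw allele fraction to call positive
#'   (limit of detection). Default 0.01.
#' @param power_threshold Empirical power defining "detectable" at a grid
#'   point. Default 0.90.
#' @param n_reps Monte-Carlo replicates per grid point. Default 1000.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(alpha = 0.01, k_min = 3L, lod_fraction = 0.01,
                             power_threshold = 0.90, n_reps = 1000L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort_invalid("alpha must be in (0, 1)")
  if (!is.numeric(k_min) || k_min < 1)
    abort_invalid("k_min must be >= 1")
  if (!is.numeric(lod_fraction) || lod_fraction < 0 || lod_fraction >= 1)
    abort_invalid("lod_fraction must be in [0, 1)")
  if (!is.numeric(power_threshold) || power_threshold <= 0 || power_threshold > 1)
    abort_invalid("power_threshold must be in (0, 1]")
  if (!is.numeric(n_reps) || n_reps < 1)
    abort_invalid("n_reps must be >= 1")
  structure(list(alpha = as.numeric(alpha), k_min = as.integer(k_min),
                 lod_fraction = as.numeric(lod_fraction),
                 power_threshold = as.numeric(power_threshold),
                 n_reps = as.integer(n_reps)),
            class = "detection_config")
}

#' Define a mutation site
#'
#' @param label Opaque HGVS-style label, e.g. `"c.2939T>A"`; the package
#'   never parses it.
#' @param chrom Chromosome name.
#' @param pos 1-based genomic coordinate.
#' @param ref,alt Reference and alternate alleles (non-empty strings;
#'   indels are carried as genotype strings, never as reads).
#' @param role Either `"known_inherited"` or `"apparent_de_novo"`.
#' @return An object of class `mutation_site`.
#' @export
mutation_site <- function(label, chrom, pos, ref, alt,
                          role = c("known_inherited", "apparent_de_novo")) {
  role <- match.arg(role)
  if (!is.numeric(pos) || pos < 1) abort_invalid("pos must be >= 1")
  if (!nzchar(ref) || !nzchar(alt) || identical(ref, alt))
    abort_invalid("ref and alt must be non-empty and distinct")
  structure(list(label = as.character(label), chrom = as.character(chrom),
                 pos = as.integer(pos), ref = as.character(ref),
                 alt = as.character(alt), role = role),
            class = "mutation_site")
}

#' Per-site read counts
#'
#' The quantification substrate: at one site, `depth` total reads of which
#' `alt_count` support the mutant allele.
#'
#' @param depth Total read depth (positive integer).
#' @param alt_count Mutant-supporting reads, `0 <= alt_count <= depth`.
#' @param sample_label Free-text sample name.
#' @param chrom,pos,ref,alt Site coordinates and alleles (optional for
#'   purely numerical work).
#' @return An object of class `site_read_count`.
#' @export
site_read_count <- function(depth, alt_count, sample_label = "sample",
                            chrom = NA_character_, pos = NA_integer_,
                            ref = NA_character_, alt = NA_character_) {
  if (!is.numeric(depth) || depth < 1)
    abort_invalid("depth must be a positive integer")
  if (!is.numeric(alt_count) || alt_count < 0 || alt_count > depth)
    abort_invalid("alt_count must satisfy 0 <= alt_count <= depth")
  structure(list(sample_label = as.character(sample_label),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 depth = as.integer(depth), alt_count = as.integer(alt_count)),
            class = "site_read_count")
}

#' @export
print.site_read_count <- function(x, ...) {
  cat(sprintf("<site_read_count> %s %s:%s %s>%s  k/D = %d/%d (%.4g)\n",
              x$sample_label, x$chrom, x$pos, x$ref, x$alt,
              x$alt_count, x$depth, x$alt_count / x$depth))
  invisible(x)
}

# Validate a SNP panel data.frame (id, chrom, pos, ref, alt, pop_het).
as_snp_panel <- function(df) {
  need <- c("id", "chrom", "pos", "ref", "alt", "pop_het")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_invalid("SNP panel lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$pos < 1)) abort_invalid("SNP positions must be >= 1")
  if (any(df$ref == df$alt)) abort_invalid("SNP ref must differ from alt")
  if (any(df$pop_het < 0 | df$pop_het > 0.5))
    abort_invalid("pop_het must lie in [0, 0.5]")
  if (anyDuplicated(df$id)) abort_invalid("duplicate SNP ids in panel")
  df <- df[need]
  df$pos <- as.integer(df$pos)
  class(df) <- c("snp_panel", "data.frame")
  df
}
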