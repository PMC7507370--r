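# On-disk formats: tab-separated tables (UTF-8, '.' for missing) for the
# bespoke records, minimal VCF 4.2 for trio genotypes, YAML for config.
# Positions are 1-based everywhere on disk.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

read_tsv_checked <- function(path, required, colClasses = NA) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  # Allele columns must never be type-guessed ("T" is not TRUE).
  if (length(colClasses) == 1L && is.na(colClasses))
    colClasses <- c(id = "character", chrom = "character",
                    ref = "character", alt = "character",
                    sample = "character", site_id = "character",
                    observed_allele = "character",
                    fragment_id = "character", marker = "character")
  if (!is.null(names(colClasses))) {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    colClasses <- colClasses[names(colClasses) %in% hdr]
  }
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = colClasses,
                   na.strings = ".")
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort_invalid(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read / write a SNP panel TSV
#'
#' Columns: `id, chrom, pos, ref, alt, pop_het`.
#'
#' @param panel A `snp_panel`.
#' @param path File path.
#' @return `read_panel_tsv()` returns a `snp_panel`;
#'   `write_panel_tsv()` returns `path` invisibly.
#' @export
write_panel_tsv <- function(panel, path) write_tsv(as_snp_panel(panel), path)

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  as_snp_panel(read_tsv_checked(
    path, c("id", "chrom", "pos", "ref", "alt", "pop_het")))
}

#' Read / write a pileup TSV
#'
#' Columns: `sample, chrom, pos, ref, alt, depth, alt_count`, one row per
#' sequenced site.
#'
#' @param counts A data.frame with the pileup columns, or a list of
#'   `site_read_count`s.
#' @param path File path.
#' @return `read_pileup_tsv()` returns the validated data.frame;
#'   `write_pileup_tsv()` returns `path` invisibly.
#' @export
write_pileup_tsv <- function(counts, path) {
  if (!is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(counts, function(x)
      data.frame(sample = x$sample_label, chrom = x$chrom, pos = x$pos,
                 ref = x$ref, alt = x$alt, depth = x$depth,
                 alt_count = x$alt_count, stringsAsFactors = FALSE)))
  }
  write_tsv(counts, path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  df <- read_tsv_checked(
    path, c("sample", "chrom", "pos", "ref", "alt", "depth", "alt_count"))
  df$depth <- as.integer(df$depth); df$alt_count <- as.integer(df$alt_count)
  bad <- which(is.na(df$depth) | is.na(df$alt_count) | df$depth < 1 |
                 df$alt_count < 0 | df$alt_count > df$depth)
  if (length(bad))
    abort_invalid(path, ": invalid depth/alt_count at row ", bad[1],
                  " (alt_count must satisfy 0 <= alt_count <= depth)")
  df
}

#' Read / write fragment observations as TSV
#'
#' Long format, columns `fragment_id, cell_id, site_id, observed_allele`;
#' a fragment with no covered sites is kept as a single row with `.` in the
#' site columns.
#'
#' @param fragments List of `fragment_observation`s.
#' @param path File path.
#' @return `read_fragments_tsv()` returns a list of
#'   `fragment_observation`s (truth homolog unknown);
#'   `write_fragments_tsv()` returns `path` invisibly.
#' @export
write_fragments_tsv <- function(fragments, path) {
  rows <- lapply(fragments, function(f) {
    if (!length(f$observed))
      return(data.frame(fragment_id = f$fragment_id, cell_id = f$cell_id,
                        site_id = NA_character_,
                        observed_allele = NA_character_,
                        stringsAsFactors = FALSE))
    data.frame(fragment_id = f$fragment_id, cell_id = f$cell_id,
               site_id = names(f$observed),
               observed_allele = unname(f$observed),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  df <- read_tsv_checked(
    path, c("fragment_id", "cell_id", "site_id", "observed_allele"))
  ids <- unique(df$fragment_id)
  lapply(ids, function(id) {
    rows <- df[df$fragment_id == id & !is.na(df$site_id), , drop = FALSE]
    observed <- setNames(as.character(rows$observed_allele),
                         as.character(rows$site_id))
    fragment_observation(
      fragment_id = id,
      cell_id = df$cell_id[match(id, df$fragment_id)],
      observed = observed)
  })
}

#' Read / write an STR trio TSV
#'
#' Columns: `marker, father_a1, father_a2, mother_a1, mother_a2, child_a1,
#' child_a2` (allele pairs unordered).
#'
#' @param trio An `str_trio` data.frame.
#' @param path File path.
#' @return `read_str_tsv()` returns an `str_trio`;
#'   `write_str_tsv()` returns `path` invisibly.
#' @export
write_str_tsv <- function(trio, path) write_tsv(trio, path)

#' @rdname write_str_tsv
#' @export
read_str_tsv <- function(path) {
  df <- read_tsv_checked(
    path, c("marker", "father_a1", "father_a2", "mother_a1", "mother_a2",
            "child_a1", "child_a2"),
    colClasses = "character")
  class(df) <- c("str_trio", "data.frame")
  df
}

TRIO_SAMPLES <- c("FATHER", "MOTHER", "PROBAND")

gt_code <- function(alleles, ref, alt) {
  idx <- match(alleles, c(ref, alt)) - 1L
  if (anyNA(idx))
    abort_invalid("genotype allele not in {ref, alt} at a site")
  paste(sort(idx), collapse = "/")
}

#' Write trio genotypes as minimal VCF 4.2
#'
#' GT-only body with the three sample columns `FATHER`, `MOTHER`,
#' `PROBAND`; unphased, unordered genotypes.
#'
#' @param trio A `trio_genotypes`.
#' @param path Output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(trio, path) {
  stopifnot(inherits(trio, "trio_genotypes"))
  s <- trio$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=microseqr",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", TRIO_SAMPLES), collapse = "\t"))
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i], s$alt[i], ".", ".",
            ".", "GT",
            gt_code(trio$father[, i], s$ref[i], s$alt[i]),
            gt_code(trio$mother[, i], s$ref[i], s$alt[i]),
            gt_code(trio$proband[, i], s$ref[i], s$alt[i])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read trio genotypes from a VCF
#'
#' Parses the GT field of a VCF containing the sample columns `FATHER`,
#' `MOTHER` and `PROBAND` (any column order). Sites with missing or
#' half-called genotypes in any trio member are skipped with a warning.
#'
#' @param path Path to a VCF 4.2 file.
#' @return A `trio_genotypes` (site table plus a 2-row allele matrix per
#'   individual). The known/de novo site ids are not set; pass them
#'   explicitly to the phasing functions.
#' @export
read_trio_vcf <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    abort_invalid("failed to parse VCF ", path, ": ",
                                  conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  miss <- setdiff(TRIO_SAMPLES, colnames(gt))
  if (length(miss))
    abort_invalid(path, ": missing sample column(s): ",
                  paste(miss, collapse = ", "))
  sites <- data.frame(id = fix$ID, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, pop_het = NA_real_,
                      type = NA_character_, stringsAsFactors = FALSE)
  parse_gt <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
    if (length(a) != 2L || anyNA(suppressWarnings(as.integer(a)))) return(NULL)
    as.integer(a)
  }
  keep <- logical(nrow(sites))
  mats <- lapply(TRIO_SAMPLES, function(s) matrix(NA_character_, 2L,
                                                  nrow(sites)))
  names(mats) <- TRIO_SAMPLES
  for (i in seq_len(nrow(sites))) {
    alleles <- c(sites$ref[i], sites$alt[i])
    ok <- TRUE
    for (s in TRIO_SAMPLES) {
      idx <- parse_gt(gt[i, s])
      if (is.null(idx) || any(idx < 0) || any(idx > 1)) { ok <- FALSE; break }
      mats[[s]][, i] <- alleles[idx + 1L]
    }
    keep[i] <- ok
  }
  if (any(!keep))
    warning(sum(!keep), " site(s) skipped (missing or half-called GT)",
            call. = FALSE)
  structure(list(sites = sites[keep, , drop = FALSE],
                 father = mats$FATHER[, keep, drop = FALSE],
                 mother = mats$MOTHER[, keep, drop = FALSE],
                 proband = mats$PROBAND[, keep, drop = FALSE],
                 known_site_id = NULL, de_novo_site_id = NULL),
            class = "trio_genotypes")
}

#' Write mosaic calls / sensitivity grids as TSV
#'
#' @param calls Calls data.frame from [quantify_pileup()].
#' @param grid A `sensitivity_grid`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) write_tsv(calls, path)

#' @rdname write_calls_tsv
#' @export
write_grid_tsv <- function(grid, path) {
  write_tsv(as.data.frame(grid), path)
}

CONFIG_KEYS <- c("eps_total", "eps_target", "alpha", "k_min", "lod_fraction",
                 "power_threshold", "n_reps", "window_bp", "min_het",
                 "capture_prob", "site_dropout", "wga_error", "n_cells",
                 "seed", "out_dir")

#' Load and validate a pipeline configuration
#'
#' YAML with any subset of the keys
#' `eps_total, eps_target, alpha, k_min, lod_fraction, power_threshold,
#' n_reps, window_bp, min_het, capture_prob, site_dropout, wga_error,
#' n_cells, seed, out_dir`; unknown keys are rejected. Missing keys take
#' the package defaults (5 Mb SNP window; error and detection defaults of
#' [error_model()] and [detection_config()]).
#'
#' @param path Path to a YAML file, or NULL for all defaults.
#' @return A validated `pipeline_config` list with components `em`
#'   (`error_model`), `detection` (`detection_config`), `window_bp`,
#'   `min_het`, `capture_prob`, `site_dropout`, `wga_error`, `n_cells`,
#'   `seed`, `out_dir`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    abort_invalid("unknown config key(s): ", paste(unknown, collapse = ", "),
                  " (allowed: ", paste(CONFIG_KEYS, collapse = ", "), ")")
  eps_total <- raw$eps_total %||% 0.001
  em <- error_model(eps_total = eps_total,
                    eps_target = raw$eps_target %||% (eps_total / 3))
  detection <- detection_config(
    alpha = raw$alpha %||% 0.01, k_min = raw$k_min %||% 3L,
    lod_fraction = raw$lod_fraction %||% 0.01,
    power_threshold = raw$power_threshold %||% 0.90,
    n_reps = raw$n_reps %||% 1000L)
  structure(list(em = em, detection = detection,
                 window_bp = raw$window_bp %||% 5e6,
                 min_het = raw$min_het %||% 0.1,
                 capture_prob = raw$capture_prob %||% (1 / 8),
                 site_dropout = raw$site_dropout %||% 0.2,
                 wga_error = raw$wga_error %||% 0.01,
                 n_cells = raw$n_cells %||% 4L,
                 seed = raw$seed %||% 1L,
                 out_dir = raw$out_dir %||% "."), class = "pipeline_config")
}
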