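# Synthetic cohort: seeded generators for every input the pipeline consumes.
# Ground truth (phased haplotypes, homolog labels, mosaic fraction) is carried
# alongside so downstream inference can be scored without any wet-lab data.

#' Simulate a SNP marker panel
#'
#' Draws `n_snps` biallelic markers with strictly increasing positions inside
#' a genomic region and population heterozygosities uniform on `het_range`.
#'
#' @param n_snps Number of markers (>= 1).
#' @param region_span Width of the region in base pairs (>= `n_snps`).
#' @param het_range Interval within \[0, 0.5\] for population heterozygosity.
#' @param seed Integer seed; identical arguments and seed give identical
#'   panels.
#' @param chrom Chromosome name for all markers.
#' @param region_start 1-based start of the region.
#' @return A `snp_panel` data.frame with columns
#'   `id, chrom, pos, ref, alt, pop_het`.
#' @examples
#' simulate_snp_panel(6, 5e6, seed = 1)
#' @export
simulate_snp_panel <- function(n_snps, region_span, het_range = c(0.1, 0.5),
                               seed = 1L, chrom = "chr2",
                               region_start = 1L) {
  if (!is.numeric(n_snps) || n_snps < 1)
    abort_invalid("n_snps must be a positive integer")
  n_snps <- as.integer(n_snps)
  if (length(het_range) != 2L || het_range[1] > het_range[2] ||
      het_range[1] < 0 || het_range[2] > 0.5)
    abort_invalid("het_range must be a non-empty interval within [0, 0.5]")
  if (region_span < n_snps)
    abort_invalid("region_span must allow n_snps distinct positions")
  local_seed(seed)
  pos <- sort(sample.int(as.integer(region_span), n_snps)) +
    as.integer(region_start) - 1L
  ref <- sample(BASES, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  het <- runif(n_snps, het_range[1], het_range[2])
  as_snp_panel(data.frame(
    id = sprintf("snp%04d", seq_len(n_snps)), chrom = chrom, pos = pos,
    ref = ref, alt = unname(alt), pop_het = het,
    stringsAsFactors = FALSE))
}

# Per-haplotype alt-allele probability q such that the expected
# heterozygosity 2 q (1 - q) equals the target pop_het (real for het <= 0.5).
alt_hap_prob <- function(pop_het) (1 - sqrt(1 - 2 * pop_het)) / 2

#' Simulate a phased trio with a known inherited and a de novo mutation
#'
#' Parental haplotypes are drawn per site, independently across sites (the
#' markers serve only as linkage anchors inside one un-recombined fragment,
#' so no LD or recombination is modelled). The known inherited mutation is
#' placed on one haplotype of the non-mosaic parent and transmitted to the
#' child; the apparent de novo allele is placed on the transmitted haplotype
#' of `de_novo_parent` in the child but is absent from that parent's
#' constitutional (blood) genotype. The child always carries the de novo
#' allele regardless of `mosaic_fraction` — the proband is ascertained;
#' `mosaic_fraction` is recorded as truth and governs gamete pileups only.
#'
#' @param panel A `snp_panel`.
#' @param known_mutation A `mutation_site` with role `known_inherited`.
#' @param de_novo_mutation A `mutation_site` with role `apparent_de_novo`.
#' @param de_novo_parent `"father"` or `"mother"`.
#' @param mosaic_fraction Fraction of the de novo parent's gametes carrying
#'   the de novo allele, in \[0, 1\].
#' @param seed Integer seed.
#' @return An object of class `phased_trio`.
#' @export
simulate_trio <- function(panel, known_mutation, de_novo_mutation,
                          de_novo_parent = c("father", "mother"),
                          mosaic_fraction = 0.03, seed = 1L) {
  de_novo_parent <- match.arg(de_novo_parent)
  panel <- as_snp_panel(panel)
  stopifnot(inherits(known_mutation, "mutation_site"),
            inherits(de_novo_mutation, "mutation_site"))
  if (known_mutation$role != "known_inherited" ||
      de_novo_mutation$role != "apparent_de_novo")
    abort_invalid("mutation roles must be known_inherited / apparent_de_novo")
  check_prob(mosaic_fraction, "mosaic_fraction")
  for (m in list(known_mutation, de_novo_mutation)) {
    if (m$pos %in% panel$pos)
      abort_invalid("mutation at ", m$chrom, ":", m$pos,
                    " collides with a panel SNP position")
    if (m$pos < min(panel$pos) || m$pos > max(panel$pos))
      abort_invalid("mutation at ", m$pos, " lies outside the panel region [",
                    min(panel$pos), ", ", max(panel$pos), "]")
  }
  if (known_mutation$pos == de_novo_mutation$pos)
    abort_invalid("mutation sites must have distinct positions")

  local_seed(seed)
  sites <- rbind(
    data.frame(id = panel$id, chrom = panel$chrom, pos = panel$pos,
               ref = panel$ref, alt = panel$alt, pop_het = panel$pop_het,
               type = "snp", stringsAsFactors = FALSE),
    data.frame(id = c(known_mutation$label, de_novo_mutation$label),
               chrom = c(known_mutation$chrom, de_novo_mutation$chrom),
               pos = c(known_mutation$pos, de_novo_mutation$pos),
               ref = c(known_mutation$ref, de_novo_mutation$ref),
               alt = c(known_mutation$alt, de_novo_mutation$alt),
               pop_het = NA_real_,
               type = c("known_inherited", "apparent_de_novo"),
               stringsAsFactors = FALSE))
  sites <- sites[order(sites$pos), ]
  rownames(sites) <- NULL
  n <- nrow(sites)

  draw_parent <- function() {
    haps <- matrix(rep(sites$ref, each = 2L), nrow = 2L)
    is_snp <- sites$type == "snp"
    q <- alt_hap_prob(sites$pop_het[is_snp])
    for (h in 1:2) {
      take_alt <- runif(sum(is_snp)) < q
      haps[h, is_snp][take_alt] <- sites$alt[is_snp][take_alt]
    }
    colnames(haps) <- sites$id
    haps
  }
  father <- draw_parent()
  mother <- draw_parent()

  known_parent <- if (de_novo_parent == "father") "mother" else "father"
  known_col <- which(sites$type == "known_inherited")
  dn_col <- which(sites$type == "apparent_de_novo")
  known_hap <- sample(1:2, 1L)
  if (known_parent == "father") father[known_hap, known_col] <- known_mutation$alt
  else mother[known_hap, known_col] <- known_mutation$alt

  # The child inherits the mutation-carrying haplotype from the known-mutation
  # parent (ascertainment: the proband is compound heterozygous) and a random
  # haplotype from the mosaic parent.
  pat_idx <- if (known_parent == "father") known_hap else sample(1:2, 1L)
  mat_idx <- if (known_parent == "mother") known_hap else sample(1:2, 1L)
  child_pat <- father[pat_idx, ]
  child_mat <- mother[mat_idx, ]
  if (de_novo_parent == "father") child_pat[dn_col] <- de_novo_mutation$alt
  else child_mat[dn_col] <- de_novo_mutation$alt

  structure(list(
    sites = sites, father_haps = father, mother_haps = mother,
    child_paternal_index = pat_idx, child_maternal_index = mat_idx,
    child_paternal_hap = child_pat, child_maternal_hap = child_mat,
    de_novo_parent = de_novo_parent,
    germline_mosaic_fraction = as.numeric(mosaic_fraction),
    known_site_id = known_mutation$label,
    de_novo_site_id = de_novo_mutation$label), class = "phased_trio")
}

#' @export
print.phased_trio <- function(x, ...) {
  cat("<phased_trio>", nrow(x$sites), "sites; de novo parent:",
      x$de_novo_parent, "; germline mosaic fraction:",
      x$germline_mosaic_fraction, "\n")
  invisible(x)
}

#' Collapse a phased trio to unphased constitutional genotypes
#'
#' Parents report their blood genotypes (the de novo allele is absent from
#' the mosaic parent's constitutional DNA by construction); the proband
#' reports both inherited haplotypes including the de novo allele.
#'
#' @param trio A `phased_trio`.
#' @return An object of class `trio_genotypes`: the site table plus a
#'   2-row allele matrix per individual (unordered pairs, columns = sites).
#' @export
trio_genotypes <- function(trio) {
  stopifnot(inherits(trio, "phased_trio"))
  structure(list(
    sites = trio$sites,
    father = trio$father_haps,
    mother = trio$mother_haps,
    proband = rbind(trio$child_paternal_hap, trio$child_maternal_hap),
    known_site_id = trio$known_site_id,
    de_novo_site_id = trio$de_novo_site_id), class = "trio_genotypes")
}

#' Simulate microdissected WGA fragments from the proband
#'
#' Each of the proband's `n_cells` metaphase cells contributes its two
#' homologous fragments (so exactly `2 * n_cells` fragments). A fragment is
#' independently captured by whole-genome amplification with probability
#' `capture_prob`; inside a captured fragment each site independently drops
#' out with probability `site_dropout`, and each surviving haploid allele is
#' flipped to a random wrong base with probability `wga_error`. The true
#' homolog of origin is recorded for scoring.
#'
#' @param trio A `phased_trio`.
#' @param n_cells Number of cells dissected. Default 4, the bench-scale
#'   number of metaphase spreads.
#' @param capture_prob Per-fragment capture probability. Default 1/8,
#'   calibrated to one successful capture among eight fragments.
#' @param site_dropout Per-site dropout probability within a captured
#'   fragment. Default 0.2.
#' @param wga_error Per-site amplification miscall probability. Default 0.01.
#' @param seed Integer seed.
#' @return A list of `fragment_observation` objects, each with
#'   `fragment_id` (`"cell-homolog"`), `cell_id`, `truth_homolog`, and a
#'   named `observed` allele vector over the covered sites.
#' @export
simulate_fragments <- function(trio, n_cells = 4L, capture_prob = 1 / 8,
                               site_dropout = 0.2, wga_error = 0.01,
                               seed = 1L) {
  stopifnot(inherits(trio, "phased_trio"))
  if (!is.numeric(n_cells) || n_cells < 1)
    abort_invalid("n_cells must be >= 1")
  check_prob(capture_prob, "capture_prob")
  check_prob(site_dropout, "site_dropout")
  check_prob(wga_error, "wga_error")
  local_seed(seed)
  haps <- list(paternal_origin_homolog = trio$child_paternal_hap,
               maternal_origin_homolog = trio$child_maternal_hap)
  out <- vector("list", 2L * as.integer(n_cells))
  idx <- 0L
  for (cell in seq_len(n_cells)) {
    for (h in 1:2) {
      idx <- idx + 1L
      hap <- haps[[h]]
      observed <- character(0)
      if (runif(1) < capture_prob) {
        keep <- runif(length(hap)) >= site_dropout
        observed <- hap[keep]
        if (length(observed) && wga_error > 0) {
          flip <- runif(length(observed)) < wga_error
          if (any(flip)) {
            observed[flip] <- vapply(observed[flip], function(a)
              sample(setdiff(BASES, a), 1L), character(1))
          }
        }
      }
      out[[idx]] <- fragment_observation(
        fragment_id = paste0(cell, "-", h), cell_id = cell,
        observed = observed, truth_homolog = names(haps)[h])
    }
  }
  out
}

#' Construct a single fragment observation
#'
#' @param fragment_id Label such as `"2-1"` (cell-homolog).
#' @param cell_id Integer cell index.
#' @param observed Named character vector: site id -> observed haploid
#'   allele. The names are the covered sites.
#' @param truth_homolog `"paternal_origin_homolog"`,
#'   `"maternal_origin_homolog"`, or `"unknown"` (real data).
#' @return An object of class `fragment_observation`.
#' @export
fragment_observation <- function(fragment_id, cell_id = NA_integer_,
                                 observed = character(0),
                                 truth_homolog = "unknown") {
  truth_homolog <- match.arg(truth_homolog,
                             c("paternal_origin_homolog",
                               "maternal_origin_homolog", "unknown"))
  if (length(observed) && is.null(names(observed)))
    abort_invalid("observed alleles must be named by site id")
  if (!length(observed)) observed <- setNames(character(0), character(0))
  structure(list(fragment_id = as.character(fragment_id),
                 cell_id = as.integer(cell_id),
                 covered_sites = names(observed) %||% character(0),
                 observed = observed,
                 truth_homolog = truth_homolog),
            class = "fragment_observation")
}

#' Forward model: expected per-read mutant probability
#'
#' A read supports the mutant allele if it comes from a mutant molecule and
#' is called correctly, or from a non-mutant molecule miscalled towards the
#' mutant base:
#' `p_obs = f * (1 - eps_total) + (1 - f) * eps_target`.
#'
#' @param true_fraction Mutant molecule fraction f in \[0, 1\].
#' @param em An `error_model`.
#' @return The per-read mutant-support probability.
#' @export
expected_alt_fraction <- function(true_fraction, em = error_model()) {
  check_prob(true_fraction, "true_fraction")
  true_fraction * (1 - em$eps_total) + (1 - true_fraction) * em$eps_target
}

#' Simulate a deep targeted pileup at one site
#'
#' Draws the mutant-supporting read count binomially at the forward-model
#' probability [expected_alt_fraction()].
#'
#' @param true_fraction Mutant molecule fraction in \[0, 1\].
#' @param depth Total read depth (>= 1).
#' @param em An `error_model`.
#' @param seed Integer seed.
#' @param sample_label,chrom,pos,ref,alt Passed to [site_read_count()].
#' @return A `site_read_count`.
#' @examples
#' simulate_pileup(0.03, 10000, seed = 1)
#' @export
simulate_pileup <- function(true_fraction, depth, em = error_model(),
                            seed = 1L, sample_label = "sim",
                            chrom = NA_character_, pos = NA_integer_,
                            ref = NA_character_, alt = NA_character_) {
  check_prob(true_fraction, "true_fraction")
  if (!is.numeric(depth) || depth < 1)
    abort_invalid("depth must be a positive integer")
  local_seed(seed)
  k <- rbinom(1L, as.integer(depth), expected_alt_fraction(true_fraction, em))
  site_read_count(depth = depth, alt_count = k, sample_label = sample_label,
                  chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Allele fraction of a heterozygote/wild-type DNA mixture
#'
#' A prepared mosaic control mixes DNA from a heterozygous carrier into
#' wild-type DNA. A heterozygote carries the mutant allele on half its
#' chromosomes, so a mass proportion `het_mix_proportion` of carrier DNA
#' yields a mutant allele fraction of `het_mix_proportion / 2`. Printed
#' mixture percentages can be read either way; this is the converter from
#' the mass parametrization to the allele-fraction one.
#'
#' @param het_mix_proportion Mass proportion of heterozygous-carrier DNA in
#'   the mixture, in \[0, 1\].
#' @return The mutant allele fraction of the mixture.
#' @examples
#' mixture_allele_fraction(0.06) # 6% carrier DNA -> 3% allele fraction
#' @export
mixture_allele_fraction <- function(het_mix_proportion) {
  check_prob(het_mix_proportion, "het_mix_proportion")
  het_mix_proportion / 2
}

#' The default 16-marker STR identity panel
#'
#' The standard forensic marker set used for paternity confirmation,
#' including the Amel sex marker.
#'
#' @return Character vector of 16 marker names.
#' @export
str_marker_panel <- function() {
  c("D8S1179", "D21S11", "D7S820", "CSF1PO", "D3S1358", "TH01", "D13S317",
    "D16S539", "D2S1338", "D19S433", "vWA", "TPOX", "D18S51", "Amel",
    "D5S818", "FGA")
}

# Allele pool for one STR marker: eight equifrequent repeat-count alleles
# (heterozygosity 1 - 8/64 = 0.875) with a marker-specific base repeat so
# panels are visibly distinct. Amel carries X/Y instead.
str_allele_pool <- function(marker) {
  if (marker == "Amel") return(c("X", "Y"))
  base <- 6L + (sum(utf8ToInt(marker)) %% 10L)
  as.character(base + 0:7)
}

draw_str_genotype <- function(marker) {
  pool <- str_allele_pool(marker)
  if (identical(pool, c("X", "Y"))) return(c("X", "Y")) # male by default
  sample(pool, 2L, replace = TRUE)
}

#' Simulate an STR trio for paternity testing
#'
#' Parental genotypes are drawn from per-marker allele pools of eight
#' equifrequent repeat alleles (Amel is carried as X/Y). The child receives
#' one allele from the mother and one from the listed father if
#' `true_father`, otherwise from a freshly drawn unrelated male.
#'
#' @param marker_names Marker names; default [str_marker_panel()].
#' @param true_father Is the listed father the biological father?
#' @param seed Integer seed.
#' @return An `str_trio` data.frame with columns
#'   `marker, father_a1, father_a2, mother_a1, mother_a2, child_a1,
#'   child_a2`.
#' @export
simulate_str_trio <- function(marker_names = str_marker_panel(),
                              true_father = TRUE, seed = 1L) {
  if (length(marker_names) < 1L)
    abort_invalid("marker_names must contain at least one marker")
  local_seed(seed)
  rows <- lapply(marker_names, function(m) {
    fa <- draw_str_genotype(m)
    mo <- if (m == "Amel") c("X", "X") else draw_str_genotype(m)
    bio <- if (true_father) fa else draw_str_genotype(m)
    child <- c(sample(mo, 1L), sample(bio, 1L))
    data.frame(marker = m, father_a1 = fa[1], father_a2 = fa[2],
               mother_a1 = mo[1], mother_a2 = mo[2],
               child_a1 = child[1], child_a2 = child[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("str_trio", "data.frame")
  out
}
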