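test_that("window listing keeps exactly the in-window SNPs, ranked by heterozygosity", {
  case <- load_case()
  hits <- list_window_snps(case$panel, case$de_novo, window_bp = 5e6)
  # six markers inside 5 Mb; the two distant decoys are excluded
  expect_identical(hits$id,
                   c("rs11674718", "rs11899501", "rs113504229",
                     "rs191358413", "rs77356042", "rs11681613"))
  expect_true(all(diff(hits$pop_het) <= 0))
  expect_equal(nrow(list_window_snps(case$panel, case$de_novo,
                                     window_bp = 0)), 0L)
  expect_equal(nrow(list_window_snps(case$panel, case$de_novo,
                                     window_bp = 5e6, top_n = 2)), 2L)
})

test_that("window listing agrees with a brute-force filter on random panels", {
  for (seed in 1:20) {
    panel <- simulate_snp_panel(40, region_span = 2e7, seed = seed,
                                het_range = c(0, 0.5))
    anchor_pos <- panel$pos[17] + 13L
    while (anchor_pos %in% panel$pos) anchor_pos <- anchor_pos + 1L
    site <- mutation_site("m", "chr2", anchor_pos, "T", "A",
                          role = "apparent_de_novo")
    got <- list_window_snps(panel, site, window_bp = 3e6, min_het = 0.2)
    want <- panel[abs(panel$pos - site$pos) <= 3e6 & panel$pop_het >= 0.2, ]
    expect_setequal(got$id, want$id)
    expect_true(all(diff(got$pop_het) <= 0))
  }
})

test_that("fragment coverage identifies the single informative WGA product", {
  case <- load_case()
  covering <- vapply(case$fragments, fragment_covers, logical(1),
                     site = case$de_novo_id)
  ids <- vapply(case$fragments, `[[`, character(1), "fragment_id")
  expect_identical(ids[covering], "2-1")
  empty <- fragment_observation("x-1")
  expect_false(fragment_covers(empty, case$de_novo_id))
  full <- case$fragments[[which(ids == "2-1")]]
  expect_true(all(vapply(names(full$observed), fragment_covers,
                         logical(1), fragment = full)))
})

test_that("allele informativeness follows the parental-exclusivity rule", {
  expect_identical(snp_informativeness("T", c("T", "C"), c("C", "C")),
                   "PATERNAL_ONLY")
  expect_identical(snp_informativeness("T", c("C", "C"), c("T", "C")),
                   "MATERNAL_ONLY")
  expect_identical(snp_informativeness("T", c("T", "C"), c("T", "T")),
                   "AMBIGUOUS")
  expect_identical(snp_informativeness("G", c("T", "T"), c("C", "C")),
                   "INCONSISTENT")
})

test_that("fragment sets map onto the five interpretation scenarios", {
  case <- load_case()
  expect_identical(
    classify_fragment(case$fragments, case$known_id, case$de_novo_id,
                      case$trio),
    "MUT_WITH_SNPS")
  wt_frag <- list(fragment_observation(
    "w-1", observed = c("c.2939T>A" = "T", rs11674718 = "C")))
  expect_identical(
    classify_fragment(wt_frag, case$known_id, case$de_novo_id, case$trio),
    "WT_WITH_SNPS")
  expect_identical(
    classify_fragment(list(fragment_observation("e-1")), case$known_id,
                      case$de_novo_id, case$trio),
    "UNINFORMATIVE")
  both <- list(
    fragment_observation("b-1", observed = c("c.2939T>A" = "A")),
    fragment_observation("b-2", observed = c("c.2939T>A" = "T")))
  expect_identical(
    classify_fragment(both, case$known_id, case$de_novo_id, case$trio),
    "BOTH_ALLELES")
  two_site <- list(fragment_observation(
    "t-1", observed = c("c.2939T>A" = "A", "c.1322delT" = "AT")))
  expect_identical(
    classify_fragment(two_site, case$known_id, case$de_novo_id, case$trio),
    "MUT_WITH_KNOWN_WT")
  two_site_wt <- list(fragment_observation(
    "t-2", observed = c("c.2939T>A" = "T", "c.1322delT" = "A")))
  expect_identical(
    classify_fragment(two_site_wt, case$known_id, case$de_novo_id,
                      case$trio),
    "WT_WITH_KNOWN_MUT")
  expect_error(classify_fragment(list(), case$known_id, case$de_novo_id,
                                 case$trio), "non-empty")
})

test_that("scenario classification is total over a brute-force toy enumeration", {
  case <- load_case()
  scenarios <- c("BOTH_ALLELES", "MUT_WITH_KNOWN_WT", "WT_WITH_KNOWN_MUT",
                 "MUT_WITH_SNPS", "WT_WITH_SNPS", "UNINFORMATIVE")
  # one fragment over {de novo, known, 2 SNPs}: every site absent / ref / alt
  site_ids <- c("c.2939T>A", "c.1322delT", "rs11674718", "rs11899501")
  refs <- c("T", "AT", "C", "A"); alts <- c("A", "A", "T", "T")
  states <- expand.grid(s1 = 0:2, s2 = 0:2, s3 = 0:2, s4 = 0:2)
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    observed <- character(0)
    for (i in seq_along(st)) {
      if (st[i] == 1L) observed[site_ids[i]] <- refs[i]
      if (st[i] == 2L) observed[site_ids[i]] <- alts[i]
    }
    frag <- list(fragment_observation("toy", observed = observed))
    got <- classify_fragment(frag, case$known_id, case$de_novo_id,
                             case$trio)
    expect_true(got %in% scenarios)
    expect_length(got, 1L)
  }
})

test_that("the worked-example fragment phases the de novo mutation to the paternal chromosome in trans", {
  case <- load_case()
  call <- phase_de_novo(case$fragments, case$trio,
                        known_site = case$known_id,
                        de_novo_site = case$de_novo_id,
                        known_mutation_parent = "mother")
  expect_identical(call$origin, "paternal")
  expect_identical(call$scenario, "MUT_WITH_SNPS")
  expect_identical(call$phase_vs_known, "trans")
  expect_equal(call$n_concordant, 6L)
  expect_false(call$conflict)
  expect_true(all(call$supporting_snps$verdict == "PATERNAL_ONLY"))
  # the observed haplotype across the six ranked markers reads TTGGTT
  expect_identical(paste(call$supporting_snps$allele, collapse = ""),
                   "TTGGTT")
})

test_that("origin inference degrades to indeterminate, never the wrong parent", {
  case <- load_case()
  ids <- vapply(case$fragments, `[[`, character(1), "fragment_id")
  frag <- case$fragments[[which(ids == "2-1")]]
  # all-ambiguous support: make every SNP allele present in both parents
  amb <- frag
  amb$observed[c("rs11674718", "rs11899501", "rs113504229", "rs191358413",
                 "rs77356042", "rs11681613")] <- c("C", "A", "A", "C", "C",
                                                   "G")
  amb_call <- infer_origin(amb, case$trio, de_novo_site = case$de_novo_id)
  # every one of those alleles is carried by both parents
  expect_true(all(amb_call$supporting_snps$verdict == "AMBIGUOUS"))
  expect_identical(amb_call$origin, "indeterminate")
  expect_false(amb_call$conflict)
  expect_equal(amb_call$n_concordant, 0L)

  # mixed parental verdicts (5 paternal-only + 1 maternal-only) conflict
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "FATHER", "MOTHER", "PROBAND", sep = "\t"),
    paste("chr2", 100, "dn", "T", "A", ".", ".", ".", "GT",
          "0/0", "0/0", "0/1", sep = "\t"),
    vapply(1:5, function(i)
      paste("chr2", 100 + i, paste0("s", i), "C", "T", ".", ".", ".", "GT",
            "0/1", "0/0", "0/1", sep = "\t"), character(1)),
    paste("chr2", 200, "s6", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "0/1", sep = "\t")), tmp)
  mini <- read_trio_vcf(tmp)
  mixed <- fragment_observation("m-1", observed = c(
    dn = "A", s1 = "T", s2 = "T", s3 = "T", s4 = "T", s5 = "T", s6 = "G"))
  call <- infer_origin(mixed, mini, de_novo_site = "dn")
  expect_identical(call$origin, "indeterminate")
  expect_true(call$conflict)
  # an allele carried by neither parent is likewise a conflict
  bad <- frag
  bad$observed["rs11899501"] <- "G"   # father A/T, mother A/A
  call <- infer_origin(bad, case$trio, de_novo_site = case$de_novo_id)
  expect_identical(call$origin, "indeterminate")
  expect_true(call$conflict)

  expect_error(infer_origin(fragment_observation("n", observed =
                                                   c(rs11674718 = "T")),
                            case$trio, de_novo_site = case$de_novo_id),
               "de novo mutant allele")
})

test_that("phase resolution is the parity of origin vs known-mutation parent", {
  expect_identical(resolve_phase("paternal", "mother"), "trans")
  expect_identical(resolve_phase("maternal", "mother"), "cis")
  expect_identical(resolve_phase("indeterminate", "father"), "unknown")
})

test_that("noise-free simulated fragments never yield the wrong parent", {
  n_resolved <- 0L; n_right <- 0L
  for (seed in 1:150) {
    parent <- if (seed %% 2 == 0) "father" else "mother"
    cs <- sim_case(seed = seed, de_novo_parent = parent)
    gt <- trio_genotypes(cs$trio)
    frags <- simulate_fragments(cs$trio, n_cells = 1, capture_prob = 1,
                                site_dropout = 0, wga_error = 0,
                                seed = seed)
    call <- phase_de_novo(frags, gt,
                          known_mutation_parent =
                            if (parent == "father") "mother" else "father")
    truth <- if (parent == "father") "paternal" else "maternal"
    # degradation is only ever to indeterminate (all SNPs ambiguous)
    expect_true(call$origin %in% c(truth, "indeterminate"))
    if (call$origin != "indeterminate") {
      n_resolved <- n_resolved + 1L
      if (identical(call$origin, truth)) n_right <- n_right + 1L
    }
  }
  # accuracy is 100% whenever at least one covered SNP is informative
  # (all-ambiguous fragments are the only indeterminate source, noise-free)
  expect_identical(n_right, n_resolved)
  expect_gt(n_resolved, 100L)
})

test_that("conflict rate rises with WGA error", {
  conflict_rate <- function(wga_error, n = 250) {
    n_conf <- 0L; n_eval <- 0L
    for (seed in seq_len(n)) {
      cs <- sim_case(seed = seed + 7000, de_novo_parent = "father")
      frags <- simulate_fragments(cs$trio, n_cells = 1, capture_prob = 1,
                                  site_dropout = 0, wga_error = wga_error,
                                  seed = seed)
      gt <- trio_genotypes(cs$trio)
      dn <- "dn_mut"
      for (f in frags) {
        if (fragment_covers(f, dn) && f$observed[[dn]] == "A") {
          n_eval <- n_eval + 1L
          if (infer_origin(f, gt, de_novo_site = dn)$conflict)
            n_conf <- n_conf + 1L
          break
        }
      }
    }
    n_conf / max(n_eval, 1L)
  }
  r0 <- conflict_rate(0)
  r1 <- conflict_rate(0.05)
  r2 <- conflict_rate(0.2)
  expect_identical(r0, 0)
  expect_lt(r0, r1)
  expect_lt(r1, r2)
})
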