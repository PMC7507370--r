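# Shared fixture builders. The packaged worked-example files live in
# inst/extdata; everything else is built in code.

ext_file <- function(name) {
  system.file("extdata", name, package = "microseqr", mustWork = TRUE)
}

load_case <- function() {
  trio <- suppressWarnings(read_trio_vcf(ext_file("trio_2q36.vcf")))
  list(
    panel = read_panel_tsv(ext_file("panel_2q36.tsv")),
    trio = trio,
    fragments = read_fragments_tsv(ext_file("fragments_2q36.tsv")),
    pileup = read_pileup_tsv(ext_file("sperm_tngs.pileup.tsv")),
    known_id = "c.1322delT", de_novo_id = "c.2939T>A",
    de_novo = mutation_site("c.2939T>A", "chr2", 228160000L, "T", "A",
                            role = "apparent_de_novo"),
    known = mutation_site("c.1322delT", "chr2", 228100000L, "AT", "A",
                          role = "known_inherited"))
}

# A small simulated case: panel + trio + mutations, used across modules.
sim_case <- function(seed = 1L, n_snps = 8L, mosaic_fraction = 0.03,
                     de_novo_parent = "father",
                     het_range = c(0.3, 0.5)) {
  panel <- simulate_snp_panel(n_snps, region_span = 4e6,
                              het_range = het_range, seed = seed,
                              region_start = 226000000L)
  span <- range(panel$pos)
  pick_pos <- function(offset) {
    p <- span[1] + offset
    while (p %in% panel$pos) p <- p + 1L
    p
  }
  known <- mutation_site("known_mut", "chr2", pick_pos(101L), "AT", "A",
                         role = "known_inherited")
  dn <- mutation_site("dn_mut", "chr2", pick_pos(211L), "T", "A",
                      role = "apparent_de_novo")
  trio <- simulate_trio(panel, known, dn, de_novo_parent = de_novo_parent,
                        mosaic_fraction = mosaic_fraction, seed = seed)
  list(panel = panel, known = known, dn = dn, trio = trio)
}

# Independent oracle for detection power: enumerate every possible alt
# count, apply detect_mosaic() itself to each, and sum the binomial mass.
brute_power <- function(f, depth, em = error_model(),
                        config = detection_config()) {
  ks <- 0:depth
  pass <- vapply(ks, function(k)
    detect_mosaic(site_read_count(depth, k), em, config)$detected,
    logical(1))
  sum(dbinom(ks[pass], depth, expected_alt_fraction(f, em)))
}
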