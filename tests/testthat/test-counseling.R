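str_row <- function(marker, fa, mo, ch) {
  data.frame(marker = marker, father_a1 = fa[1], father_a2 = fa[2],
             mother_a1 = mo[1], mother_a2 = mo[2], child_a1 = ch[1],
             child_a2 = ch[2], stringsAsFactors = FALSE)
}

test_that("paternity verdicts partition exactly on the exclusion count", {
  ok <- do.call(rbind, lapply(paste0("M", 1:5), str_row,
                              fa = c("12", "14"), mo = c("10", "11"),
                              ch = c("10", "12")))
  expect_identical(paternity_check(ok)$verdict, "confirmed")
  expect_equal(paternity_check(ok)$n_exclusions, 0L)

  one_bad <- rbind(ok, str_row("M6", c("12", "14"), c("10", "11"),
                               c("10", "19")))
  res <- paternity_check(one_bad)
  expect_equal(res$n_exclusions, 1L)
  expect_identical(res$verdict, "inconclusive")

  two_bad <- rbind(one_bad, str_row("M7", c("12", "14"), c("10", "11"),
                                    c("11", "19")))
  res <- paternity_check(two_bad)
  expect_equal(res$n_exclusions, 2L)
  expect_identical(res$verdict, "excluded")

  # the child allele pair is unordered: either assignment may rescue
  swapped <- str_row("M8", c("10", "11"), c("12", "14"), c("10", "12"))
  expect_identical(paternity_check(swapped)$verdict, "confirmed")
})

test_that("Amel is a sex check only and missing markers are skipped with a warning", {
  trio <- rbind(
    str_row("M1", c("12", "14"), c("10", "11"), c("10", "12")),
    str_row("Amel", c("X", "Y"), c("X", "X"), c("X", "19")),
    str_row("M2", c("12", "14"), c("10", "11"), c(".", ".")))
  expect_warning(res <- paternity_check(trio), "M2")
  expect_equal(res$n_exclusions, 0L)
  expect_identical(unname(res$per_marker[["Amel"]]), "sex_inconsistent")
  expect_identical(res$verdict, "confirmed")
})

test_that("simulated trios confirm true fathers and exclude unrelated males", {
  for (seed in 1:30) {
    expect_equal(
      paternity_check(simulate_str_trio(true_father = TRUE,
                                        seed = seed))$n_exclusions, 0L)
  }
  verdicts <- vapply(1:200, function(seed)
    paternity_check(simulate_str_trio(true_father = FALSE,
                                      seed = seed))$verdict, character(1))
  expect_gte(mean(verdicts == "excluded"), 0.95)
})

test_that("recurrence risk is the sperm fraction scaled by the transmission factor", {
  expect_identical(recurrence_risk(0.03, "AR", TRUE)$recurrence_risk, 0.015)
  expect_identical(recurrence_risk(0.0265, "AR", TRUE)$recurrence_risk,
                   0.01325)
  expect_identical(recurrence_risk(0, "AD")$recurrence_risk, 0)
  expect_identical(recurrence_risk(0.03, "AR", FALSE)$recurrence_risk, 0)
  # AR-with-carrier risk is exactly half the AD risk at equal fraction
  for (f in c(0.001, 0.0265, 0.2)) {
    ad <- recurrence_risk(f, "AD")$recurrence_risk
    ar <- recurrence_risk(f, "AR", TRUE)$recurrence_risk
    expect_identical(ar, ad / 2)
    for (m in c("AD", "XD", "YL"))
      expect_lte(recurrence_risk(f, m)$recurrence_risk, f)
  }
  expect_error(recurrence_risk(0.03, "AR"), "partner_carrier")
  expect_error(recurrence_risk(0.03, "XR"), "partner_carrier")
  expect_match(recurrence_risk(0.01, "YL")$narrative, "sons")
})

test_that("the decision engine reproduces the diagnostic path of the worked case", {
  sperm <- detect_mosaic(site_read_count(10000, 265,
                                         sample_label = "father_sperm"))
  state <- case_state(inheritance_mode = "AR", paternity_confirmed = TRUE,
                      parental_blood_tngs = "negative", origin = "paternal",
                      semen_available = TRUE, sperm_call = sperm)
  plan <- plan_case(state)
  expect_identical(plan$actions,
                   c("SPERM_TNGS", "RISK_ESTIMATE", "RECOMMEND_PGD_PND"))
  # purity: identical state gives an identical plan
  expect_identical(plan_case(state), plan)
})

test_that("decision rules branch on paternity, blood status, and origin", {
  # unknown paternity: the paternity test comes first
  p0 <- plan_case(case_state())
  expect_identical(p0$actions[1], "PATERNITY_TEST")
  # maternal origin: indirect evidence only, never sperm sequencing
  pm <- plan_case(case_state(paternity_confirmed = TRUE,
                             parental_blood_tngs = "negative",
                             origin = "maternal"))
  expect_true("MATERNAL_INDIRECT_EVIDENCE" %in% pm$actions)
  expect_false("SPERM_TNGS" %in% pm$actions)
  # positive parental blood reports somatic mosaicism
  pb <- plan_case(case_state(paternity_confirmed = TRUE,
                             parental_blood_tngs = "positive"))
  expect_true("REPORT_SOMATIC_MOSAIC" %in% pb$actions)
  # blood-negative without origin requires fragment-based origin work
  pn <- plan_case(case_state(paternity_confirmed = TRUE,
                             parental_blood_tngs = "negative"))
  expect_true("MICROSEQ_ORIGIN" %in% pn$actions)
  expect_match(pn$rationale[["MICROSEQ_ORIGIN"]], "trans/cis")
  # a negative sperm result reports de novo but carries the LOD caveat
  neg <- detect_mosaic(site_read_count(10000, 2))
  pd <- plan_case(case_state(paternity_confirmed = TRUE,
                             parental_blood_tngs = "negative",
                             origin = "paternal", sperm_call = neg))
  expect_true("REPORT_DE_NOVO" %in% pd$actions)
  expect_match(pd$rationale[["REPORT_DE_NOVO"]], "0.01")
  # the emitted sequence always respects the fixed precedence order
  prec <- c("PATERNITY_TEST", "BLOOD_TNGS", "MICROSEQ_ORIGIN", "SPERM_TNGS",
            "RISK_ESTIMATE", "RECOMMEND_PGD_PND", "REPORT_DE_NOVO",
            "REPORT_SOMATIC_MOSAIC", "MATERNAL_INDIRECT_EVIDENCE")
  for (p in list(p0, pm, pb, pn, pd)) {
    expect_false(anyDuplicated(p$actions) > 0)
    expect_true(!is.unsorted(match(p$actions, prec)))
  }
  expect_error(plan_case(case_state(apparent_de_novo = FALSE)),
               "de novo")
})

test_that("case reports aggregate every stage and round-trip through JSON", {
  empty <- build_report()
  expect_s3_class(empty, "case_report")
  expect_null(empty$origin)

  case <- load_case()
  sperm <- detect_mosaic(site_read_count(
    10000, 265, sample_label = "father_sperm", chrom = "chr2",
    pos = 228160000L, ref = "T", alt = "A"))
  origin <- phase_de_novo(case$fragments, case$trio,
                          known_site = case$known_id,
                          de_novo_site = case$de_novo_id,
                          known_mutation_parent = "mother")
  paternity <- paternity_check(read_str_tsv(ext_file("str_trio_case.tsv")))
  risk <- recurrence_risk(sperm$raw_fraction, "AR", TRUE)
  plan <- plan_case(case_state(
    paternity_confirmed = TRUE, parental_blood_tngs = "negative",
    origin = origin$origin, sperm_call = sperm))
  report <- build_report(calls = list(sperm), origin = origin,
                         paternity = paternity, risk = risk, plan = plan,
                         seed = 1L)
  expect_identical(report$origin$origin, "paternal")
  expect_identical(report$origin$phase_vs_known, "trans")
  expect_identical(report$risk$recurrence_risk, 0.01325)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  back <- read_report(path)
  expect_identical(back$origin$origin, "paternal")
  expect_equal(back$risk$recurrence_risk, 0.01325)
  expect_identical(back$plan$actions, plan$actions)
  expect_equal(back$config$alpha, 0.01)
})
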