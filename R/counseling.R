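# Counseling stage: paternity consistency, recurrence risk, and the
# decision engine that strings the diagnostic stages into a case plan.

#' Paternity check by Mendelian exclusion counting
#'
#' A marker is compatible when the child's two alleles can be assigned so
#' that one occurs in the mother's pair and the other in the father's pair.
#' The Amel sex marker is checked for sex consistency only and never
#' counted towards exclusions. Markers with missing genotypes are skipped
#' with a warning. No likelihood-ratio paternity index is computed —
#' exclusion counting only.
#'
#' @param trio An `str_trio` data.frame (see [simulate_str_trio()] /
#'   [read_str_tsv()]).
#' @param exclusion_threshold Number of incompatible markers required to
#'   exclude paternity. Default 2, allowing one exclusion for a germline
#'   STR mutation; a single exclusion is inconclusive.
#' @return A `paternity_result`: `per_marker` (named compatible/incompatible
#'   vector), `n_exclusions`, `verdict` (`confirmed` iff 0 exclusions,
#'   `excluded` iff >= threshold, else `inconclusive`).
#' @export
paternity_check <- function(trio, exclusion_threshold = 2L) {
  stopifnot(is.data.frame(trio), nrow(trio) >= 1)
  per_marker <- character(0)
  for (i in seq_len(nrow(trio))) {
    r <- trio[i, ]
    gts <- c(r$father_a1, r$father_a2, r$mother_a1, r$mother_a2,
             r$child_a1, r$child_a2)
    if (anyNA(gts) || any(gts == ".")) {
      warning("marker ", r$marker, " has missing genotypes; skipped",
              call. = FALSE)
      next
    }
    fa <- c(r$father_a1, r$father_a2); mo <- c(r$mother_a1, r$mother_a2)
    ch <- c(r$child_a1, r$child_a2)
    compatible <- (ch[1] %in% mo && ch[2] %in% fa) ||
      (ch[2] %in% mo && ch[1] %in% fa)
    if (r$marker == "Amel") {
      # Sex-consistency only: the child's pair must be attainable from an
      # X-bearing maternal gamete; never an exclusion.
      ok <- compatible
      per_marker[["Amel"]] <- if (ok) "compatible" else "sex_inconsistent"
      next
    }
    per_marker[[r$marker]] <- if (compatible) "compatible" else "incompatible"
  }
  n_excl <- sum(per_marker == "incompatible")
  verdict <- if (n_excl == 0) "confirmed"
             else if (n_excl >= exclusion_threshold) "excluded"
             else "inconclusive"
  structure(list(per_marker = per_marker, n_exclusions = as.integer(n_excl),
                 verdict = verdict,
                 exclusion_threshold = as.integer(exclusion_threshold)),
            class = "paternity_result")
}

#' @export
print.paternity_result <- function(x, ...) {
  cat("<paternity_result>", x$verdict, "(", x$n_exclusions,
      "exclusions over", length(x$per_marker), "markers )\n")
  invisible(x)
}

# Transmission factor: probability that a conception receiving the mosaic
# gamete is affected, by inheritance mode. Per conception, unconditional on
# offspring sex; sex-conditional refinements live in the narrative only.
transmission_factor <- function(mode, partner_carrier) {
  switch(mode,
    AD = 1,
    AR = if (isTRUE(partner_carrier)) 0.5 else 0,
    XD = 1,
    XR = if (isTRUE(partner_carrier)) 0.5 else 0,
    YL = 1)
}

#' Recurrence risk for a future child of a germline-mosaic father
#'
#' The risk is the sperm mutant allele fraction multiplied by the
#' probability that the mutant gamete produces an affected conception:
#' `risk = sperm_fraction * t`. The factors are `t = 1` for autosomal
#' dominant (the mosaic allele alone suffices), `t = 1/2` for autosomal
#' recessive with a carrier partner (the second pathogenic allele is
#' transmitted with probability 1/2) and `t = 0` without one; X-linked
#' dominant and Y-linked use `t = 1`, X-linked recessive mirrors the AR
#' factor. Risk is reported per conception, unconditional on offspring sex;
#' the narrative notes which sexes are at risk.
#'
#' @param sperm_fraction Mutant allele fraction measured in sperm, \[0, 1\].
#' @param mode Inheritance mode: `"AD"`, `"AR"`, `"XD"`, `"XR"`, `"YL"`.
#' @param partner_carrier Does the partner carry the second pathogenic
#'   allele? Required (TRUE/FALSE) for AR and XR.
#' @return A `risk_assessment`: `sperm_fraction`, `inheritance_mode`,
#'   `partner_carrier`, `recurrence_risk`, `narrative`.
#' @examples
#' recurrence_risk(0.03, "AR", partner_carrier = TRUE)  # risk 0.015
#' @export
recurrence_risk <- function(sperm_fraction,
                            mode = c("AD", "AR", "XD", "XR", "YL"),
                            partner_carrier = NULL) {
  mode <- match.arg(mode)
  check_prob(sperm_fraction, "sperm_fraction")
  if (mode %in% c("AR", "XR") && !is.logical(partner_carrier))
    abort_invalid("mode ", mode, " requires partner_carrier = TRUE or FALSE ",
                  "(the second pathogenic allele must be accounted for)")
  t <- transmission_factor(mode, partner_carrier)
  risk <- sperm_fraction * t
  narrative <- sprintf(
    paste0("Sperm mutant allele fraction %.4g; mode %s (transmission factor ",
           "%.2g%s). Estimated recurrence risk per conception: %.4g.%s"),
    sperm_fraction, mode, t,
    if (mode %in% c("AR", "XR"))
      sprintf(", partner carrier: %s", partner_carrier) else "",
    risk,
    switch(mode,
           XD = " Risk concentrated in daughters (father's X).",
           XR = " Affected conceptions are daughters receiving both alleles.",
           YL = " Risk confined to sons.", ""))
  structure(list(sperm_fraction = as.numeric(sperm_fraction),
                 inheritance_mode = mode,
                 partner_carrier = partner_carrier %||% NA,
                 recurrence_risk = risk, narrative = narrative),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment>", x$narrative, "\n")
  invisible(x)
}

#' Describe the current evidence state of a case
#'
#' @param inheritance_mode `"AD"`, `"AR"`, `"XD"`, `"XR"`, `"YL"`.
#' @param apparent_de_novo Was an apparent de novo mutation identified by
#'   regular genetic testing? The workflow only applies when TRUE.
#' @param paternity_confirmed Optional logical; NULL while untested.
#' @param parental_blood_tngs Optional `"negative"`/`"positive"` deep
#'   sequencing of parental blood; NULL while untested.
#' @param origin Optional `"paternal"`/`"maternal"`/`"indeterminate"`;
#'   NULL while undetermined.
#' @param semen_available Can sperm be sampled for deep sequencing?
#' @param sperm_call Optional `mosaic_call` from sperm; NULL while untested.
#' @param partner_carrier Carrier status of the partner (for AR/XR risk).
#' @return A `case_state` list.
#' @export
case_state <- function(inheritance_mode = "AR", apparent_de_novo = TRUE,
                       paternity_confirmed = NULL,
                       parental_blood_tngs = NULL, origin = NULL,
                       semen_available = TRUE, sperm_call = NULL,
                       partner_carrier = NULL) {
  if (!is.null(parental_blood_tngs))
    parental_blood_tngs <- match.arg(parental_blood_tngs,
                                     c("negative", "positive"))
  if (!is.null(origin))
    origin <- match.arg(origin, c("paternal", "maternal", "indeterminate"))
  structure(list(inheritance_mode = match.arg(inheritance_mode,
                                              c("AD", "AR", "XD", "XR", "YL")),
                 apparent_de_novo = isTRUE(apparent_de_novo),
                 paternity_confirmed = paternity_confirmed,
                 parental_blood_tngs = parental_blood_tngs,
                 origin = origin, semen_available = isTRUE(semen_available),
                 sperm_call = sperm_call,
                 partner_carrier = partner_carrier),
            class = "case_state")
}

PLAN_ACTIONS <- c("PATERNITY_TEST", "BLOOD_TNGS", "MICROSEQ_ORIGIN",
                  "SPERM_TNGS", "RISK_ESTIMATE", "RECOMMEND_PGD_PND",
                  "REPORT_DE_NOVO", "REPORT_SOMATIC_MOSAIC",
                  "MATERNAL_INDIRECT_EVIDENCE")

#' Plan the diagnostic workup of an apparent de novo mutation
#'
#' A pure, deterministic decision engine for single-patient germline
#' mosaicism. Rules, in order of evidence: unknown paternity demands the
#' paternity test first; unknown parental blood status demands deep blood
#' sequencing; a positive blood result reports somatic mosaicism (with the
#' risk path); blood-negative with unknown origin requires
#' microdissection-based origin determination — for recessive modes this is
#' also the only route to the trans/cis proof; a paternal origin with semen
#' available leads to sperm deep sequencing and risk estimation; a maternal
#' origin can only be supported indirectly (oocytes are not obtainable); a
#' detected sperm mosaic leads to risk estimation and a PGD/PND
#' recommendation, while a negative sperm result is reported as de novo —
#' with the caveat that mosaicism below the detection limit is not
#' excluded.
#'
#' @param state A `case_state` with `apparent_de_novo = TRUE`.
#' @param config A `detection_config` (its `lod_fraction` is quoted in the
#'   negative-sperm rationale).
#' @return A `case_plan`: `actions` (ordered, no repeats, in fixed
#'   precedence order) and a `rationale` string per action.
#' @export
plan_case <- function(state, config = detection_config()) {
  stopifnot(inherits(state, "case_state"))
  if (!state$apparent_de_novo)
    abort_invalid("the workflow applies only to an apparent de novo mutation")
  rationale <- character(0)
  add <- function(action, why) {
    if (!action %in% names(rationale)) rationale[[action]] <<- why
    rationale
  }
  if (is.null(state$paternity_confirmed))
    rationale <- add("PATERNITY_TEST",
                     "Paternity must be confirmed before any origin work.")
  if (is.null(state$parental_blood_tngs))
    rationale <- add("BLOOD_TNGS",
                     "Deep sequencing of parental blood rules somatic mosaicism in or out.")
  if (identical(state$parental_blood_tngs, "positive")) {
    rationale <- add("REPORT_SOMATIC_MOSAIC",
                     "Mutant allele present in parental blood: somatic (possibly gonosomal) mosaicism.")
    rationale <- add("RISK_ESTIMATE",
                     "Recurrence risk follows from the measured mosaic fraction.")
  }
  if (identical(state$parental_blood_tngs, "negative") &&
      (is.null(state$origin) || identical(state$origin, "indeterminate"))) {
    why <- "Blood-negative: only haploid fragment sequencing can assign the mutant chromosome's parental origin in a single patient."
    if (state$inheritance_mode %in% c("AR", "XR"))
      why <- paste(why, "Required for the trans/cis proof under a recessive mode.")
    rationale <- add("MICROSEQ_ORIGIN", why)
  }
  if (identical(state$origin, "paternal")) {
    if (state$semen_available) {
      rationale <- add("SPERM_TNGS",
                       "Paternal origin: quantify the mutant fraction directly in sperm.")
      rationale <- add("RISK_ESTIMATE",
                       "Recurrence risk follows from the sperm mutant fraction.")
    }
    if (!is.null(state$sperm_call)) {
      if (isTRUE(state$sperm_call$detected)) {
        rationale <- add("RISK_ESTIMATE",
                         sprintf("Sperm mosaic detected at raw fraction %.4g.",
                                 state$sperm_call$raw_fraction))
        rationale <- add("RECOMMEND_PGD_PND",
                         "Confirmed germline mosaicism: offer preimplantation or prenatal diagnosis.")
      } else {
        rationale <- add("REPORT_DE_NOVO",
                         sprintf(paste0("Sperm negative: consistent with a true de novo event; germline ",
                                        "mosaicism below the %.3g detection limit is not excluded."),
                                 config$lod_fraction))
      }
    }
  }
  if (identical(state$origin, "maternal"))
    rationale <- add("MATERNAL_INDIRECT_EVIDENCE",
                     "Maternal origin: oocytes cannot be sampled; only indirect evidence of germline mosaicism is attainable.")
  actions <- PLAN_ACTIONS[PLAN_ACTIONS %in% names(rationale)]
  structure(list(actions = actions, rationale = rationale[actions]),
            class = "case_plan")
}

#' @export
print.case_plan <- function(x, ...) {
  cat("<case_plan>\n")
  for (a in x$actions) cat(" -", a, "—", x$rationale[[a]], "\n")
  invisible(x)
}

#' Aggregate all stage outputs into one case report
#'
#' @param calls List of `mosaic_call`s (may be empty).
#' @param origin An `origin_call` or NULL.
#' @param paternity A `paternity_result` or NULL.
#' @param risk A `risk_assessment` or NULL.
#' @param plan A `case_plan` or NULL.
#' @param config A `detection_config` recorded for provenance.
#' @param em An `error_model` recorded for provenance.
#' @param seed Seed(s) used upstream, recorded for provenance.
#' @return A `case_report` list that serializes losslessly to JSON via
#'   [write_report()] / [read_report()].
#' @export
build_report <- function(calls = list(), origin = NULL, paternity = NULL,
                         risk = NULL, plan = NULL,
                         config = detection_config(), em = error_model(),
                         seed = NULL) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  structure(list(
    software = list(package = "microseqr",
                    version = as.character(packageVersion("microseqr"))),
    config = unclass(config), error_model = unclass(em), seed = seed,
    mosaic_calls = lapply(calls, strip),
    origin = strip(origin), paternity = strip(paternity),
    risk = strip(risk), plan = strip(plan)), class = "case_report")
}

#' Write / read a case report as JSON
#'
#' @param report A `case_report`.
#' @param path Output file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the parsed `case_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "case_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE),
            class = "case_report")
}
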