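# End-to-end verification: dynalog pair -> reconstructed plans -> doses ->
# agreement report with verdict.

#' Run the full treatment-verification workflow
#'
#' Merges a dynalog bank pair, reconstructs the delivered beam twice (from
#' the expected and from the actual leaf positions), computes both dose
#' distributions with the toy engine in the given phantom, and reports their
#' agreement per structure (PA and gamma pass rates), together with the
#' leaf-error statistics (RMS, MLE) of the field. When the original plan is
#' supplied, the original-vs-expected comparison -- the accuracy check of the
#' reconstruction itself -- is included as well. The verdict fails when the
#' PA of any target (PTV) structure does not exceed \code{pa_fail_threshold}
#' (default 99\%) in the expected-vs-actual comparison.
#'
#' @param bank_a,bank_b \code{dynalog_bank} objects or file paths.
#' @param plan optional original [rt_plan()] or RT Plan file path.
#' @param ph a [phantom()]; default [make_phantom()].
#' @param recon_cfg base [reconstruction_config()]; its \code{source} is
#'   overridden for the two reconstructions.
#' @param criteria list of gamma criteria pairs.
#' @param config toy dose engine configuration.
#' @param pa_fail_threshold verification-failure threshold on PA, percent.
#' @param dialect dynalog dialect used when paths are given.
#' @return a list of class \code{verification_result}: \code{report}
#'   (expected vs actual), \code{reconstruction_report} (original vs
#'   expected, when a plan was given), \code{pass}, \code{summary}.
#' @export
verify_workflow <- function(bank_a, bank_b, plan = NULL,
                            ph = make_phantom(),
                            recon_cfg = reconstruction_config("psr"),
                            criteria = list(c(2, 1), c(2, 2), c(3, 3)),
                            config = toy_dose_config(),
                            pa_fail_threshold = 99,
                            dialect = dynalog_dialect("clinac")) {
  if (is.character(bank_a)) bank_a <- parse_bank_file(bank_a, dialect)
  if (is.character(bank_b)) bank_b <- parse_bank_file(bank_b, dialect)
  if (is.character(plan)) plan <- read_rtplan(plan)
  field <- merge_banks(bank_a, bank_b)
  masks <- phantom_masks(ph)
  mu <- if (!is.null(plan)) plan$beams[[1L]]$meterset_mu else 100
  bounds <- if (!is.null(plan)) plan$beams[[1L]]$leaf_boundaries_cm else NULL
  cfg_exp <- recon_cfg; cfg_exp$source <- "expected"
  cfg_act <- recon_cfg; cfg_act$source <- "actual"
  beam_exp <- reconstruct(field, cfg_exp, meterset_mu = mu,
                          leaf_boundaries_cm = bounds)
  beam_act <- reconstruct(field, cfg_act, meterset_mu = mu,
                          leaf_boundaries_cm = bounds)
  dose_exp <- compute_dose(beam_exp, ph, config)
  dose_act <- compute_dose(beam_act, ph, config)
  report <- compare_doses(dose_exp, dose_act, masks, criteria, field = field)
  recon_report <- NULL
  if (!is.null(plan)) {
    dose_orig <- compute_dose(plan, ph, config)
    recon_report <- compare_doses(dose_orig, dose_exp, masks, criteria)
  }
  target <- grep("ptv", vapply(report$structures, `[[`, "", "structure"),
                 ignore.case = TRUE)
  if (length(target) == 0L) target <- seq_along(report$structures)
  pa_target <- vapply(report$structures[target], `[[`, 0, "pa")
  pass <- all(pa_target > pa_fail_threshold)
  structure(list(
    report = report, reconstruction_report = recon_report, pass = pass,
    summary = list(
      n_records = length(field$time_ms),
      n_control_points = n_control_points(beam_exp),
      rms_mm = rms_error(field), mle_mm = max_leaf_error(field),
      mode = recon_cfg$mode, pa_fail_threshold = pa_fail_threshold,
      min_target_pa = min(pa_target))),
    class = "verification_result")
}

#' @export
print.verification_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Verification (%s): %d records -> %d control points; RMS %.3f mm, MLE %.3f mm\n",
    s$mode, s$n_records, s$n_control_points, s$rms_mm, s$mle_mm))
  cat("-- expected vs actual dose --\n")
  print(x$report)
  if (!is.null(x$reconstruction_report)) {
    cat("-- original vs expected dose --\n")
    print(x$reconstruction_report)
  }
  cat(sprintf("Verdict: %s (min target PA %.2f%%, threshold %g%%)\n",
              if (x$pass) "PASS" else "FAIL", s$min_target_pa,
              s$pa_fail_threshold))
  invisible(x)
}
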