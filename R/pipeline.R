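#' Run the full synthetic study pipeline
#'
#' Simulate a claims bundle, identify practices on the measure-year
#' patient-sharing networks, build the diabetic cohort, compute the
#' per-patient measure panel, and (optionally) fit practice-clustered GLMMs
#' for a set of outcomes. When `out_dir` is given, every stage's tables are
#' written as CSV so that repeated runs with the same configuration can be
#' compared byte for byte.
#'
#' @param config a [sim_config()].
#' @param codesets a [codeset_config()].
#' @param min_shared,walk_length,gate identification-stage parameters (see
#'   [identify_practices()]).
#' @param min_visits,min_patients cohort-stage parameters (see
#'   [build_cohort()]).
#' @param model_outcomes named character vector: outcome column ->
#'   family (see [fit_glmm()]); `NULL` skips model fitting.
#' @param model_covariates adjustment covariates for the models.
#' @param out_dir optional output directory for stage CSVs.
#' @return List with `bundle`, `partitions`, `practice_set`, `cohort`,
#'   `attribution`, `panel`, `recovery` (ARI and per-area modularity), `fits`
#'   and `model_table`.
#' @export
run_pipeline <- function(config = sim_config(),
                         codesets = codeset_config(),
                         min_shared = 30, walk_length = 4, gate = 0.4,
                         min_visits = 2, min_patients = 20,
                         model_outcomes = c(eye_exam = "binomial_logit",
                                            mci_any_pcp = "normal_identity",
                                            visits_any_provider = "negbin_log"),
                         model_covariates = c("age10", "male", "dual"),
                         out_dir = NULL) {
  bundle <- simulate_claims(config, codesets)

  partitions <- identify_practices(bundle$visits, bundle$providers, codesets,
                                   year = 2015, min_shared = min_shared,
                                   walk_length = walk_length, gate = gate)
  pset <- gate_and_assign(partitions, bundle$providers, gate = gate,
                          min_patients = min_patients,
                          attributed_counts = NULL)
  built <- build_cohort(bundle$visits, pset, bundle$beneficiaries, codesets,
                        min_visits = min_visits, min_patients = min_patients)
  cohort <- built$cohort
  pset <- built$practice_set

  panel <- build_measure_panel(cohort, bundle$visits, bundle$prescriptions,
                               bundle$facility_stays, bundle$providers,
                               pset, codesets)

  recovered <- stats::setNames(pset$membership$practice_id,
                               pset$membership$provider_id)
  truth <- truth_partition(bundle)
  recovery <- list(
    ari = partition_ari(recovered, truth),
    modularity = vapply(partitions, `[[`, numeric(1), "modularity"),
    n_candidate = nrow(pset$practices),
    n_included = sum(pset$practices$included))

  fits <- list(); model_table <- NULL
  if (!is.null(model_outcomes)) {
    mdata <- merge(panel, cohort[cohort$included,
                                 c("patient_id", "practice_id", "team_type",
                                   "age_on_index", "sex", "dual_eligible")],
                   by = "patient_id")
    mdata$age10 <- (mdata$age_on_index - 75) / 10
    mdata$male <- as.numeric(mdata$sex == "male")
    mdata$dual <- as.numeric(mdata$dual_eligible)
    for (oc in names(model_outcomes)) {
      y <- mdata[[oc]]
      if (is.logical(y)) mdata[[oc]] <- as.numeric(y)
      fits[[oc]] <- fit_glmm(mdata, oc, family = model_outcomes[[oc]],
                             covariates = model_covariates)
    }
    model_table <- do.call(rbind, lapply(fits, tidy_glmm))
    rownames(model_table) <- NULL
  }

  out <- list(bundle = bundle, partitions = partitions, practice_set = pset,
              cohort = cohort, attribution = built$attribution, panel = panel,
              recovery = recovery, fits = fits, model_table = model_table)

  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

#' Write all pipeline result tables as CSV
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(result$practice_set$practices, "practices.csv")
  w(result$practice_set$membership, "practice_membership.csv")
  w(result$cohort, "cohort.csv")
  w(cohort_flow(result$cohort), "cohort_flow.csv")
  w(result$panel, "measure_panel.csv")
  mod <- data.frame(area_id = names(result$recovery$modularity),
                    modularity = unname(result$recovery$modularity))
  w(mod, "area_modularity.csv")
  if (!is.null(result$model_table)) w(result$model_table, "model_results.csv")
  invisible(dir)
}
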