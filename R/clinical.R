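# Clinical table handling, the GTV1-SliceNum feature, two-year labels and
# feature-importance ranking.

.clinical_required <- c("PatientID", "age", "clinical.T.Stage",
                        "Clinical.N.Stage", "Clinical.M.Stage",
                        "Overall.Stage", "Histology", "gender",
                        "Survival.time", "deadstatus.event")

#' Load a clinical CSV
#'
#' Reads the cohort clinical table (columns `PatientID`, `age`,
#' `clinical.T.Stage`, `Clinical.N.Stage`, `Clinical.M.Stage`,
#' `Overall.Stage`, `Histology`, `gender`, `Survival.time`,
#' `deadstatus.event`) into typed records. Ages above 200 are taken to be
#' recorded in days and converted to years (with a message); missing or
#' blank cells are preserved as `NA`. Survival time is in days from
#' treatment start; `deadstatus.event` is 1 for an observed death, 0 for a
#' censored observation.
#'
#' @param path CSV path (comma separated, header row).
#' @return data.frame with columns `patient_id`, `age` (years), `t_stage`,
#'   `n_stage`, `m_stage`, `overall_stage`, `histology`, `gender`,
#'   `survival_time`, `deadstatus_event`, and `gtv1_slice_num` (`NA` until
#'   filled by [add_gtv1_slice_num()]).
#' @export
load_clinical_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(.clinical_required, names(df))
  if (length(missing))
    ctsurv_abort(paste0("clinical CSV missing column(s): ",
                        paste(missing, collapse = ", ")),
                 "ctsurv_missing_column")
  age <- as.numeric(df$age)
  if (any(age > 200, na.rm = TRUE)) {
    message("ages above 200 interpreted as days; converted to years")
    age <- ifelse(!is.na(age) & age > 200, age / 365.25, age)
  }
  out <- data.frame(
    patient_id = as.character(df$PatientID),
    age = age,
    t_stage = suppressWarnings(as.integer(df$`clinical.T.Stage`)),
    n_stage = suppressWarnings(as.integer(df$`Clinical.N.Stage`)),
    m_stage = suppressWarnings(as.integer(df$`Clinical.M.Stage`)),
    overall_stage = as.character(df$`Overall.Stage`),
    histology = as.character(df$Histology),
    gender = as.character(df$gender),
    survival_time = as.numeric(df$`Survival.time`),
    deadstatus_event = as.integer(df$`deadstatus.event`),
    stringsAsFactors = FALSE
  )
  if (!"gtv1_slice_num" %in% names(df)) out$gtv1_slice_num <- NA_integer_
  else out$gtv1_slice_num <- as.integer(df$gtv1_slice_num)
  bad <- !is.na(out$survival_time) & out$survival_time <= 0
  if (any(bad)) warning(sum(bad), " record(s) with non-positive survival time",
                        call. = FALSE)
  out
}

#' The GTV1-SliceNum feature for one patient
#'
#' The number of distinct CT slices carrying at least one GTV-1 contour --
#' with a fixed slice thickness this is a proxy for the tumor's
#' cranio-caudal extent (thickness in mm = slice count x slice thickness).
#' A slice with several GTV-1 regions counts once. Errors (excluding the
#' patient) when the ROI is absent.
#'
#' @param series a `ct_series`.
#' @param ss a `structure_set`.
#' @inheritParams gtv1_slice_uids
#' @return non-negative integer.
#' @export
gtv1_slice_num <- function(series, ss, roi_name = "GTV-1", regex = FALSE) {
  length(gtv1_slice_uids(series, ss, roi_name, regex))
}

#' Append GTV1-SliceNum to a clinical table
#'
#' @param records a [load_clinical_csv()] data.frame.
#' @param counts named integer vector mapping `patient_id` to slice count.
#' @return the records with `gtv1_slice_num` filled where known.
#' @export
add_gtv1_slice_num <- function(records, counts) {
  j <- match(records$patient_id, names(counts))
  records$gtv1_slice_num <- ifelse(is.na(j), records$gtv1_slice_num,
                                   as.integer(counts[j]))
  records
}

#' Two-year survival labels
#'
#' Labels each record 1 when survival exceeds two years (strictly more than
#' 730 days; exactly 730 is labelled 0). Under `"discard_censored"`,
#' censored records (`deadstatus_event == 0`) are removed before labelling.
#' Under `"include_censored"`, a censored patient with follow-up beyond 730
#' days is a known long survivor (label 1); a censored patient with shorter
#' follow-up is labelled 0, although the true class is unknown -- such
#' records are flagged in the `label_uncertain` column.
#'
#' @param records a [load_clinical_csv()] data.frame.
#' @param policy `"discard_censored"` or `"include_censored"`.
#' @param cutoff_days classification threshold (default 730).
#' @return object of class `labeled_cohort`: the retained records plus
#'   `label` and `label_uncertain` columns, with the policy in
#'   `attr(, "policy")`.
#' @export
label_two_year <- function(records,
                           policy = c("discard_censored", "include_censored"),
                           cutoff_days = 730) {
  policy <- match.arg(policy)
  if (policy == "discard_censored")
    records <- records[records$deadstatus_event == 1L, , drop = FALSE]
  records$label <- as.integer(records$survival_time > cutoff_days)
  records$label_uncertain <- records$deadstatus_event == 0L &
    records$survival_time <= cutoff_days
  rownames(records) <- NULL
  structure(records, policy = policy, class = c("labeled_cohort",
                                                "data.frame"))
}

.mode_impute <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  x[is.na(x)] <- names(tab)[1]
  x
}

#' Feature-importance ranking of the clinical covariates
#'
#' Fits a decision tree or random forest to the two-year label on the
#' clinical covariates (age, T/N/M stage, overall stage, histology, gender,
#' GTV1-SliceNum) and returns impurity-based importances normalized to sum
#' to one, ranked descending. Ordinal/numeric covariates are median-imputed
#' and categoricals mode-imputed (with fixed, sorted level order) before the
#' fit; the fit is deterministic given `seed`.
#'
#' @param cohort a [label_two_year()] result.
#' @param model `"decision_tree"` (CART) or `"random_forest"`.
#' @param seed RNG seed.
#' @param ntree trees for the random forest.
#' @param extra_features optional data.frame of additional numeric columns
#'   (aligned with `cohort`) to enter the ranking.
#' @return data.frame `feature`, `importance` (sums to 1), sorted
#'   descending.
#' @export
feature_importance <- function(cohort,
                               model = c("decision_tree", "random_forest"),
                               seed = 1L, ntree = 500L,
                               extra_features = NULL) {
  model <- match.arg(model)
  if (length(unique(cohort$label)) < 2L)
    ctsurv_abort("cohort has a single class; importances undefined",
                 "ctsurv_degenerate_cohort")
  num_cols <- c("age", "t_stage", "n_stage", "m_stage", "gtv1_slice_num")
  cat_cols <- c("overall_stage", "histology", "gender")
  X <- cohort[, intersect(c(num_cols, cat_cols), names(cohort)), drop = FALSE]
  X <- as.data.frame(X)
  for (cc in intersect(num_cols, names(X))) {
    v <- as.numeric(X[[cc]])
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    X[[cc]] <- v
  }
  for (cc in intersect(cat_cols, names(X))) {
    v <- .mode_impute(as.character(X[[cc]]))
    X[[cc]] <- factor(v, levels = sort(unique(v)))
  }
  if (!is.null(extra_features)) X <- cbind(X, extra_features)
  X <- X[, vapply(X, function(v) length(unique(v)) > 0L, TRUE), drop = FALSE]
  y <- factor(cohort$label, levels = c(0, 1))
  set.seed(seed)
  if (model == "decision_tree") {
    fit <- rpart::rpart(y ~ ., data = cbind(X, y = y), method = "class",
                        control = rpart::rpart.control(cp = 0.001,
                                                       minsplit = 5L))
    imp <- fit$variable.importance
    raw <- stats::setNames(rep(0, ncol(X)), names(X))
    raw[names(imp)] <- imp
  } else {
    fit <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                      importance = FALSE)
    gi <- randomForest::importance(fit, type = 2)
    raw <- stats::setNames(as.numeric(gi), rownames(gi))
  }
  if (sum(raw) > 0) raw <- raw / sum(raw)
  out <- data.frame(feature = names(raw), importance = as.numeric(raw),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
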