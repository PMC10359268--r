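#' The four diagnostic prediction tasks
#'
#' Slide-level binary contrasts used throughout the package: disease
#' detection (any anemia or MDS vs. control), disease classification (MDS vs.
#' deficiency anemia), MDS genetic subtyping (SF3B1-mutant vs. SF3B1-wildtype
#' MDS) and anemia classification (iron-deficiency vs. megaloblastic anemia).
#' Each task is defined only on its eligible slides; elsewhere the label is NA.
#'
#' @export
cyto_tasks <- c("disease_detection", "disease_classification",
                "mds_subtyping", "anemia_classification")

#' Recognized clinical conditions
#' @export
cyto_conditions <- c("control", "IDA", "MA", "MDS_SF3B1", "MDS_other")

#' Task labels implied by a clinical condition
#'
#' @param condition One of [cyto_conditions].
#' @return Named numeric vector over [cyto_tasks]; NA marks an ineligible
#'   slide for that task.
#' @export
condition_labels <- function(condition) {
  condition <- match.arg(condition, cyto_conditions)
  is_mds <- condition %in% c("MDS_SF3B1", "MDS_other")
  is_anemia <- condition %in% c("IDA", "MA")
  c(
    disease_detection = as.numeric(condition != "control"),
    disease_classification = if (is_mds) 1 else if (is_anemia) 0 else NA_real_,
    mds_subtyping = if (condition == "MDS_SF3B1") 1
                    else if (condition == "MDS_other") 0 else NA_real_,
    anemia_classification = if (condition == "MA") 1
                            else if (condition == "IDA") 0 else NA_real_
  )
}

#' Bundle one slide's cells, blood counts and labels
#'
#' A slide bag is the unit of multiple-instance learning: all per-cell feature
#' vectors of one smear (WBC and RBC separately), the slide's blood counts
#' when available, and its task labels.
#'
#' @param slide_id Character scalar.
#' @param wbc_features,rbc_features Numeric matrices (cells x features); may
#'   have zero rows.
#' @param blood_counts Named numeric vector with entries `wbcc` (cells/uL),
#'   `hb` (g/dL) and `plt` (platelets/uL); NA where unknown.
#' @param labels Named numeric vector over [cyto_tasks] (0/1/NA), or a
#'   condition name via `condition` from which labels are derived.
#' @param condition Optional clinical condition, stored for reference.
#' @return An object of class `slide_bag`.
#' @export
slide_bag <- function(slide_id, wbc_features, rbc_features,
                      blood_counts = c(wbcc = NA_real_, hb = NA_real_,
                                       plt = NA_real_),
                      labels = NULL, condition = NULL) {
  wbc_features <- as.matrix(wbc_features)
  rbc_features <- as.matrix(rbc_features)
  if (nrow(wbc_features) && any(!is.finite(wbc_features))) {
    stop("non-finite WBC features in slide ", slide_id, call. = FALSE)
  }
  if (nrow(rbc_features) && any(!is.finite(rbc_features))) {
    stop("non-finite RBC features in slide ", slide_id, call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(condition)) condition_labels(condition) else
      stats::setNames(rep(NA_real_, length(cyto_tasks)), cyto_tasks)
  }
  if (!all(names(labels) %in% cyto_tasks)) {
    stop("labels must be named by the four defined tasks", call. = FALSE)
  }
  full <- stats::setNames(rep(NA_real_, length(cyto_tasks)), cyto_tasks)
  full[names(labels)] <- labels
  structure(
    list(slide_id = slide_id, wbc_features = wbc_features,
         rbc_features = rbc_features, blood_counts = blood_counts,
         labels = full, condition = condition),
    class = "slide_bag"
  )
}

#' @export
print.slide_bag <- function(x, ...) {
  cat(sprintf("<slide_bag %s: %d WBC x %d, %d RBC x %d, condition=%s>\n",
              x$slide_id, nrow(x$wbc_features), ncol(x$wbc_features),
              nrow(x$rbc_features), ncol(x$rbc_features),
              x$condition %||% "?"))
  invisible(x)
}

#' Tabulate slide-level metadata for a list of bags
#'
#' @param bags List of [slide_bag()] objects.
#' @return Tibble with one row per slide: id, condition, cell counts, blood
#'   counts and the four task labels.
#' @export
bags_metadata <- function(bags) {
  purrr::map_dfr(bags, function(b) {
    tibble::tibble(
      slide_id = b$slide_id,
      condition = b$condition %||% NA_character_,
      n_wbc = nrow(b$wbc_features), n_rbc = nrow(b$rbc_features),
      wbcc = b$blood_counts[["wbcc"]], hb = b$blood_counts[["hb"]],
      plt = b$blood_counts[["plt"]],
      !!!as.list(b$labels)
    )
  })
}
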