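# Post-hoc statistics linking morphotypes to expert annotations and clinical
# conditions: enrichment ratios with chi-squared tests, condition
# proportion-ratio contrasts with top-k selection, 2-D embedding density
# ratios, and external-validation AUC with its standard error.

#' Morphotype x annotated-type enrichment table
#'
#' For morphotype (CM) `c` and annotated type `t`,
#' `enrichment(c, t) = [n(c,t)/n(c)] / [n(t)/N]` — the over-representation of
#' type `t` within CM `c` relative to its overall prevalence. Each (CM, type)
#' pair is tested with a continuity-corrected chi-squared test on the 2x2
#' table (in CM vs. not) x (type vs. not), with Benjamini-Hochberg correction
#' across the grid. For every type, `sum_c P(c) * enrichment(c, t) = 1`.
#'
#' @param assignments Integer/character vector: hard CM label per annotated
#'   cell (argmax of the soft assignment; ties broken by lowest index).
#' @param annotations Character vector: expert type per cell.
#' @param alpha Significance level after adjustment.
#' @return Object of class `enrichment_table` (a tibble with counts, ratios
#'   and test results).
#' @export
enrichment <- function(assignments, annotations, alpha = 0.05) {
  stopifnot(length(assignments) == length(annotations))
  N <- length(assignments)
  tab <- table(cm = assignments, type = annotations)
  n_cm <- rowSums(tab)
  n_type <- colSums(tab)
  grid <- tidyr::expand_grid(cm = rownames(tab), type = colnames(tab))
  out <- purrr::pmap_dfr(grid, function(cm, type) {
    n_ct <- tab[cm, type]
    enr <- (n_ct / n_cm[[cm]]) / (n_type[[type]] / N)
    m2 <- matrix(c(n_ct, n_cm[[cm]] - n_ct,
                   n_type[[type]] - n_ct,
                   N - n_cm[[cm]] - n_type[[type]] + n_ct), 2)
    pv <- tryCatch(
      suppressWarnings(stats::chisq.test(m2, correct = TRUE)$p.value),
      error = function(e) NA_real_)
    tibble::tibble(cm = cm, type = type, n_cm = n_cm[[cm]],
                   n_type = n_type[[type]], n_both = n_ct, n_total = N,
                   enrichment = enr, p_value = pv)
  })
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  structure(out, class = c("enrichment_table", class(out)))
}

#' @export
tidy.enrichment_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.enrichment_table <- function(x, ...) {
  tibble::tibble(n_cells = x$n_total[1], n_cm = length(unique(x$cm)),
                 n_types = length(unique(x$type)),
                 n_significant = sum(x$significant))
}

#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$type, y = factor(.data$cm),
                               fill = log2(pmax(.data$enrichment, 2^-4)))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "annotated type", y = "morphotype",
                  fill = "log2 enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Hard morphotype labels from soft assignments
#'
#' @param A Soft-assignment matrix (cells x K).
#' @return Integer vector of argmax labels; ties broken by lowest index.
#' @export
hard_assignments <- function(A) {
  apply(A, 1, which.max)
}

#' Condition-contrast proportion ratios with top-k selection
#'
#' For each morphotype, the ratio of the median per-slide proportion in
#' condition A to that in condition B; the `top_k` morphotypes with the
#' highest absolute difference in median proportions (the "median effect
#' size") are flagged as selected. Swapping the contrast inverts the ratios.
#'
#' @param proportions Tibble with columns `slide_id`, `condition`,
#'   `morphotype`, `proportion` (long format; see [slide_proportions()]).
#' @param contrast Length-2 character vector `c(A, B)` of condition labels.
#' @param top_k Number of morphotypes to select.
#' @param effect `"median_diff"` (absolute difference of medians, default) or
#'   `"standardized"` (difference scaled by the pooled MAD).
#' @return Tibble per morphotype: medians, `ratio` (Inf flagged when the B
#'   median is 0), `effect`, `selected`.
#' @export
proportion_ratio <- function(proportions, contrast, top_k = 5,
                             effect = c("median_diff", "standardized")) {
  effect <- match.arg(effect)
  stopifnot(length(contrast) == 2)
  pa <- dplyr::filter(proportions, .data$condition == contrast[1])
  pb <- dplyr::filter(proportions, .data$condition == contrast[2])
  if (!nrow(pa) || !nrow(pb)) {
    stop("both contrast conditions need at least one slide", call. = FALSE)
  }
  med <- function(df) dplyr::summarise(
    dplyr::group_by(df, .data$morphotype),
    median_prop = stats::median(.data$proportion),
    mad_prop = stats::mad(.data$proportion), .groups = "drop")
  m <- dplyr::full_join(med(pa), med(pb), by = "morphotype",
                        suffix = c("_a", "_b"))
  m <- dplyr::mutate(m,
    ratio = .data$median_prop_a / .data$median_prop_b,
    infinite = .data$median_prop_b == 0,
    effect = if (effect == "median_diff") {
      abs(.data$median_prop_a - .data$median_prop_b)
    } else {
      abs(.data$median_prop_a - .data$median_prop_b) /
        pmax((.data$mad_prop_a + .data$mad_prop_b) / 2, 1e-12)
    })
  m <- dplyr::arrange(m, dplyr::desc(.data$effect))
  m$selected <- seq_len(nrow(m)) <= top_k
  dplyr::select(m, "morphotype", "median_prop_a", "median_prop_b", "ratio",
                "infinite", "effect", "selected")
}

#' Long-format per-slide morphotype proportions
#'
#' @param P Matrix from [slide_proportions()] (slides x K, rownames =
#'   slide ids).
#' @param conditions Named vector or tibble mapping slide_id to condition.
#' @return Long tibble: `slide_id`, `condition`, `morphotype`, `proportion`.
#' @export
proportions_long <- function(P, conditions) {
  P <- matrix(as.numeric(P), nrow(P), ncol(P),
              dimnames = list(rownames(P), as.character(seq_len(ncol(P)))))
  tb <- tibble::as_tibble(P, rownames = "slide_id")
  long <- tidyr::pivot_longer(tb, -"slide_id", names_to = "morphotype",
                              values_to = "proportion")
  long$morphotype <- as.integer(long$morphotype)
  if (is.data.frame(conditions)) {
    dplyr::left_join(long, conditions, by = "slide_id")
  } else {
    dplyr::mutate(long, condition = unname(conditions[.data$slide_id]))
  }
}

#' Per-point class-density ratio in a 2-D embedding
#'
#' A Gaussian kernel density estimate is computed per class at every point;
#' the ratio is the density of the locally predominant (maximum-density)
#' class divided by the summed density of all classes, as used to shade
#' class-dominance maps of cytomorphology embeddings.
#'
#' @param embedding n x 2 matrix of embedding coordinates.
#' @param classes Class label per point.
#' @param bandwidth Kernel bandwidth (> 0), same units as the embedding.
#' @return Numeric vector of ratios in \[1/n_classes, 1\]; 1 everywhere when
#'   only one class is present.
#' @export
density_ratio <- function(embedding, classes, bandwidth = 1) {
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2, bandwidth > 0,
            nrow(embedding) == length(classes))
  cls <- unique(classes)
  if (length(cls) == 1) return(rep(1, nrow(embedding)))
  dens <- sapply(cls, function(cl) {
    pts <- embedding[classes == cl, , drop = FALSE]
    d2 <- outer(embedding[, 1], pts[, 1], "-")^2 +
      outer(embedding[, 2], pts[, 2], "-")^2
    rowMeans(exp(-d2 / (2 * bandwidth^2))) / (2 * pi * bandwidth^2)
  })
  apply(dens, 1, max) / pmax(rowSums(dens), 1e-300)
}

#' External-validation AUC with standard error
#'
#' AUC by the rank (Mann-Whitney) statistic, with standard error `1/sqrt(n)`
#' and the interval `[max(AUC - se, 0), min(AUC + se, 1)]`.
#'
#' @param scores Predicted probabilities/scores on the validation cohort.
#' @param labels Binary labels.
#' @return One-row tibble: `auc`, `se`, `lower`, `upper`, `n`.
#' @export
external_validate <- function(scores, labels) {
  a <- auc_rank(scores, labels)
  n <- length(labels)
  se <- 1 / sqrt(n)
  tibble::tibble(auc = a, se = se,
                 lower = max(a - se, 0), upper = min(a + se, 1), n = n)
}
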