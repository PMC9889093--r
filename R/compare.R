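#' Assign random blind codes to samples
#'
#' Before analysis, samples are assigned random numeric codes so the analyst
#' is blind to the preparation condition. Codes are a seeded random
#' permutation of zero-padded integers; the map is bijective and regenerates
#' identically for the same ids and seed.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param seed Integer seed.
#' @return A `blinding_map` tibble with columns `sample_id`, `blind_code`.
#' @export
blind_assign <- function(sample_ids, seed = 1L) {
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(sample_ids)
  width <- max(3L, nchar(as.character(n)))
  codes <- with_seed(seed, sample(n))
  out <- tibble::tibble(
    sample_id = as.character(sample_ids),
    blind_code = formatC(codes, width = width, flag = "0")
  )
  attr(out, "seed") <- seed
  class(out) <- c("blinding_map", class(out))
  out
}

#' Re-key blinded results back to sample ids
#'
#' Joins results keyed by `blind_code` onto a [blind_assign()] map, restoring
#' the original sample order (the map's order, i.e. manifest order). Codes in
#' the results that are absent from the map are an error; samples without
#' results are kept with `NA` values and flagged.
#'
#' @param results A data frame with a `blind_code` column.
#' @param map A `blinding_map`.
#' @return The results re-keyed by `sample_id`, in map order, with attribute
#'   `missing_ids` listing samples that had no result rows.
#' @export
unblind <- function(results, map) {
  stopifnot(inherits(map, "blinding_map"))
  if (!"blind_code" %in% names(results)) {
    stop("`results` must have a `blind_code` column", call. = FALSE)
  }
  unknown <- setdiff(unique(results$blind_code), map$blind_code)
  if (length(unknown)) {
    stop("unknown blind codes: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(map, tibble::as_tibble(results), by = "blind_code")
  missing_ids <- map$sample_id[!map$blind_code %in% results$blind_code]
  if (length(missing_ids)) {
    message("no results for: ", paste(missing_ids, collapse = ", "))
  }
  attr(out, "missing_ids") <- missing_ids
  class(out) <- setdiff(class(out), "blinding_map")
  out
}

#' Mean and standard error of replicate values
#'
#' @param values Numeric replicate measurements (e.g. half-max depths, µm).
#' @return A one-row tibble `n`, `mean_um`, `sem_um`; `sem_um` is `NA` for a
#'   single replicate (sample SD with n−1 denominator over sqrt(n)).
#' @export
summarize_condition <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no replicate values", call. = FALSE)
  n <- length(values)
  tibble::tibble(
    n = n,
    mean_um = mean(values),
    sem_um = if (n >= 2) sd(values) / sqrt(n) else NA_real_
  )
}

sig_label <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = "ns"
  )
}

#' Two-sided t-test of a condition against baseline
#'
#' Student's pooled-variance two-sample t-test by default (Welch by flag),
#' two-tailed, with the conventional significance labels p < 0.05 = `*`,
#' p < 0.01 = `**`, otherwise `ns`. If both groups have zero variance and
#' equal means, p = 1 by convention (p = 0 when the constant means differ).
#'
#' @param cond_values,baseline_values Numeric replicate values, each n >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A one-row tibble `t`, `df`, `p`, `sig_label`, `variant`.
#' @export
ttest_vs_baseline <- function(cond_values, baseline_values,
                              variant = c("student", "welch")) {
  variant <- match.arg(variant)
  cond_values <- cond_values[!is.na(cond_values)]
  baseline_values <- baseline_values[!is.na(baseline_values)]
  if (length(cond_values) < 2 || length(baseline_values) < 2) {
    stop("both groups need at least 2 replicates", call. = FALSE)
  }
  if (sd(cond_values) == 0 && sd(baseline_values) == 0) {
    same <- mean(cond_values) == mean(baseline_values)
    t_stat <- if (same) 0 else sign(mean(cond_values) - mean(baseline_values)) * Inf
    p <- if (same) 1 else 0
    df <- length(cond_values) + length(baseline_values) - 2
  } else {
    fit <- stats::t.test(cond_values, baseline_values,
                         var.equal = variant == "student")
    t_stat <- unname(fit$statistic)
    df <- unname(fit$parameter)
    p <- fit$p.value
  }
  tibble::tibble(t = t_stat, df = df, p = p, sig_label = sig_label(p),
                 variant = variant)
}

#' Compare all conditions against the baseline protocol
#'
#' Aggregates replicate half-max depths per condition (mean, SEM) and tests
#' every non-baseline condition against the baseline with a two-tailed
#' t-test, separately within each fluorophore group (conditions are never
#' compared across fluorophores). No multiplicity adjustment is applied by
#' default, matching the per-condition star convention; `bonferroni = TRUE`
#' multiplies p-values by the number of comparisons in the group (capped at
#' 1) and is recorded in the output.
#'
#' @param halfmax A tibble of per-replicate results with columns
#'   `condition_id`, `half_max_depth_um`, and optionally `replicate_id`,
#'   `fluorophore`, `baseline` (logical).
#' @param baseline Baseline `condition_id`; defaults to the condition flagged
#'   in a logical `baseline` column.
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @param bonferroni Apply Bonferroni correction within each group.
#' @return A `staining_comparison` tibble: one row per condition with `n`,
#'   `mean_um`, `sem_um`, `t`, `df`, `p`, `sig_label` (baseline row has `NA`
#'   test fields). Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
compare_conditions <- function(halfmax, baseline = NULL,
                               variant = c("student", "welch"),
                               bonferroni = FALSE) {
  variant <- match.arg(variant)
  halfmax <- tibble::as_tibble(halfmax)
  if (!"fluorophore" %in% names(halfmax) || all(is.na(halfmax$fluorophore))) {
    halfmax$fluorophore <- "all"
  }
  if (is.null(baseline)) {
    if (!"baseline" %in% names(halfmax)) {
      stop("supply `baseline` or a logical `baseline` column", call. = FALSE)
    }
  } else {
    halfmax$baseline <- halfmax$condition_id %in% baseline
  }
  out <- halfmax |>
    dplyr::group_by(.data$fluorophore) |>
    dplyr::group_modify(function(df, key) {
      base_ids <- unique(df$condition_id[df$baseline])
      if (length(base_ids) != 1) {
        stop("group `", key[[1]], "` must have exactly one baseline condition (found ",
             length(base_ids), ")", call. = FALSE)
      }
      base_vals <- df$half_max_depth_um[df$condition_id == base_ids]
      conds <- unique(df$condition_id)
      n_tests <- length(conds) - 1L
      purrr::map_dfr(conds, function(cid) {
        vals <- df$half_max_depth_um[df$condition_id == cid]
        n_def <- sum(!is.na(vals))
        summ <- if (n_def) {
          summarize_condition(vals)
        } else {
          # e.g. staining never fell below half-maximum in any replicate
          tibble::tibble(n = 0L, mean_um = NA_real_, sem_um = NA_real_)
        }
        na_test <- tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                                  sig_label = NA_character_, variant = variant)
        if (cid == base_ids || n_def < 2 || sum(!is.na(base_vals)) < 2) {
          tt <- na_test
        } else {
          tt <- ttest_vs_baseline(vals, base_vals, variant)
          if (bonferroni) {
            tt$p <- min(1, tt$p * n_tests)
            tt$sig_label <- sig_label(tt$p)
          }
        }
        tibble::tibble(condition_id = cid, baseline = cid == base_ids,
                       summ, tt["t"], df = tt$df, p = tt$p,
                       sig_label = tt$sig_label)
      })
    }) |>
    dplyr::ungroup()
  attr(out, "variant") <- variant
  attr(out, "bonferroni") <- bonferroni
  class(out) <- c("staining_comparison", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.staining_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "staining_comparison")
  attr(out, "variant") <- NULL
  attr(out, "bonferroni") <- NULL
  out
}

#' @export
glance.staining_comparison <- function(x, ...) {
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$fluorophore),
    n_conditions = dplyr::n_distinct(x$condition_id),
    n_significant = sum(x$sig_label %in% c("*", "**")),
    variant = attr(x, "variant"),
    bonferroni = attr(x, "bonferroni")
  )
}

#' Export a depth-by-condition heatmap matrix
#'
#' Averages normalized scores over replicates and pivots them to a matrix of
#' rows = depth, columns = condition — the layout used for staining-quality
#' heatmaps. Profiles shorter than the deepest one are padded with `NA`.
#'
#' @param scores A [normalize_across_conditions()] result (optionally
#'   filtered to one fluorophore group).
#' @param file Optional CSV path to write.
#' @return A tibble with `depth_um` and one column per condition.
#' @export
export_heatmap_matrix <- function(scores, file = NULL) {
  if (!nrow(scores)) stop("no scores to export", call. = FALSE)
  mat <- scores |>
    dplyr::group_by(.data$condition_id, .data$plane, .data$depth_um) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(score = ifelse(is.nan(.data$score), NA_real_, .data$score)) |>
    dplyr::arrange(.data$plane) |>
    tidyr::pivot_wider(id_cols = c("plane", "depth_um"),
                       names_from = "condition_id", values_from = "score") |>
    dplyr::select(-"plane")
  if (!is.null(file)) readr::write_csv(mat, file, na = "")
  mat
}
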