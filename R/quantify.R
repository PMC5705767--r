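#' Build per-cell profiles from annotated spots
#'
#' One row per cell: spot counts per channel and compartment, pre-mRNA
#' calls, foci statistics and mean protein intensities. The population
#' mean transcripts per cell is also computed with the field estimator —
#' total spot count divided by the number of nuclei — and stored alongside
#' the mean of per-cell counts (the two agree exactly when no spot falls
#' outside a cell).
#'
#' @param annotated_spots Spot tibble after [assign_compartments()] (and
#'   optionally [call_pre_mrna()]), with `channel`, `compartment`,
#'   `cell_id`.
#' @param foci Optional [detect_foci()] output.
#' @param intensities Optional [measure_cell_intensity()] output (per
#'   cell).
#' @param labels A `cell_geometry`/`segmentation_labels` object (defines
#'   the cell universe and border cells).
#' @param condition,timepoint Optional labels attached to every row.
#' @return A `cell_profiles` tibble; attributes `population_estimator`
#'   (named per channel) and `n_nuclei`.
#' @export
build_cell_profiles <- function(annotated_spots, foci = NULL,
                                intensities = NULL, labels,
                                condition = NA_character_,
                                timepoint = NA_real_) {
  stopifnot(inherits(labels, "cell_geometry"))
  n_nuclei <- length(setdiff(unique(labels$nuclei[labels$nuclei > 0L]), 0L))
  cell_ids <- sort(setdiff(unique(labels$cells[labels$cells > 0L]), 0L))
  if (nrow(annotated_spots) > 0 &&
      any(!is.na(annotated_spots$cell_id) &
            !(annotated_spots$cell_id %in% cell_ids))) {
    abort("annotated spots refer to cell ids absent from the labels")
  }

  base <- tibble(cell_id = cell_ids)
  if (nrow(annotated_spots) > 0) {
    counts <- annotated_spots |>
      filter(!is.na(.data$cell_id), .data$compartment != "outside") |>
      dplyr::count(.data$cell_id, .data$channel, .data$compartment) |>
      tidyr::pivot_wider(names_from = c("channel", "compartment"),
                         values_from = "n", names_prefix = "n_",
                         values_fill = 0L)
    totals <- annotated_spots |>
      filter(!is.na(.data$cell_id), .data$compartment != "outside") |>
      dplyr::count(.data$cell_id, .data$channel) |>
      tidyr::pivot_wider(names_from = "channel", values_from = "n",
                         names_prefix = "n_", values_fill = 0L)
    base <- base |> left_join(counts, by = "cell_id") |>
      left_join(totals, by = "cell_id")
    if ("species_call" %in% names(annotated_spots)) {
      pre <- annotated_spots |>
        filter(.data$species_call == "pre_mRNA",
               .data$channel == "intron", !is.na(.data$cell_id)) |>
        dplyr::count(.data$cell_id, name = "n_pre_mrna")
      base <- left_join(base, pre, by = "cell_id")
    }
  }
  if (!is.null(foci) && nrow(foci) > 0) {
    fsum <- foci |>
      filter(!is.na(.data$cell_id)) |>
      group_by(.data$cell_id) |>
      summarise(n_foci = n(),
                foci_transcript_equivalents =
                  sum(.data$transcript_equivalent))
    base <- left_join(base, fsum, by = "cell_id")
  }
  if (!is.null(intensities)) {
    base <- left_join(
      base,
      dplyr::rename(intensities, cell_id = "region_id",
                    mean_protein_intensity = "mean_intensity") |>
        select("cell_id", "mean_protein_intensity"),
      by = "cell_id")
  }
  base <- base |>
    mutate(across(dplyr::everything(), ~ tidyr::replace_na(., 0)),
           border_cell = cell_ids %in% border_cells(labels),
           condition = condition, timepoint = timepoint)

  pop <- NULL
  if (nrow(annotated_spots) > 0 && n_nuclei > 0) {
    pop <- annotated_spots |>
      dplyr::count(.data$channel) |>
      mutate(per_cell = .data$n / n_nuclei)
    pop <- setNames(pop$per_cell, pop$channel)
  }
  class(base) <- c("cell_profiles", class(base))
  attr(base, "population_estimator") <- pop
  attr(base, "n_nuclei") <- n_nuclei
  base
}

border_cells <- function(labels) {
  cells <- labels$cells
  d <- dim(cells)
  edge <- unique(c(cells[c(1, d[1]), , ], cells[, c(1, d[2]), ],
                   cells[, , c(1, d[3])]))
  setdiff(edge, 0L)
}

#' Summarise cell profiles per condition
#'
#' Per-condition mean, median and CV of every numeric per-cell metric,
#' plus percent-of-reference for the means — the reporting style used for
#' drug time courses (e.g. "decreased to 65%, recovered to 86%"). Border
#' cells are excluded by default to avoid truncation bias.
#'
#' @param profiles A `cell_profiles` tibble (rows from several conditions
#'   may be bound together).
#' @param reference_condition Condition the percentages refer to.
#' @param drop_border_cells Exclude cells touching the field border.
#' @return Long tibble: `condition`, `metric`, `n_cells`, `mean`,
#'   `median`, `cv`, `percent_of_reference`.
#' @export
summarize_conditions <- function(profiles, reference_condition,
                                 drop_border_cells = TRUE) {
  if (!reference_condition %in% profiles$condition) {
    abort(sprintf("reference condition '%s' not present",
                  reference_condition))
  }
  dat <- profiles
  if (drop_border_cells && "border_cell" %in% names(dat)) {
    dat <- filter(dat, !.data$border_cell)
  }
  long <- dat |>
    select(-dplyr::any_of(c("border_cell", "timepoint"))) |>
    tidyr::pivot_longer(-c("cell_id", "condition"), names_to = "metric",
                        values_to = "value") |>
    group_by(.data$condition, .data$metric) |>
    summarise(n_cells = n(), mean = mean(.data$value),
              median = median(.data$value),
              cv = ifelse(mean(.data$value) > 0,
                          sd(.data$value) / mean(.data$value), NA_real_),
              .groups = "drop")
  ref <- long |>
    filter(.data$condition == reference_condition) |>
    select("metric", ref_mean = "mean")
  long |>
    left_join(ref, by = "metric") |>
    mutate(percent_of_reference = ifelse(.data$ref_mean > 0,
                                         100 * .data$mean / .data$ref_mean,
                                         NA_real_)) |>
    select(-"ref_mean")
}

#' Ratio of a measurement to a reference measurement
#'
#' Plain quotient used to normalise external assay values (e.g. RNA-seq
#' read counts relative to a housekeeping gene, western band intensities
#' relative to actin) before cross-assay comparison.
#'
#' @param target_value,reference_value Numeric vectors (recycled).
#' @return `target_value / reference_value`.
#' @export
ratio_to_reference <- function(target_value, reference_value) {
  if (any(!is.finite(reference_value)) || any(reference_value <= 0)) {
    abort("`reference_value` must be positive")
  }
  target_value / reference_value
}

#' Correlate pipeline measurements with an external assay
#'
#' Inner-joins the two tables on a sample id and computes the Pearson (or
#' Spearman) correlation with a two-sided t-distribution p-value — the
#' concordance analysis used to benchmark image-based counts against
#' RNA-seq, western blotting or copy-number data.
#'
#' @param x_table,y_table Data frames with a shared id column and one
#'   value column each.
#' @param by Name of the id column (default `"sample_id"`).
#' @param x_col,y_col Value column names (default: first numeric column).
#' @param method `"pearson"` or `"spearman"`.
#' @return An `if_correlation` object; see [tidy()] and [glance()].
#' @export
correlate_measurements <- function(x_table, y_table, by = "sample_id",
                                   x_col = NULL, y_col = NULL,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pick <- function(tb, col) {
    col %||% setdiff(names(tb)[vapply(tb, is.numeric, TRUE)], by)[1]
  }
  x_col <- pick(x_table, x_col)
  y_col <- pick(y_table, y_col)
  joined <- inner_join(
    select(x_table, dplyr::all_of(c(by, x_col))),
    select(y_table, dplyr::all_of(c(by, y_col))),
    by = by, suffix = c("_x", "_y"))
  if (x_col == y_col) {
    x_col <- paste0(x_col, "_x")
    y_col <- paste0(y_col, "_y")
  }
  if (nrow(joined) < 3) abort("need at least 3 paired observations")
  xv <- joined[[x_col]]; yv <- joined[[y_col]]
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlation undefined: one input is constant")
  }
  ct <- cor.test(xv, yv, method = method)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(joined),
                 method = method, data = joined,
                 x_col = x_col, y_col = y_col),
            class = "if_correlation")
}

#' @export
print.if_correlation <- function(x, ...) {
  cat(sprintf("<if_correlation> %s r = %.3f (p = %.3g, n = %d)\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' @rdname correlate_measurements
#' @param x An `if_correlation` object.
#' @param ... Unused.
#' @export
tidy.if_correlation <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n = x$n, method = x$method)
}

#' @rdname correlate_measurements
#' @export
glance.if_correlation <- function(x, ...) tidy.if_correlation(x)
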