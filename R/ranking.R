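# Dataset-level processing: per-image measure records, normalization to a
# common 0-1 scale, composite scores, ranking, and order-preserving CSV
# output. The enumeration order of the dataset is never modified: ranking
# produces a separate sorted view, and the results file keeps the original
# row order so time-lapse recordings stay interpretable.

# measures with a sign: absolute values are taken before normalization
signed_measures <- c("skewness", "kurtosis")

# inverse columns materialized after normalization
inverse_map <- c(invSTD = "fSTD", invSkew = "skewness", invMeanBin = "MeanBin")

spectral_measure_names <- c("fMean", "fSTD", "cv", "skewness", "kurtosis",
                            "spectral_entropy", "high90", "MeanBin")

#' Compute the quality measures of a single image
#'
#' Evaluates the masked spatial entropy, the power-spectrum tail
#' statistics, and (optionally) the baseline autofocus metrics on one
#' image, returning one named value per measure.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param threshold Power-spectrum tail threshold in (0, 1); default 0.40.
#' @param spectrum_method `"summed"` (default, fast) or `"radial"`
#'   reduction of the 2D spectrum.
#' @param mask_radius Averaging-filter radius of the detail mask.
#' @param mask_percentile Detail-mask threshold percentile.
#' @param bins Histogram bin count for the entropy measure.
#' @param metrics Character vector among `"brenner"`,
#'   `"spectral_moments"` to append baseline metric values.
#' @return Named numeric vector: `entropy`, `fMean`, `fSTD`, `cv`,
#'   `skewness`, `kurtosis`, `spectral_entropy`, `high90`, `MeanBin`,
#'   plus any requested metric.
#' @export
measure_image <- function(img, threshold = 0.40, spectrum_method = "summed",
                          mask_radius = 100L, mask_percentile = 80,
                          bins = 256L, metrics = character()) {
  spectrum_method <- match.arg(spectrum_method, c("summed", "radial"))
  bad <- setdiff(metrics, c("brenner", "spectral_moments"))
  if (length(bad)) {
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ent <- spatial_entropy(img, mask_radius, mask_percentile, bins)
  ps <- power_spectrum_2d(img)
  ps1d <- if (spectrum_method == "summed") reduce_summed(ps) else
    reduce_radial(ps)
  st <- tail_stats(ps1d, threshold)
  out <- c(entropy = ent, unlist(st[spectral_measure_names]))
  if ("brenner" %in% metrics) out <- c(out, brenner = brenner(img)$value)
  if ("spectral_moments" %in% metrics) {
    out <- c(out, spectral_moments = spectral_moments(img)$value)
  }
  out
}

#' Compute measure records for a whole dataset
#'
#' Enumerates a directory with [list_dataset()] (or takes an explicit
#' vector of file paths), loads each image and evaluates
#' [measure_image()] on it. Images that fail to load or measure are
#' skipped with a warning rather than aborting the batch.
#'
#' @param x A dataset directory or a character vector of image file paths.
#' @param name_filter Optional filename substring filter (directories
#'   only), see [list_dataset()].
#' @inheritParams measure_image
#' @return A data.frame with `image_id` (filename) and one column per
#'   measure, rows in dataset enumeration order.
#' @export
measure_dataset <- function(x, name_filter = NULL, threshold = 0.40,
                            spectrum_method = "summed", mask_radius = 100L,
                            mask_percentile = 80, bins = 256L,
                            metrics = character()) {
  paths <- if (length(x) == 1L && dir.exists(x)) {
    list_dataset(x, name_filter)
  } else {
    x
  }
  rows <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    rows[[i]] <- tryCatch({
      img <- load_image(paths[i])
      vals <- suppressWarnings(
        measure_image(img, threshold, spectrum_method, mask_radius,
                      mask_percentile, bins, metrics))
      cbind(data.frame(image_id = basename(paths[i]),
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(vals)))
    }, error = function(e) {
      warning("skipping ", paths[i], ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no image in the dataset could be measured", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Normalize a table of measure records to a 0-1 scale
#'
#' Divides each measure column by its maximum value within the dataset so
#' every measure spans `[0, 1]` and becomes comparable with the others.
#' Signed measures (skewness, kurtosis) are replaced by their absolute
#' values first. A degenerate all-zero column maps to zeros with a
#' warning. Normalized columns are added with a `norm_` prefix, and the
#' inverse columns `invSTD`, `invSkew` and `invMeanBin`
#' (`1 - normalized value`) are materialized whenever their source
#' measure is present, so that noise-sensitive and blur-sensitive
#' rankings come out of a single pass.
#'
#' Ranking is relative by construction, so at least two records are
#' required.
#'
#' @param records A data.frame from [measure_dataset()]: `image_id` plus
#'   numeric measure columns.
#' @return A `ranking_table` (data.frame) with the raw columns, the
#'   `norm_*` columns and the inverse columns, rows in the input order.
#' @export
normalize_table <- function(records) {
  if (!is.data.frame(records) || !"image_id" %in% names(records)) {
    stop("`records` must be a data.frame with an `image_id` column",
         call. = FALSE)
  }
  if (nrow(records) < 2L) {
    stop("relative ranking requires at least 2 records", call. = FALSE)
  }
  measures <- setdiff(names(records), c("image_id", "label"))
  out <- records
  for (m in measures) {
    v <- records[[m]]
    if (!is.numeric(v)) next
    if (m %in% signed_measures) v <- abs(v)
    v[!is.finite(v)] <- 0
    mx <- max(v)
    if (mx == 0) {
      warning("measure '", m, "' is zero for every record; ",
              "normalized column set to 0", call. = FALSE)
      out[[paste0("norm_", m)]] <- rep(0, length(v))
    } else {
      out[[paste0("norm_", m)]] <- v / mx
    }
  }
  for (inv in names(inverse_map)) {
    src <- paste0("norm_", inverse_map[[inv]])
    if (src %in% names(out)) out[[inv]] <- invert_measure(out[[src]])
  }
  structure(out, class = c("ranking_table", "data.frame"),
            measures = measures)
}

# resolve a user-facing measure name to a normalized column of the table
resolve_measure <- function(table, m) {
  if (paste0("norm_", m) %in% names(table)) return(paste0("norm_", m))
  if (m %in% names(table) &&
      (m %in% c(names(inverse_map), "composite") || startsWith(m, "norm_"))) {
    return(m)
  }
  avail <- c(sub("^norm_", "", grep("^norm_", names(table), value = TRUE)),
             intersect(c(names(inverse_map), "composite"), names(table)))
  stop("unknown measure '", m, "'; available: ",
       paste(avail, collapse = ", "), call. = FALSE)
}

#' Composite quality score from several normalized measures
#'
#' Averages the selected normalized measures record by record. The
#' classic recipe for finding high-contrast, well-structured images is
#' the mean of the spatial `entropy` and `invSTD` (the inverted spectral
#' standard deviation, which penalizes noisy, dotty structure).
#'
#' @param table A `ranking_table` from [normalize_table()].
#' @param measures Character vector of measure names; normalized (`norm_`)
#'   and inverse (`invSTD`, ...) columns are resolved automatically.
#' @return The table with a `composite` column added.
#' @export
composite_score <- function(table, measures = c("entropy", "invSTD")) {
  stopifnot(inherits(table, "ranking_table"))
  cols <- vapply(measures, function(m) resolve_measure(table, m),
                 character(1))
  table$composite <- rowMeans(as.data.frame(table)[, cols, drop = FALSE])
  attr(table, "composite_measures") <- unname(measures)
  table
}

#' Rank the images of a table by a measure
#'
#' Returns a sorted view `(image_id, score)` without touching the row
#' order of the underlying table. Ties are broken by lexicographic
#' `image_id` so the ranking is deterministic.
#'
#' @param table A `ranking_table`.
#' @param key Measure name (resolved like in [composite_score()]) or
#'   `"composite"`.
#' @param descending Sort best-first (default `TRUE`).
#' @return data.frame `(image_id, score)` in rank order.
#' @export
rank_order <- function(table, key = "composite", descending = TRUE) {
  stopifnot(inherits(table, "ranking_table"))
  col <- resolve_measure(table, key)
  score <- table[[col]]
  o <- order(if (descending) -score else score, table$image_id,
             method = "radix")
  data.frame(image_id = table$image_id[o], score = score[o],
             stringsAsFactors = FALSE)
}

#' Write a results table to CSV in enumeration order
#'
#' Writes `image_id`, the raw measure columns, the normalized and inverse
#' columns and (when present) the composite score as a comma-separated
#' UTF-8 file with a header row. Rows keep the dataset enumeration order
#' -- the original image files are never renamed, moved or modified.
#' Floats are written with 9 significant digits, so normalized values
#' round-trip within 1e-9.
#'
#' @param table A `ranking_table` (or plain data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 9, format = "g")
    }
  }
  ok <- tryCatch({
    suppressWarnings(
      utils::write.table(df, path, sep = ",", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) {
    stop("cannot write results to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Three-way focus triage from a ranked measure
#'
#' Labels every record by comparing its score against two cut points on
#' the normalized 0-1 scale: `score < low_cut` is `out_of_focus`,
#' `low_cut <= score < high_cut` is `blurred`, and anything above is
#' `in_focus`. In screening time courses the lower cut captures the
#' autofocus failures while the upper cut flags slightly soft frames.
#'
#' @param table A `ranking_table`.
#' @param key Measure name to threshold (resolved like in
#'   [composite_score()]).
#' @param low_cut,high_cut Cut points with `0 <= low_cut <= high_cut <= 1`.
#' @return Character vector of labels, one per record, in table order.
#' @export
two_level_blur_flags <- function(table, key, low_cut, high_cut) {
  stopifnot(inherits(table, "ranking_table"))
  if (!(low_cut >= 0 && low_cut <= high_cut && high_cut <= 1)) {
    stop("cuts must satisfy 0 <= low_cut <= high_cut <= 1", call. = FALSE)
  }
  score <- table[[resolve_measure(table, key)]]
  ifelse(score < low_cut, "out_of_focus",
         ifelse(score < high_cut, "blurred", "in_focus"))
}
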