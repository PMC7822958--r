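#' Extract neighboring-channel stream connections from a DC matrix
#'
#' For each hemisphere and rostro-caudal stream, takes the directly
#' neighboring level pairs (1-2, 2-3, 3-4 on the full grid) and reads off
#' the directed-coherence value in each direction: rostro-caudal (lower to
#' higher level) and caudo-rostral. On the default 4 streams x 4 levels
#' grid this yields 12 connections per hemisphere per direction and 48 rows
#' per measurement.
#'
#' @param dc A `dc_matrix` (see [estimate_connectivity()]).
#' @param grid A [build_channel_grid()].
#' @return A data frame with columns `hemisphere`, `stream`, `level_pair`
#'   (e.g. `"1-2"`), `level` (rostral level of the pair, numeric),
#'   `direction` (`"rostro_caudal"`/`"caudo_rostral"`), `source`, `sink`,
#'   `dc`.
#' @export
extract_stream_connections <- function(dc, grid) {
  ana <- grid[grid$analyzed, , drop = FALSE]
  missing <- setdiff(ana$id, dc$channels)
  if (length(missing)) {
    stop("data error: channel(s) absent from DC matrix: ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  for (h in unique(ana$hemisphere)) {
    for (s in sort(unique(ana$stream[ana$hemisphere == h]))) {
      ch <- ana[ana$hemisphere == h & ana$stream == s, ]
      ch <- ch[order(ch$level), ]
      for (k in seq_len(nrow(ch) - 1)) {
        rostral <- ch$id[k]; caudal <- ch$id[k + 1]
        pair <- paste(ch$level[k], ch$level[k + 1], sep = "-")
        rows[[length(rows) + 1]] <- data.frame(
          hemisphere = h, stream = s, level_pair = pair, level = ch$level[k],
          direction = c("rostro_caudal", "caudo_rostral"),
          source = c(rostral, caudal), sink = c(caudal, rostral),
          dc = c(dc$dc[caudal, rostral], dc$dc[rostral, caudal]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$dc)) stop("data error: DC value missing for a stream connection")
  rownames(out) <- NULL
  out
}

#' Label hemispheres relative to the side of disease onset
#'
#' Motor symptoms at onset on one body side reflect a disease process that
#' began in the opposite hemisphere. With the default
#' `onset_is_body_side = TRUE`, the hemisphere *contralateral* to
#' `side_of_onset` is labeled `"ipsi"` (ipsilateral to the hemisphere of
#' disease onset) and the other `"contra"`. Set
#' `onset_is_body_side = FALSE` if `side_of_onset` already names the
#' affected hemisphere.
#'
#' @param table A connection table with a `hemisphere` column (and
#'   optionally a `side_of_onset` column used when the argument is `NULL`).
#' @param side_of_onset `"left"` or `"right"`, or `NULL` to take it from
#'   the table.
#' @param onset_is_body_side Interpret `side_of_onset` as the symptomatic
#'   body side (default) rather than the affected hemisphere.
#' @return The table with a `hemisphere_label` column (`"ipsi"`/`"contra"`).
#' @export
label_hemispheres <- function(table, side_of_onset = NULL,
                              onset_is_body_side = TRUE) {
  if (is.null(side_of_onset)) {
    if (!"side_of_onset" %in% names(table)) {
      stop("data error: side of disease onset missing")
    }
    side_of_onset <- table$side_of_onset
  }
  if (anyNA(side_of_onset) || !all(side_of_onset %in% c("left", "right"))) {
    stop("data error: side of disease onset missing or invalid")
  }
  onset_hemi <- if (onset_is_body_side) {
    ifelse(side_of_onset == "left", "right", "left")
  } else {
    side_of_onset
  }
  table$hemisphere_label <- ifelse(table$hemisphere == onset_hemi,
                                   "ipsi", "contra")
  table
}

#' Build the full connection table of a study
#'
#' Runs [extract_stream_connections()] for every measurement, joins the
#' participant covariates and labels hemispheres; the result is the
#' long-format input to [fit_lmm()].
#'
#' @param dc_list Named list of `dc_matrix` objects, names
#'   `participant.state`.
#' @param grid A [build_channel_grid()].
#' @param cohort A [generate_cohort()] data frame (or any data frame with
#'   a `participant` column and covariates, including `side_of_onset`).
#' @return A `connection_table` data frame: one row per directed connection
#'   per measurement, with participant, state, hemisphere labels, stream,
#'   level pair, direction, dc, and joined covariates.
#' @export
build_connection_table <- function(dc_list, grid, cohort) {
  rows <- lapply(names(dc_list), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tab <- extract_stream_connections(dc_list[[nm]], grid)
    tab$participant <- parts[1]
    tab$state <- parts[2]
    tab
  })
  out <- do.call(rbind, rows)
  out <- merge(out, as.data.frame(cohort), by = "participant", sort = FALSE)
  out <- label_hemispheres(out)
  class(out) <- c("connection_table", "data.frame")
  out
}

#' Summarize a connection table the way the figures present it
#'
#' Mean DC by direction x level pair, optionally split at the terciles of a
#' participant-level covariate (tercile boundaries computed on the unique
#' participant values, the projection device used for the figure panels).
#'
#' @param table A connection table.
#' @param tercile_by Optional covariate name for a tercile split.
#' @return A data frame of group means (`direction`, `level_pair`,
#'   optionally `tercile`, `mean_dc`, `n`). Empty groups are retained with
#'   `NA` mean and flagged via a warning, not an error.
#' @export
project_summary <- function(table, tercile_by = NULL) {
  if (!nrow(table)) stop("data error: empty connection table")
  groups <- list(direction = table$direction, level_pair = table$level_pair)
  if (!is.null(tercile_by)) {
    v <- table[[tercile_by]]
    pv <- tapply(v, table$participant, `[`, 1)
    br <- stats::quantile(pv, c(0, 1/3, 2/3, 1), names = FALSE)
    table$tercile <- cut(v, breaks = br, include.lowest = TRUE,
                         labels = c("low", "mid", "high"))
    groups$tercile <- table$tercile
  }
  agg <- stats::aggregate(table$dc, groups,
                          function(x) c(mean = mean(x), n = length(x)),
                          drop = FALSE)
  out <- data.frame(agg[names(groups)],
                    mean_dc = agg$x[, "mean"], n = agg$x[, "n"])
  out$n[is.na(out$n)] <- 0
  if (any(out$n == 0)) warning("empty group(s) in summary")
  out
}

#' Tercile membership of participants for a covariate
#'
#' @param cohort A cohort data frame.
#' @param covariate Covariate name.
#' @return Factor of tercile labels (`low`/`mid`/`high`) per participant.
#' @export
tercile_split <- function(cohort, covariate) {
  v <- cohort[[covariate]]
  br <- stats::quantile(v, c(0, 1/3, 2/3, 1), names = FALSE)
  cut(v, breaks = br, include.lowest = TRUE, labels = c("low", "mid", "high"))
}
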