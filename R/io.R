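#' Write a hemoglobin or optical time series to delimited text
#'
#' Signals are written as delimited matrices with a header row of channel
#' ids (samples as rows), one file per signal component
#' (`<stem>_hbo.tsv` / `<stem>_hbr.tsv`, or `<stem>_w1.tsv` /
#' `<stem>_w2.tsv` for optical data), plus a JSON metadata sidecar
#' (`<stem>_meta.json`) holding the sampling rate and, for optical data,
#' the wavelengths.
#'
#' @param ts A [hemo_ts()] or [optical_ts()].
#' @param stem Output path stem (directories are created).
#' @return Invisibly, the written file paths.
#' @export
write_timeseries <- function(ts, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, path) {
    utils::write.table(t(m), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  if (inherits(ts, "hemo_ts")) {
    paths <- paste0(stem, c("_hbo.tsv", "_hbr.tsv", "_meta.json"))
    wr(ts$hbo, paths[1]); wr(ts$hbr, paths[2])
    meta <- list(kind = "hemoglobin", fs = ts$fs, channels = ts$channels,
                 n_samples = ncol(ts$hbo))
  } else if (inherits(ts, "optical_ts")) {
    paths <- paste0(stem, c("_w1.tsv", "_w2.tsv", "_meta.json"))
    wr(ts$intensities[[1]], paths[1]); wr(ts$intensities[[2]], paths[2])
    meta <- list(kind = "optical", fs = ts$fs, channels = ts$channels,
                 wavelengths = ts$wavelengths,
                 n_samples = ncol(ts$intensities[[1]]))
  } else {
    stop("data error: unsupported time-series object")
  }
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

read_matrix_file <- function(path, channels) {
  m <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  got <- colnames(m)
  if (!identical(got, channels)) {
    bad <- c(setdiff(got, channels), setdiff(channels, got))
    stop("data error: channel header mismatch in ", basename(path),
         " (offending channel(s): ", paste(unique(bad), collapse = ", "), ")")
  }
  t(as.matrix(m))
}

#' Read a time series written by [write_timeseries()]
#'
#' @param stem Path stem used at write time.
#' @param layout Optional [build_channel_grid()]; when given, the file's
#'   channel ids are checked against the layout and mismatches are
#'   reported by name.
#' @return A [hemo_ts()] or [optical_ts()] depending on the metadata.
#' @export
read_timeseries <- function(stem, layout = NULL) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  channels <- meta$channels
  if (!is.null(layout)) {
    unknown <- setdiff(channels, layout$id)
    if (length(unknown)) {
      stop("data error: channel(s) not in layout: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (identical(meta$kind, "hemoglobin")) {
    hemo_ts(read_matrix_file(paste0(stem, "_hbo.tsv"), channels),
            read_matrix_file(paste0(stem, "_hbr.tsv"), channels),
            meta$fs, channels)
  } else {
    optical_ts(list(read_matrix_file(paste0(stem, "_w1.tsv"), channels),
                    read_matrix_file(paste0(stem, "_w2.tsv"), channels)),
               meta$wavelengths, meta$fs, channels)
  }
}

#' Write analysis tables to delimited files
#'
#' Writes `dc_matrix` objects (square matrix and tidy source/sink/dc
#' table), connection tables, and mixed-model outputs (Type III table,
#' reduction history) with stable column order. Writing an identical
#' object twice produces identical bytes.
#'
#' @param objects Named list of objects.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_tables <- function(objects, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    path
  }
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (inherits(obj, "dc_matrix")) {
      paths <- c(paths,
                 wr(data.frame(sink = rownames(obj$dc), obj$dc,
                               check.names = FALSE),
                    file.path(outdir, paste0(nm, "_dc_matrix.tsv"))),
                 wr(as.data.frame(obj),
                    file.path(outdir, paste0(nm, "_dc_tidy.tsv"))))
    } else if (inherits(obj, "dc_lmm")) {
      paths <- c(paths,
                 wr(obj$anova, file.path(outdir, paste0(nm, "_anova.tsv"))),
                 wr(obj$history, file.path(outdir, paste0(nm, "_reduction.tsv"))),
                 wr(data.frame(term = names(coef(obj)), estimate = coef(obj)),
                    file.path(outdir, paste0(nm, "_coefficients.tsv"))))
    } else if (inherits(obj, "contrast_table")) {
      paths <- c(paths,
                 wr(obj$estimates, file.path(outdir, paste0(nm, "_estimates.tsv"))),
                 wr(obj$contrasts, file.path(outdir, paste0(nm, "_contrasts.tsv"))))
    } else if (is.data.frame(obj)) {
      paths <- c(paths, wr(as.data.frame(obj),
                           file.path(outdir, paste0(nm, ".tsv"))))
    } else {
      stop("data error: cannot serialize object '", nm, "'")
    }
  }
  invisible(paths)
}
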