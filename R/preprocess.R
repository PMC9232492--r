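#' Construct a raw strip-FRAP trace
#'
#' One cell's time-stamped in-strip and out-of-strip (background) intensity
#' readings, together with the index of the single bleach frame.
#'
#' @param cell_id Cell identifier.
#' @param times Frame times in seconds; strictly increasing with uniform
#'   spacing.
#' @param strip_intensity Non-negative in-strip fluorescence per frame
#'   (arbitrary units).
#' @param background_intensity Non-negative out-of-strip fluorescence per
#'   frame (arbitrary units).
#' @param bleach_frame 1-based index of the bleach frame; all earlier frames
#'   are pre-bleach.
#' @param condition Condition label, e.g. `"0 J"` or `"4 J 1-2 h"`.
#'
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(cell_id, times, strip_intensity, background_intensity,
                       bleach_frame, condition = "") {
  n <- length(times)
  if (n == 0) stop("empty trace", call. = FALSE)
  if (length(strip_intensity) != n || length(background_intensity) != n)
    stop("times, strip_intensity and background_intensity must have equal length",
         call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (n > 2 && diff(range(diff(times))) > 1e-6 * mean(diff(times)))
    stop("times must be uniformly spaced", call. = FALSE)
  if (any(strip_intensity < 0) || any(background_intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  bleach_frame <- as.integer(bleach_frame)
  if (bleach_frame < 2 || bleach_frame > n)
    stop("bleach_frame must point at a frame after at least one pre-bleach frame",
         call. = FALSE)
  structure(
    list(cell_id = cell_id, condition = condition, times = as.numeric(times),
         strip_intensity = as.numeric(strip_intensity),
         background_intensity = as.numeric(background_intensity),
         bleach_frame = bleach_frame),
    class = "frap_trace"
  )
}

#' Background-correct a raw trace
#'
#' Subtracts the out-of-strip background intensity from the in-strip
#' intensity frame by frame. Negative corrected values are clipped to 0 to
#' keep the signal physical; all other fields are unchanged.
#'
#' @param trace A [frap_trace()].
#' @return The corrected `frap_trace`, flagged so downstream normalization
#'   knows correction has been applied.
#' @export
background_correct <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  trace$strip_intensity <-
    pmax(trace$strip_intensity - trace$background_intensity, 0)
  attr(trace, "background_corrected") <- TRUE
  trace
}

#' Normalize a background-corrected trace to its pre-bleach intensity
#'
#' The mean corrected intensity over the pre-bleach reference window
#' (frames 10-20 of the pre-bleach block by default, 0-based inclusive) is
#' taken as the pre-bleach fluorescence intensity and set to 100; every
#' frame is scaled accordingly to give the relative fluorescence intensity
#' (RFI). Times are re-zeroed at the bleach frame so pre-bleach frames carry
#' negative times. The pre-bleach FI is retained as a proxy for total
#' protein level.
#'
#' @param trace A background-corrected [frap_trace()].
#' @param reference_frames 1-based frame indices of the reference window;
#'   defaults to `11:21` (pre-bleach frames 10-20 in the 0-based convention
#'   of the acquisition protocol). Must lie entirely before the bleach
#'   frame.
#'
#' @return An object of class `frap_curve`: list with `cell_id`,
#'   `condition`, `times` (s, bleach at 0), `rfi`, and `prebleach_fi`.
#' @export
normalize_prebleach <- function(trace, reference_frames = 11:21) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!isTRUE(attr(trace, "background_corrected")))
    warning("trace does not appear to be background-corrected; ",
            "call background_correct() first", call. = FALSE)
  reference_frames <- as.integer(reference_frames)
  if (any(reference_frames < 1) || any(reference_frames >= trace$bleach_frame))
    stop("reference window must lie entirely before the bleach frame",
         call. = FALSE)
  if (any(reference_frames > length(trace$times)))
    stop("reference window outside the trace", call. = FALSE)
  ref_mean <- mean(trace$strip_intensity[reference_frames])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("degenerate trace: pre-bleach reference mean is not positive",
         call. = FALSE)
  rfi <- 100 * trace$strip_intensity / ref_mean
  structure(
    list(cell_id = trace$cell_id, condition = trace$condition,
         times = trace$times - trace$times[trace$bleach_frame],
         rfi = rfi, prebleach_fi = ref_mean),
    class = "frap_curve"
  )
}

#' Average normalized curves within a condition
#'
#' Computes the pointwise mean and sample SD of the RFI across cells.
#' Curves must share one condition label and a common time grid; curves of
#' unequal length are truncated to the shortest with a warning.
#'
#' @param curves Non-empty list of [normalize_prebleach()] outputs.
#' @return An object of class `frap_mean_curve`: list with `condition`,
#'   `times`, `rfi_mean`, `rfi_sd` and `n_cells`.
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0) stop("empty curve list", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "frap_curve")))
  conds <- unique(vapply(curves, function(x) as.character(x$condition),
                         character(1)))
  if (length(conds) != 1)
    stop("curves span multiple conditions: ", paste(conds, collapse = ", "),
         call. = FALSE)
  lens <- vapply(curves, function(x) length(x$times), integer(1))
  n_keep <- min(lens)
  if (any(lens != n_keep)) {
    warning("curves of unequal length; truncating to the shortest (",
            n_keep, " frames)", call. = FALSE)
    curves <- lapply(curves, function(x) {
      x$times <- x$times[seq_len(n_keep)]
      x$rfi <- x$rfi[seq_len(n_keep)]
      x
    })
  }
  times <- curves[[1]]$times
  for (x in curves[-1]) {
    if (max(abs(x$times - times)) > 1e-6)
      stop("curves are not on a common time grid", call. = FALSE)
  }
  rfi <- do.call(rbind, lapply(curves, `[[`, "rfi"))
  rfi_sd <- if (nrow(rfi) > 1) apply(rfi, 2, sd) else rep(0, ncol(rfi))
  structure(
    list(condition = conds, times = times, rfi_mean = colMeans(rfi),
         rfi_sd = rfi_sd, n_cells = length(curves)),
    class = "frap_mean_curve"
  )
}

#' @export
print.frap_mean_curve <- function(x, ...) {
  cat(sprintf("Mean strip-FRAP curve '%s': %d cells, %d frames\n",
              x$condition, x$n_cells, length(x$times)))
  invisible(x)
}

#' Summarize pre-bleach fluorescence as a protein-level proxy
#'
#' The pre-bleach fluorescence intensity of a nucleus scales with total
#' protein abundance, so its mean over cells serves as a relative
#' protein-level readout. Curves are grouped by condition; if a reference
#' condition is given, each condition's mean is also reported relative to
#' the reference mean.
#'
#' @param curves Non-empty list of [normalize_prebleach()] outputs (one or
#'   several conditions).
#' @param reference Optional reference condition label for relative levels.
#' @return A data.frame with one row per condition: `condition`, `n_cells`,
#'   `mean_fi`, `sd_fi`, and `rel_mean` when a reference is given.
#' @export
prebleach_level_summary <- function(curves, reference = NULL) {
  if (length(curves) == 0) stop("empty curve list", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "frap_curve")))
  cond <- vapply(curves, function(x) as.character(x$condition), character(1))
  fi <- vapply(curves, `[[`, numeric(1), "prebleach_fi")
  out <- do.call(rbind, lapply(split(fi, cond), function(v) {
    data.frame(n_cells = length(v), mean_fi = mean(v),
               sd_fi = if (length(v) > 1) sd(v) else 0)
  }))
  out <- cbind(condition = rownames(out), out)
  rownames(out) <- NULL
  if (!is.null(reference)) {
    if (!reference %in% out$condition)
      stop("reference condition '", reference, "' not present", call. = FALSE)
    out$rel_mean <- out$mean_fi / out$mean_fi[out$condition == reference]
  }
  out
}

#' Read raw traces from a long-format delimited table
#'
#' Expects columns `cell_id`, `condition`, `frame`, `time_s`,
#' `strip_intensity`, `background_intensity`, and either a `bleach` column
#' (1 on the bleach frame, 0 elsewhere) or a single `bleach_frame` argument
#' (1-based, shared by all cells).
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension).
#' @param bleach_frame Optional 1-based bleach-frame index applied to every
#'   cell when the table carries no `bleach` column.
#' @return A list of [frap_trace()] objects, one per cell.
#' @export
read_frap_traces <- function(path, bleach_frame = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "frame", "time_s", "strip_intensity",
            "background_intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  lapply(split(tab, tab$cell_id), function(d) {
    d <- d[order(d$frame), ]
    bf <- if ("bleach" %in% names(tab)) {
      idx <- which(d$bleach > 0)
      if (length(idx) != 1)
        stop("cell ", d$cell_id[1], ": expected exactly one bleach frame",
             call. = FALSE)
      idx
    } else if (!is.null(bleach_frame)) {
      bleach_frame
    } else {
      stop("no 'bleach' column and no bleach_frame given", call. = FALSE)
    }
    frap_trace(cell_id = d$cell_id[1], times = d$time_s,
               strip_intensity = d$strip_intensity,
               background_intensity = d$background_intensity,
               bleach_frame = bf, condition = d$condition[1])
  })
}

#' Write traces, normalized curves or mean curves as CSV
#'
#' Floats are written with 9+ significant digits so that curves round-trip
#' through disk without losing precision.
#'
#' @param x A list of `frap_trace` or `frap_curve` objects, or a single
#'   `frap_mean_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(x, path) {
  df <- frap_as_df(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

frap_as_df <- function(x) {
  if (inherits(x, "frap_mean_curve")) {
    return(data.frame(condition = x$condition, time_s = x$times,
                      rfi_mean = x$rfi_mean, rfi_sd = x$rfi_sd,
                      n_cells = x$n_cells))
  }
  if (inherits(x, c("frap_trace", "frap_curve"))) x <- list(x)
  stopifnot(is.list(x), length(x) > 0)
  do.call(rbind, lapply(x, function(el) {
    if (inherits(el, "frap_trace")) {
      data.frame(cell_id = el$cell_id, condition = el$condition,
                 frame = seq_along(el$times) - 1L, time_s = el$times,
                 strip_intensity = el$strip_intensity,
                 background_intensity = el$background_intensity,
                 bleach = as.integer(seq_along(el$times) == el$bleach_frame))
    } else if (inherits(el, "frap_curve")) {
      data.frame(cell_id = el$cell_id, condition = el$condition,
                 time_s = el$times, rfi = el$rfi,
                 prebleach_fi = el$prebleach_fi)
    } else {
      stop("unsupported element of class ", paste(class(el), collapse = "/"),
           call. = FALSE)
    }
  }))
}

#' Read a condition-mean curve written by [write_frap_csv()]
#'
#' @param path CSV with columns `condition`, `time_s`, `rfi_mean`,
#'   `rfi_sd`, `n_cells`.
#' @return A `frap_mean_curve`.
#' @export
read_frap_mean_curve <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_s", "rfi_mean", "rfi_sd", "n_cells")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  structure(
    list(condition = d$condition[1], times = d$time_s,
         rfi_mean = d$rfi_mean, rfi_sd = d$rfi_sd,
         n_cells = as.integer(d$n_cells[1])),
    class = "frap_mean_curve"
  )
}

#' Preprocess a set of raw traces into normalized curves
#'
#' Convenience wrapper: background-corrects and pre-bleach-normalizes every
#' trace.
#'
#' @param traces List of [frap_trace()] objects.
#' @param reference_frames Passed to [normalize_prebleach()].
#' @return List of `frap_curve` objects.
#' @export
preprocess_traces <- function(traces, reference_frames = 11:21) {
  lapply(traces, function(tr)
    normalize_prebleach(background_correct(tr),
                        reference_frames = reference_frames))
}
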