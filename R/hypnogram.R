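# Hypnogram container: 30-s AASM stage labels with a lights-off/on window.

#' AASM sleep stage labels, in fixed matrix order
#' @return character vector `c("W","N1","N2","N3","R")`
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of 30-s epochs scored with AASM stages. The
#' lights window defaults to the whole recording (lights-off at epoch 1,
#' lights-on just past the last epoch), which is the synthetic-data
#' convention; real recordings may carry explicit markers.
#'
#' @param stages character vector of labels in `W, N1, N2, N3, R`
#' @param epoch_length epoch duration in seconds (fixed at 30)
#' @param lights_off first epoch of the analysis window (1-based)
#' @param lights_on first epoch after the analysis window
#' @return object of class `hypnogram`
#' @export
hypnogram <- function(stages, epoch_length = 30, lights_off = 1L,
                      lights_on = length(stages) + 1L) {
  stages <- as.character(stages)
  if (length(stages) == 0) stop("hypnogram must be non-empty")
  bad <- setdiff(unique(stages), sleep_stages())
  if (length(bad)) {
    stop("invalid stage label(s): ", paste(bad, collapse = ", "))
  }
  if (epoch_length != 30) stop("epoch_length is fixed at 30 s")
  if (!(lights_off >= 1 && lights_on > lights_off &&
        lights_on <= length(stages) + 1)) {
    stop("lights window must satisfy 1 <= lights_off < lights_on <= n+1")
  }
  structure(list(stages = stages, epoch_length = 30,
                 lights_off = as.integer(lights_off),
                 lights_on = as.integer(lights_on)),
            class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  cat("hypnogram:", length(x$stages), "x 30-s epochs (",
      round(length(x$stages) / 2, 1), "min ), lights window epochs",
      x$lights_off, "-", x$lights_on - 1, "\n")
  print(table(factor(x$stages, sleep_stages())))
  invisible(x)
}

#' Stage labels restricted to the lights-off/on window
#' @param h a [hypnogram()]
#' @return character vector of stage labels
#' @export
lights_window_stages <- function(h) {
  h$stages[seq.int(h$lights_off, h$lights_on - 1L)]
}

#' Read a hypnogram from a CSV annotation file
#'
#' Expected columns: `epoch_index`, `stage` (one row per 30-s epoch, in
#' order). Optional columns `lights_off`, `lights_on` (epoch indices,
#' constant) are honoured when present.
#'
#' @param path CSV file path
#' @return a [hypnogram()]
#' @export
read_hypnogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(d))) {
    stop("hypnogram CSV needs columns epoch_index, stage")
  }
  d <- d[order(d$epoch_index), ]
  lo <- if ("lights_off" %in% names(d)) d$lights_off[1] else 1L
  hi <- if ("lights_on" %in% names(d)) d$lights_on[1] else nrow(d) + 1L
  hypnogram(d$stage, lights_off = lo, lights_on = hi)
}

#' Write a hypnogram to CSV
#' @param h a [hypnogram()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hypnogram_csv <- function(h, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_along(h$stages), stage = h$stages,
               lights_off = h$lights_off, lights_on = h$lights_on),
    path, row.names = FALSE)
  invisible(path)
}
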