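#' Read and write recordings as delimited text or a columnar container
#'
#' The text format has one \code{time} column (seconds) followed by one
#' column per channel, tab-separated with a header; labeled segments travel
#' in a BED-like sidecar (see \code{\link{writeLabelTrack}}). With
#' \code{format = "feather"} the same table is written through the arrow
#' columnar container instead (requires the arrow package).
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @param path output file.
#' @param format "text" (default) or "feather".
#' @return \code{readRecording} returns an \linkS4class{EmgRecording}
#'   (without segments; attach them via the label-track sidecar).
#' @export
writeRecording <- function(rec, path, format = c("text", "feather")) {
  stopifnot(is(rec, "EmgRecording"))
  format <- match.arg(format)
  df <- data.frame(time = (seq_len(nSamples(rec)) - 1) / rec@samplingRate,
                   t(rec@samples))
  names(df) <- c("time", rec@channelLabels)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for format = 'feather'")
    arrow::write_feather(df, path)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname writeRecording
#' @param samplingRate sampling rate in Hz; NULL infers it from the time
#'   column.
#' @param subjectId subject identifier for the returned object.
#' @export
readRecording <- function(path, samplingRate = NULL, subjectId = "S1",
                          format = c("text", "feather")) {
  format <- match.arg(format)
  df <- if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for format = 'feather'")
    as.data.frame(arrow::read_feather(path))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE)
  }
  if (names(df)[1] != "time") stop("expected a leading 'time' column")
  fs <- samplingRate %||% round(1 / stats::median(diff(df$time)))
  new("EmgRecording", samples = t(as.matrix(df[, -1, drop = FALSE])),
      samplingRate = fs, channelLabels = names(df)[-1],
      subjectId = subjectId)
}

#' Read and write BED-like label tracks
#'
#' Three tab-separated columns without header: start s, end s, label;
#' half-open intervals.
#'
#' @param rec an \linkS4class{EmgRecording} with labeled segments.
#' @param path output file.
#' @export
writeLabelTrack <- function(rec, path) {
  stopifnot(is(rec, "EmgRecording"))
  seg <- rec@segments
  df <- data.frame(start = seg$start / rec@samplingRate,
                   end = seg$end / rec@samplingRate,
                   label = seg$label)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLabelTrack
#' @param samplingRate sampling rate used to convert seconds to samples.
#' @return \code{readLabelTrack} returns a segments data.frame with sample
#'   columns \code{start}, \code{end} and \code{label}.
#' @export
readLabelTrack <- function(path, samplingRate) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("start", "end", "label"))
  data.frame(start = round(df$start * samplingRate),
             end = round(df$end * samplingRate),
             label = as.character(df$label), stringsAsFactors = FALSE)
}

#' Read and write feature tables
#'
#' Comma-separated interchange format with header
#' \code{subject,window,label,<channel>_<feature>,...}: the table every
#' downstream stage consumes.
#'
#' @param set a \linkS4class{LabeledFeatureSet}.
#' @param path output file.
#' @param subject per-sample subject ids (recycled; default "S1").
#' @export
writeFeatureSet <- function(set, path, subject = "S1") {
  stopifnot(is(set, "LabeledFeatureSet"))
  df <- data.frame(subject = rep_len(subject, nrow(set@X)),
                   window = seq_len(nrow(set@X)),
                   label = as.character(set@y),
                   set@X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureSet
#' @return \code{readFeatureSet} returns a \linkS4class{LabeledFeatureSet}.
#' @export
readFeatureSet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject", "window", "label")
  if (!all(need %in% names(df)[1:3]))
    stop("expected leading columns subject, window, label")
  X <- as.matrix(df[, -(1:3), drop = FALSE])
  newFeatureSet(X, df$label)
}

#' Read and write feature masks
#'
#' Serialized as a single line of 0/1 characters, followed by a
#' channels x features grid rendering (comment lines) when the mask length
#' is a multiple of six.
#'
#' @param mask a \linkS4class{FeatureMask}.
#' @param path output file.
#' @param channelLabels optional channel names for the grid rendering.
#' @export
writeMask <- function(mask, path, channelLabels = NULL) {
  stopifnot(is(mask, "FeatureMask"))
  bits <- as.integer(mask@bits)
  lines <- paste(bits, collapse = "")
  nf <- length(featureNames())
  if (length(bits) %% nf == 0L) {
    nc <- length(bits) %/% nf
    labs <- channelLabels %||% sprintf("ch%02d", seq_len(nc))
    grid <- matrix(bits, nrow = nc, byrow = TRUE)
    lines <- c(lines,
               paste("#", format("channel", width = 22),
                     paste(format(featureNames(), width = 5),
                           collapse = " ")),
               vapply(seq_len(nc), function(i)
                 paste("#", format(labs[i], width = 22),
                       paste(format(grid[i, ], width = 5), collapse = " ")),
                 character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMask
#' @return \code{readMask} returns a \linkS4class{FeatureMask}.
#' @export
readMask <- function(path) {
  lines <- readLines(path)
  bitline <- lines[!startsWith(lines, "#")][1L]
  featureMask(as.integer(strsplit(bitline, "")[[1]]) == 1L)
}

#' Save and load a fitted SBL model as a text archive
#'
#' A self-contained, versioned plain-text serialization holding the tuned
#' (gam, sig2), the feature mask, the class table and every binary
#' machine's training references and dual solution.
#'
#' @param model an \linkS4class{SblModel}.
#' @param path output file.
#' @export
saveSblModel <- function(model, path) {
  stopifnot(is(model, "SblModel"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(format(x, digits = 17), collapse = ",")
  writeLines(c("emgSBL-model v1",
               paste0("gam=", num(model@gam)),
               paste0("sig2=", num(model@sig2)),
               paste0("mask=", paste(as.integer(model@mask@bits),
                                     collapse = "")),
               paste0("classes=", paste(model@ensemble@classes,
                                        collapse = ",")),
               paste0("center=", num(model@center)),
               paste0("scale=", num(model@scale)),
               paste0("history=", num(model@history)),
               paste0("nmachines=", length(model@ensemble@machines))),
             con)
  for (m in model@ensemble@machines) {
    writeLines(c(paste0("machine=", paste(m@classPair, collapse = ",")),
                 paste0("b=", num(m@b)),
                 paste0("alpha=", num(m@alpha)),
                 paste0("y=", num(m@y)),
                 paste0("n=", nrow(m@X)),
                 paste0("X=", num(as.numeric(m@X)))),
               con)
  }
  invisible(path)
}

#' @rdname saveSblModel
#' @return \code{loadSblModel} returns the reconstructed
#'   \linkS4class{SblModel}.
#' @export
loadSblModel <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "emgSBL-model v1") stop("unrecognized model archive header")
  val <- function(key, ln) sub(paste0("^", key, "="), "", ln)
  nums <- function(s) as.numeric(strsplit(s, ",")[[1]])
  gam <- nums(val("gam", lines[2]))
  sig2 <- nums(val("sig2", lines[3]))
  mask <- featureMask(as.integer(strsplit(val("mask", lines[4]),
                                          "")[[1]]) == 1L)
  classes <- strsplit(val("classes", lines[5]), ",")[[1]]
  center <- nums(val("center", lines[6]))
  scale <- nums(val("scale", lines[7]))
  history <- nums(val("history", lines[8]))
  nm <- as.integer(val("nmachines", lines[9]))
  machines <- vector("list", nm)
  pos <- 10L
  for (k in seq_len(nm)) {
    pair <- strsplit(val("machine", lines[pos]), ",")[[1]]
    b <- nums(val("b", lines[pos + 1L]))
    alpha <- nums(val("alpha", lines[pos + 2L]))
    yv <- nums(val("y", lines[pos + 3L]))
    n <- as.integer(val("n", lines[pos + 4L]))
    Xv <- nums(val("X", lines[pos + 5L]))
    machines[[k]] <- new("TrainedLssvm", alpha = alpha, b = b, gam = gam,
                         sig2 = sig2, X = matrix(Xv, nrow = n), y = yv,
                         classPair = pair, residual = 0)
    pos <- pos + 6L
  }
  ens <- new("MulticlassLssvm", machines = machines, classes = classes)
  new("SblModel", ensemble = ens, mask = mask, gam = gam, sig2 = sig2,
      center = center, scale = scale, history = history)
}
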