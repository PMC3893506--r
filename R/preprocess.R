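#' Build a raw probe-intensity table
#'
#' Holds per-probe foreground signal and local background intensity for each
#' sample, plus the feature (gene or miRNA) each probe maps to; duplicated
#' spots map several probes to one feature.
#'
#' @param probe_id Unique probe identifiers.
#' @param feature_id Feature each probe measures (may repeat).
#' @param signal,background Nonnegative numeric matrices, probes x samples,
#'   with identical column names.
#' @return A list of class \code{"raw_intensity_table"}.
#' @export
raw_intensity_table <- function(probe_id, feature_id, signal, background) {
  signal <- as.matrix(signal); background <- as.matrix(background)
  if (anyDuplicated(probe_id)) abort_input("probe_id must be unique")
  if (length(probe_id) != length(feature_id))
    abort_input("probe_id and feature_id lengths differ")
  if (!identical(dim(signal), dim(background)) ||
      nrow(signal) != length(probe_id))
    abort_input("signal and background must be probes x samples matrices")
  if (any(!is.finite(signal)) || any(!is.finite(background)))
    abort_input("intensities must be finite")
  if (any(signal < 0) || any(background < 0))
    abort_input("negative intensities are not allowed")
  rownames(signal) <- rownames(background) <- probe_id
  structure(list(probe_id = as.character(probe_id),
                 feature_id = as.character(feature_id),
                 signal = signal, background = background),
            class = "raw_intensity_table")
}

#' Read a raw intensity TSV
#'
#' Expects columns \code{probe_id}, \code{feature_id}, then one
#' \code{<sample>_signal} / \code{<sample>_background} pair per sample.
#'
#' @param path File path.
#' @return A \code{\link{raw_intensity_table}}.
#' @export
read_raw_intensity_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  sig_cols <- grep("_signal$", names(df), value = TRUE)
  bg_cols <- sub("_signal$", "_background", sig_cols)
  if (!all(bg_cols %in% names(df)))
    abort_input("every <sample>_signal column needs a matching _background column")
  samples <- sub("_signal$", "", sig_cols)
  sig <- as.matrix(df[sig_cols]); colnames(sig) <- samples
  bg <- as.matrix(df[bg_cols]); colnames(bg) <- samples
  raw_intensity_table(df$probe_id, df$feature_id, sig, bg)
}

#' Keep probes measured above local background
#'
#' A probe is well measured when its signal exceeds \code{fold} times its
#' local background in at least one sample (strictly greater). A zero
#' background keeps any positive signal.
#'
#' @param raw A \code{\link{raw_intensity_table}}.
#' @param fold Ratio threshold (default 1.4).
#' @return Character vector of retained probe ids.
#' @export
filter_well_measured <- function(raw, fold = 1.4) {
  stopifnot_scalar_number(fold, "fold", min = 0, strict_min = TRUE)
  keep <- rowSums(raw$signal > fold * raw$background) > 0L
  raw$probe_id[keep]
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every column to share one sorted value multiset (the per-rank
#' cross-column mean); tied values receive the mean of their tied ranks'
#' row means. Delegates to \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param values Numeric matrix (features x samples), finite.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    abort_input("cannot quantile-normalize an empty matrix")
  if (any(!is.finite(values))) abort_input("values must be finite")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Average duplicated spots into one row per feature
#'
#' @param values Numeric matrix with probe rownames.
#' @param probe_to_feature Named character vector mapping every probe in
#'   \code{values} to its feature.
#' @return Matrix with one row per feature (order of first appearance),
#'   each value the arithmetic mean over the feature's probes.
#' @export
average_duplicates <- function(values, probe_to_feature) {
  values <- as.matrix(values)
  probes <- rownames(values)
  if (is.null(probes)) abort_input("values must have probe rownames")
  if (!all(probes %in% names(probe_to_feature)))
    abort_input("probes without feature mapping: ",
                paste(setdiff(probes, names(probe_to_feature)), collapse = ", "))
  feat <- as.character(probe_to_feature[probes])
  lev <- unique(feat)
  sums <- rowsum(values, group = factor(feat, levels = lev))
  counts <- as.vector(table(factor(feat, levels = lev)))
  out <- sums / counts
  rownames(out) <- lev
  out
}

#' Compute log2 expression ratios against the control sample
#'
#' \code{value(f, t) = log2(intensity(f, t) / intensity(f, control))}; the
#' control column is dropped from the output. When any intensity is zero, a
#' small positive offset is first added everywhere so the log is defined.
#'
#' @param intensities Feature x sample matrix of nonnegative intensities.
#' @param control_label Column name of the control sample.
#' @param offset Offset added to all intensities when zeros are present
#'   (default 1 intensity unit).
#' @return An \code{\link{expression_matrix}} of log2 ratios.
#' @export
compute_ratios <- function(intensities, control_label, offset = 1) {
  intensities <- as.matrix(intensities)
  if (!control_label %in% colnames(intensities))
    abort_input("control column '", control_label, "' not found")
  if (any(intensities < 0)) abort_input("intensities must be nonnegative")
  if (any(intensities == 0)) intensities <- intensities + offset
  ctrl <- intensities[, control_label]
  if (any(ctrl <= 0))
    abort_input("nonpositive control intensity for: ",
                paste(rownames(intensities)[ctrl <= 0], collapse = ", "))
  rest <- setdiff(colnames(intensities), control_label)
  vals <- log2(intensities[, rest, drop = FALSE] / ctrl)
  expression_matrix(vals, feature_ids = rownames(intensities),
                    time_labels = rest)
}
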