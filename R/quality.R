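# Model-confidence gates and disorder summaries.

#' Domain-level model quality report
#'
#' Mean per-residue confidence over the segment (whole model if `NULL`) on
#' the 0--100 pLDDT scale, the good-model call (mean at or above the gate,
#' default 70) and per-residue pass flags (residue confidence at or above
#' the same gate).
#'
#' @param model a [protein_model()] (confidences already normalized to
#'   0--100 at parse time).
#' @param segment optional [domain_segment()]; all its positions must exist
#'   in the model.
#' @param conf_gate confidence gate on the 0--100 scale.
#' @param inclusive logical; `TRUE` (default) uses `>=`.
#' @return an object of class `quality_report`: list with `mean_confidence`,
#'   `good_model`, `residue_pass` (named logical vector) and the gate used.
#' @export
domain_quality <- function(model, segment = NULL, conf_gate = 70,
                           inclusive = TRUE) {
  res <- model$residues
  if (!is.null(segment)) {
    pos <- segment_positions(segment)
    if (length(pos) == 0L) stop("empty segment")
    miss <- setdiff(pos, res$number)
    if (length(miss))
      stop("segment positions absent from model: ",
           paste(head(miss, 5L), collapse = ", "))
    res <- res[res$number %in% pos, , drop = FALSE]
  }
  if (nrow(res) == 0L) stop("empty segment")
  cmp <- if (inclusive) `>=` else `>`
  m <- mean(res$confidence)
  structure(list(
    mean_confidence = m,
    good_model = cmp(m, conf_gate),
    residue_pass = setNames(cmp(res$confidence, conf_gate), res$number),
    conf_gate = conf_gate, inclusive = inclusive
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> mean confidence %.1f (gate %s%g): %s; %d/%d residues pass\n",
              x$mean_confidence, if (x$inclusive) ">=" else ">", x$conf_gate,
              if (x$good_model) "good model" else "low-quality model",
              sum(x$residue_pass), length(x$residue_pass)))
  invisible(x)
}

#' Disorder summary for a segment
#'
#' A residue is disordered iff its disorder probability is strictly greater
#' than `disorder_cut` (default 0.5); the segment is highly disordered iff
#' the disordered percentage is strictly greater than `high_cut` (default
#' 40 percent).
#'
#' @param disorder_prob numeric vector named by residue position.
#' @param segment a [domain_segment()].
#' @param disorder_cut per-residue probability cutoff.
#' @param high_cut percentage above which the segment is flagged.
#' @return list with `percent_disordered` and `high_disorder`.
#' @export
disorder_summary <- function(disorder_prob, segment, disorder_cut = 0.5,
                             high_cut = 40) {
  pos <- segment_positions(segment)
  p <- disorder_prob[as.character(pos)]
  if (any(is.na(p)))
    stop("missing disorder probabilities for positions: ",
         paste(head(pos[is.na(p)], 10L), collapse = ", "))
  pct <- 100 * mean(p > disorder_cut)
  list(percent_disordered = pct, high_disorder = pct > high_cut)
}

#' Correlation coefficient
#'
#' Pearson or Spearman correlation (ties handled by average ranks, as in
#' [stats::cor()]). Zero-variance input yields `NA` with a warning rather
#' than an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = method)
}
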