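#' Species richness versus rearrangement load across families
#'
#' Fits a locally weighted regression (LOESS: tricube weights, degree 1,
#' default span 0.75) of per-family species richness on total
#' rearrangement score, and flags families whose residual z-score exceeds
#' 2 in absolute value. The sign convention follows the rearrangement
#' axis: \code{+1} marks RS above the trend for the observed richness
#' (richness below the fitted curve), \code{-1} marks richness above the
#' trend. Exactly collinear input reproduces the line and flags nothing.
#'
#' @param records data.frame with columns \code{family}, \code{richness}
#'   (species count, >= 1), \code{total_rs} (>= 0); at least 5 rows.
#' @param span LOESS span.
#' @param z_threshold absolute residual z-score above which a family is
#'   flagged.
#' @return data.frame: \code{family}, \code{richness}, \code{total_rs},
#'   \code{fitted}, \code{residual}, \code{z}, \code{outlier} (-1, 0,
#'   +1), \code{direction} (\code{""}, \code{"high_rs"},
#'   \code{"high_richness"}), ordered as the input.
#' @export
richness_vs_rs <- function(records, span = 0.75, z_threshold = 2) {
  if (nrow(records) < 5) stop("at least 5 family records required")
  fit <- stats::loess(richness ~ total_rs, data = records, span = span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  fitted <- stats::predict(fit, records$total_rs)
  residual <- records$richness - fitted
  s <- stats::sd(residual)
  z <- if (is.na(s) || s < .Machine$double.eps^0.5) {
    rep(0, length(residual))
  } else residual / s
  outlier <- integer(length(z))
  outlier[z < -z_threshold] <- 1L    # RS above trend (richness deficit)
  outlier[z > z_threshold] <- -1L    # richness above trend
  data.frame(family = records$family, richness = records$richness,
             total_rs = records$total_rs, fitted = fitted,
             residual = residual, z = z, outlier = outlier,
             direction = c("high_richness", "", "high_rs")[outlier + 2L],
             stringsAsFactors = FALSE)
}

#' Per-taxon summaries of the RS distribution
#'
#' Order statistics of the rearrangement scores of gene-order types
#' against a reference, grouped by taxon, with a count of extreme values
#' above a threshold and a crude modality hint (number of modes of a
#' kernel density estimate; reported as 1 for degenerate spreads).
#'
#' @param types list of \code{rearrangement_type} carrying taxa.
#' @param reference_id reference type id.
#' @param scheme,weights,breakpoints see [accumulate_rf()].
#' @param rank taxon rank column to group by (default \code{"family"}).
#' @param threshold extreme-value threshold (default 20).
#' @return list: \code{per_type} (type_id, taxon, rs), \code{summary}
#'   (taxon, n_types, min, median, mean, max, n_above, modality),
#'   \code{extremes} (type ids above threshold).
#' @export
rs_distribution_summary <- function(types, reference_id,
                                    scheme = c("qmgr", "qgo"),
                                    weights = event_weights(),
                                    breakpoints = default_breakpoints(),
                                    rank = "family", threshold = 20) {
  scheme <- match.arg(scheme)
  if (length(types) == 0) stop("no types supplied")
  ids <- vapply(types, function(t) t$type_id, integer(1))
  ref <- types[[match(reference_id, ids)]]$order
  rs <- vapply(types, function(t) {
    switch(scheme,
           qmgr = qmgr_rs(t$order, ref),
           qgo = qgo_rs(t$order, ref, weights = weights,
                        breakpoints = breakpoints))
  }, numeric(1))
  taxon_of <- vapply(types, function(t) {
    if (is.null(t$taxa) || !rank %in% names(t$taxa) ||
        nrow(t$taxa) == 0) return(NA_character_)
    paste(sort(unique(t$taxa[[rank]])), collapse = "|")
  }, character(1))
  per_type <- data.frame(type_id = ids, taxon = taxon_of, rs = rs,
                         stringsAsFactors = FALSE)
  expanded <- do.call(rbind, lapply(seq_along(types), function(i) {
    tx <- if (is.na(taxon_of[i])) NA_character_ else
      strsplit(taxon_of[i], "|", fixed = TRUE)[[1]]
    data.frame(type_id = ids[i], taxon = tx, rs = rs[i],
               stringsAsFactors = FALSE)
  }))
  groups <- c("all", sort(unique(stats::na.omit(expanded$taxon))))
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- if (g == "all") rs else expanded$rs[expanded$taxon %in% g]
    modality <- if (length(v) < 3 || stats::sd(v) == 0) 1L else {
      d <- stats::density(v)
      y <- d$y
      sum(diff(sign(diff(y))) == -2) # local maxima
    }
    data.frame(taxon = g, n_types = length(v), min = min(v),
               median = stats::median(v), mean = mean(v), max = max(v),
               n_above = sum(v > threshold), modality = as.integer(modality),
               stringsAsFactors = FALSE)
  }))
  list(per_type = per_type, summary = summ,
       extremes = ids[rs > threshold])
}
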