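#' Split an image into four clockwise quadrants
#'
#' Partitions the pixel grid into quadrants numbered clockwise from the top
#' left: 1 = top-left, 2 = top-right, 3 = bottom-right, 4 = bottom-left.
#' Odd dimensions use a floor split (top/left blocks take the smaller half),
#' so the four quadrants always form an exact partition of the image.
#'
#' @param x a `lifetime_image` or any matrix of at least 2 x 2.
#' @return Integer matrix of quadrant ids (1-4) with the input's dimensions.
#' @export
quadrant_map <- function(x) {
  d <- if (inherits(x, "lifetime_image")) dim(x$tau_m_map) else dim(x)
  if (is.null(d) || d[1] < 2 || d[2] < 2)
    stop("image must be at least 2 x 2 to split into quadrants")
  top <- seq_len(d[1]) <= d[1] %/% 2
  left <- seq_len(d[2]) <= d[2] %/% 2
  q <- matrix(3L, d[1], d[2])
  q[top, left] <- 1L
  q[top, !left] <- 2L
  q[!top, left] <- 4L
  q
}

#' Per-quadrant mean lifetimes of a fitted image
#'
#' Computes the mean tau_m over masked-in pixels of each clockwise quadrant
#' (see [quadrant_map()]), the per-region records feeding the group
#' comparison and normalization.
#'
#' @param image a `lifetime_image`.
#' @param sample_id,region labels attached to the output rows.
#' @return A data.frame with columns sample_id, region, quadrant,
#'   mean_tau_m_ps (4 rows, quadrants 1-4).
#' @export
measure_quadrants <- function(image, sample_id = "S1",
                              region = c("cancerous", "peritumoral")) {
  stopifnot(inherits(image, "lifetime_image"))
  region <- match.arg(region)
  q <- quadrant_map(image)
  means <- vapply(1:4, function(j) {
    sel <- q == j & image$mask
    if (!any(sel)) return(NA_real_)
    mean(image$tau_m_map[sel])
  }, numeric(1))
  data.frame(sample_id = sample_id, region = region, quadrant = 1:4,
             mean_tau_m_ps = means)
}

#' Mean lifetime over a region
#'
#' Arithmetic mean of tau_m over pixels that are inside both the fit mask
#' and an optional region mask.
#'
#' @param image a `lifetime_image`.
#' @param mask optional logical matrix selecting the region.
#' @return Mean lifetime in ps.
#' @export
region_mean_tau <- function(image, mask = NULL) {
  stopifnot(inherits(image, "lifetime_image"))
  sel <- image$mask
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("empty region: no masked-in pixels")
  mean(image$tau_m_map[sel])
}

#' Normalize lifetimes to each sample's peritumoral mean
#'
#' Per sample, every measurement is divided by the mean of that sample's
#' peritumoral measurements, so the peritumoral group mean becomes exactly 1
#' and the cancerous values become the cancerous/peritumoral lifetime
#' ratios. Normalized values are scale-invariant within a sample.
#'
#' @param measurements data.frame as returned by [measure_quadrants()]
#'   (columns sample_id, region, mean_tau_m_ps at least).
#' @return The input with an added `normalized` column.
#' @export
normalize_to_peritumoral <- function(measurements) {
  stopifnot(all(c("sample_id", "region", "mean_tau_m_ps") %in%
                  names(measurements)))
  out <- measurements
  out$normalized <- NA_real_
  for (s in unique(out$sample_id)) {
    rows <- out$sample_id == s
    peri <- rows & out$region == "peritumoral" & !is.na(out$mean_tau_m_ps)
    if (!any(peri))
      stop("no peritumoral measurements for sample ", s)
    out$normalized[rows] <- out$mean_tau_m_ps[rows] /
      mean(out$mean_tau_m_ps[peri])
  }
  out
}

#' Per-sample cancerous/peritumoral lifetime ratio
#'
#' @param measurements data.frame with sample_id, region, mean_tau_m_ps.
#' @return data.frame with one row per sample: sample_id, lifetime_ratio.
#' @export
lifetime_ratios <- function(measurements) {
  norm <- normalize_to_peritumoral(measurements)
  canc <- norm[norm$region == "cancerous" & !is.na(norm$normalized), ]
  agg <- stats::aggregate(normalized ~ sample_id, data = canc, FUN = mean)
  names(agg)[2] <- "lifetime_ratio"
  agg
}

#' Two-sided Student t-test (pooled variance)
#'
#' Classical equal-variance two-sample t-test, the comparison applied to the
#' 12 cancerous vs 12 peritumoral quadrant means. Degenerate input with zero
#' pooled variance and equal means is reported as t = 0, p = 1.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Sample correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need two equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Clinical characteristics table of the four HCC patients
#'
#' Per-patient China Liver Cancer (CNLC) stage, cancerous/peritumoral
#' lifetime ratio, and preoperative laboratory indicators (prothrombin time,
#' bilirubin fractions, transaminases, plasma proteins, AFP), stored exactly
#' as printed.
#'
#' @return A data.frame, one row per patient.
#' @export
hcc_clinical_table <- function() {
  path <- system.file("extdata", "table1_clinical.csv",
                      package = "flimpipe", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Correlate lifetime ratios against clinical indicators
#'
#' Pearson r of the lifetime_ratio column against every numeric indicator
#' column, in table order. With n = 4 patients no meaningful p-value exists,
#' so only r (rounded to 2 decimals in `r_2dp`) and n are reported. Columns
#' where the correlation is undefined (constant values) are reported as NA.
#'
#' @param table a clinical data.frame with a `lifetime_ratio` column (see
#'   [hcc_clinical_table()]); non-numeric columns are skipped.
#' @return data.frame with columns indicator, r, r_2dp, n.
#' @export
correlate_table <- function(table) {
  if (!"lifetime_ratio" %in% names(table))
    stop("table must contain a lifetime_ratio column")
  if (nrow(table) < 3) stop("need at least 3 patients")
  x <- table$lifetime_ratio
  cols <- setdiff(names(table), "lifetime_ratio")
  cols <- cols[vapply(table[cols], is.numeric, logical(1))]
  r <- vapply(cols, function(cl) {
    y <- table[[cl]]
    tryCatch(pearson_r(x, y), error = function(e) NA_real_)
  }, numeric(1))
  data.frame(indicator = cols, r = unname(r), r_2dp = round(unname(r), 2),
             n = length(x))
}

#' Box-plot summary statistics
#'
#' Median, quartiles (linear interpolation), interquartile range and mean of
#' a set of lifetime values, the quantities drawn in the group box plots.
#'
#' @param values numeric vector, n >= 1.
#' @return List with `median`, `q1`, `q3`, `iqr`, `mean`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) == 0 || all(is.na(values)))
    stop("need at least one value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7,
                              na.rm = TRUE))
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       mean = mean(values, na.rm = TRUE))
}
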