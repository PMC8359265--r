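#' Dice overlap coefficient between two segmentations
#'
#' `2|A intersect B| / (|A| + |B|)`, the standard spatial agreement score for
#' repeated manual tracings.
#'
#' @param mask_a,mask_b logical arrays of identical shape; at least one
#'   nonempty.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share a grid", call. = FALSE)
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0)
    stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(mask_a & mask_b) / (a + b)
}

#' Intraclass correlation coefficient for a subjects-by-raters matrix
#'
#' Single-rater ICC from the two-way ANOVA mean squares. The default,
#' ICC(2,1), treats raters as a random sample and scores absolute agreement,
#' so systematic offsets between raters count against it; ICC(3,1)
#' (consistency, raters fixed) is available behind the `type` flag.
#'
#' With zero between-subject variance the coefficient is not positive; a
#' warning is raised and the (<= 0) value returned rather than an error, as
#' conventional for degenerate reliability designs.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns, no
#'   missing cells, >= 2 of each.
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return The ICC estimate (a single number).
#' @export
icc <- function(ratings, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings must have no missing cells",
                                call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  grand <- mean(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  val <- if (type == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  if (is.nan(val)) val <- 0
  if (val <= 0)
    warning("no positive between-subject variance: ICC <= 0", call. = FALSE)
  val
}
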