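#' Classify the vessel pattern of a hemisphere
#'
#' The vessel pattern is the number of independent arteries supplying the
#' ROI — the count of strictly positive supply volume fractions — together
#' with the composition (which ACA branches and MCA groups contribute).
#' Because fractions derive from integer voxel counts, the non-zero test is
#' exact (> 0), with no epsilon.
#'
#' @param fractions A [supply_record()] / [supply_fractions()] object.
#' @return An object of class `vessel_pattern`: list with `count` (1..5)
#'   and `composition` (character vector of vessel names, canonical order).
#' @export
#' @examples
#' classify_pattern(supply_record(
#'   c(pericallosa = 0.4, precentral = 0.35, central = 0.25)))
classify_pattern <- function(fractions) {
  stopifnot(inherits(fractions, "supply_fractions"))
  present <- names(.CANONICAL_VESSELS)[fractions[names(.CANONICAL_VESSELS)] > 0]
  if (length(present) == 0L) stop("all supply fractions are zero")
  structure(list(count = length(present), composition = present),
            class = "vessel_pattern")
}

#' @export
print.vessel_pattern <- function(x, ...) {
  cat(sprintf("<vessel_pattern> %d vessels: %s\n", x$count,
              paste(x$composition, collapse = " + ")))
  invisible(x)
}

#' @export
format.vessel_pattern <- function(x, ...) paste(x$composition, collapse = "+")

#' Vessel dominance ratios
#'
#' Four ratios of supply volume fractions quantifying the relative
#' contribution of vessels of interest against their counterparts. Each
#' ratio is the fraction of interest divided by the sum of the fraction of
#' interest and its counterpart(s): 1 if the vessel of interest is the sole
#' supplier of that pool, 0.5 for equal contribution, 0 if it does not
#' contribute. A ratio whose denominator is zero is undefined (`NA`).
#'
#' * `aca_mca`: combined ACA supply over the total supply.
#' * `peri_callosomarginalis`: A. pericallosa over the combined ACA supply.
#' * `central_precentral`: central group over central + precentral groups.
#' * `postcentral_mca`: postcentral group over the combined MCA supply.
#'
#' @param fractions A [supply_record()] object.
#' @return Named numeric vector of the four ratios (`NA` where undefined),
#'   class `dominance_ratios`.
#' @export
#' @examples
#' dominance_ratios(supply_record(
#'   c(pericallosa = 0.4, precentral = 0.3, central = 0.3)))
dominance_ratios <- function(fractions) {
  stopifnot(inherits(fractions, "supply_fractions"))
  f <- fractions
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  aca <- sum(f[.ACA_VESSELS])
  mca <- sum(f[.MCA_VESSELS])
  out <- c(
    aca_mca = ratio(aca, aca + mca),
    peri_callosomarginalis = ratio(f[["pericallosa"]], aca),
    central_precentral = ratio(f[["central"]],
                               f[["central"]] + f[["precentral"]]),
    postcentral_mca = ratio(f[["postcentral"]], mca)
  )
  structure(out, class = "dominance_ratios")
}

#' @export
print.dominance_ratios <- function(x, ...) {
  cat("<dominance_ratios>\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Convert a dominance ratio to a categorical rating
#'
#' Continuous supply volume ratios are converted into qualitative ratings
#' with a lower/upper threshold pair: ratios within `[lower, upper]` are
#' rated equal contribution, above `upper` the numerator vessel dominates,
#' below `lower` the denominator vessel dominates. Boundary values count as
#' equal contribution (closed interval), which keeps the equidistant
#' default (0.33, 0.66) symmetric. Undefined ratios (`NA`) are rated
#' `"undefined"`.
#'
#' @param ratio Numeric vector of ratios in `[0, 1]` (`NA` allowed).
#' @param lower,upper Threshold pair with `0 < lower < upper < 1`. The
#'   defaults are the equidistant thresholds 0.33 and 0.66.
#' @return Factor with levels `numerator-dominant`, `equal`,
#'   `denominator-dominant`, `undefined`.
#' @export
#' @examples
#' rate_dominance(c(0.5, 1, 0, NA))
rate_dominance <- function(ratio, lower = 0.33, upper = 0.66) {
  check_threshold_pair(lower, upper)
  ratio <- as.numeric(ratio)
  if (any(!is.na(ratio) & (ratio < 0 | ratio > 1)))
    stop("dominance ratios must lie in [0, 1]")
  out <- ifelse(is.na(ratio), "undefined",
         ifelse(ratio > upper, "numerator-dominant",
         ifelse(ratio < lower, "denominator-dominant", "equal")))
  factor(out, levels = .DOMINANCE_LEVELS)
}

.DOMINANCE_LEVELS <- c("numerator-dominant", "equal", "denominator-dominant",
                       "undefined")

check_threshold_pair <- function(lower, upper) {
  if (!(is.numeric(lower) && is.numeric(upper) &&
        lower > 0 && lower < upper && upper < 1))
    stop("thresholds must satisfy 0 < lower < upper < 1")
  invisible(TRUE)
}

#' Threshold sweep grid
#'
#' Builds the systematic, joint threshold variation used to test the
#' robustness of dominance ratings: `n` lower thresholds equally spaced on
#' `[low, high]` (endpoints included), each paired with the complementary
#' upper threshold `1 - lower`. The defaults give 100 pairs from
#' (0.05, 0.95) to (0.45, 0.55).
#'
#' @param n Number of pairs (>= 2).
#' @param low,high Range of lower thresholds, `0 < low < high < 0.5`.
#' @return Data frame with columns `lower` and `upper`.
#' @export
build_sweep_grid <- function(n = 100, low = 0.05, high = 0.45) {
  if (n < 2) stop("n must be >= 2")
  if (!(low > 0 && low < high && high < 0.5))
    stop("bounds must satisfy 0 < low < high < 0.5")
  lower <- seq(low, high, length.out = n)
  data.frame(lower = lower, upper = 1 - lower)
}

#' Threshold sweep with agreement scoring
#'
#' Rates a set of dominance ratios under every threshold pair of a sweep
#' grid, tabulates the relative frequency of each rating category, and
#' scores each pair's agreement with a reference frequency table (e.g. a
#' post-mortem benchmark) as `1 - L1/2`, where L1 is the total variation
#' distance between the two frequency vectors. Undefined ratios are
#' excluded from the frequencies (their count is reported separately).
#'
#' @param ratios Numeric vector of dominance ratios (`NA` = undefined).
#' @param grid Data frame from [build_sweep_grid()].
#' @param reference Named numeric vector of reference relative frequencies
#'   over the categories `numerator-dominant`, `equal`,
#'   `denominator-dominant`; must sum to 1 (tolerance 1e-9). Missing
#'   categories count as frequency 0.
#' @return An object of class `sweep_result`: list with `grid`,
#'   `frequencies` (n_pairs x 3 matrix), `counts` (n_pairs x 3),
#'   `n_undefined`, `agreement` (numeric), `best` (row of `grid` with the
#'   highest agreement; ties resolved towards the smallest lower
#'   threshold).
#' @export
sweep_agreement <- function(ratios, grid, reference) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L) stop("no ratios supplied")
  stopifnot(is.data.frame(grid), all(c("lower", "upper") %in% names(grid)))
  cats <- .DOMINANCE_LEVELS[1:3]
  ref <- setNames(numeric(3), cats)
  unknown <- setdiff(names(reference), cats)
  if (length(unknown))
    stop("unknown reference category: ", paste(unknown, collapse = ", "))
  ref[names(reference)] <- as.numeric(reference)
  if (abs(sum(ref) - 1) > 1e-9) stop("reference frequencies must sum to 1")
  defined <- ratios[!is.na(ratios)]
  n_def <- length(defined)
  if (n_def == 0L) stop("all ratios are undefined")
  counts <- matrix(0L, nrow = nrow(grid), ncol = 3,
                   dimnames = list(NULL, cats))
  for (i in seq_len(nrow(grid))) {
    r <- rate_dominance(defined, grid$lower[i], grid$upper[i])
    counts[i, ] <- tabulate(r, nbins = 4L)[1:3]
  }
  freqs <- counts / n_def
  agreement <- 1 - 0.5 * rowSums(abs(sweep(freqs, 2L, ref, "-")))
  best_i <- order(-agreement, grid$lower)[1]
  structure(list(grid = grid, counts = counts, frequencies = freqs,
                 n_undefined = sum(is.na(ratios)), n_rated = n_def,
                 reference = ref, agreement = agreement,
                 best = grid[best_i, , drop = FALSE]),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d threshold pairs, %d rated hemispheres",
              nrow(x$grid), x$n_rated))
  if (x$n_undefined > 0) cat(sprintf(" (%d undefined)", x$n_undefined))
  cat(sprintf("\nbest pair: lower %.4f upper %.4f (agreement %.4f)\n",
              x$best$lower, x$best$upper, max(x$agreement)))
  invisible(x)
}

#' Frequency table of patterns or dominance ratings
#'
#' Counts and relative frequencies (percent, one decimal as conventionally
#' reported) of vessel patterns or dominance rating categories. Undefined
#' dominance ratings form their own row; percentages are over all supplied
#' items, so the table sums to 100%.
#'
#' @param items A list of `vessel_pattern` objects, or a factor/character
#'   vector of dominance ratings.
#' @param by For patterns: `"count"` (default) tabulates by number of
#'   vessels; `"composition"` stratifies by the exact vessel set.
#' @return Data frame with columns `category`, `count`, `percent`.
#' @export
frequency_table <- function(items, by = c("count", "composition")) {
  by <- match.arg(by)
  if (length(items) == 0L) stop("no items supplied")
  if (is.list(items) && inherits(items[[1]], "vessel_pattern")) {
    keys <- vapply(items, function(p) {
      if (by == "count") as.character(p$count) else format(p)
    }, character(1))
    tab <- table(keys)
  } else {
    tab <- table(factor(as.character(items),
                        levels = intersect(.DOMINANCE_LEVELS,
                                           unique(as.character(items)))))
  }
  data.frame(category = names(tab),
             count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(items), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inter-rater correlation of supply fractions
#'
#' Pearson correlation (with two-sided p-value) between supply volume
#' fractions obtained from two independent raters' vessel delineations.
#'
#' @param fractions_a,fractions_b Paired numeric vectors (length >= 3).
#' @return List with `r`, `p.value`, `n`.
#' @export
interrater_correlation <- function(fractions_a, fractions_b) {
  fractions_a <- as.numeric(fractions_a)
  fractions_b <- as.numeric(fractions_b)
  if (length(fractions_a) != length(fractions_b))
    stop("fraction vectors must have equal length")
  if (length(fractions_a) < 3) stop("need at least 3 paired values")
  if (var(fractions_a) == 0 || var(fractions_b) == 0)
    stop("zero variance in supply fractions")
  ct <- cor.test(fractions_a, fractions_b, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n = length(fractions_a))
}
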