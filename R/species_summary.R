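# Species-level aggregation of basic wood-densities: per-species medians
# (within-species distributions can be highly asymmetrical, so the median
# is the species-level statistic), light/medium/heavy classification at
# 0.4 and 0.75 g/cm3, ranked extremes, histogram, and an among/within-
# species variance partition.

#' Classify basic wood-density as light, medium or heavy
#'
#' Standard three-way wood classification: densities up to 0.4 g/cm3 are
#' low ("light wood"), between 0.4 and 0.75 g/cm3 medium, and from
#' 0.75 g/cm3 upward high ("heavy wood"). The verbal bounds are ambiguous
#' exactly at the thresholds; the convention here is half-open intervals
#' \[0, 0.40), \[0.40, 0.75), \[0.75, Inf), configurable via `thresholds`.
#'
#' @param Db Basic density in g/cm3 (> 0). Vectorised.
#' @param thresholds Two increasing cut points; default `c(0.40, 0.75)`.
#' @return A factor with levels `low`, `medium`, `high`.
#' @examples
#' classify_density(c(0.197, 0.530, 0.866))
#' @export
classify_density <- function(Db, thresholds = c(0.40, 0.75)) {
  if (any(!is.finite(Db)) || any(Db <= 0)) {
    stop("`Db` must be finite and positive", call. = FALSE)
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  cut(Db, breaks = c(0, thresholds, Inf), labels = c("low", "medium", "high"),
      right = FALSE)
}

#' Per-species median basic densities
#'
#' Aggregates sample-level basic densities to one summary per species:
#' sample count, median density (even counts interpolate the two central
#' order statistics) and density class of the median.
#'
#' @param records A data frame with columns `species` and `basic_density`.
#' @param thresholds Classification cut points, passed to
#'   [classify_density()].
#' @return A tibble `(species, n_samples, median_density, density_class)`,
#'   one row per species, sorted by species name.
#' @export
species_medians <- function(records, thresholds = c(0.40, 0.75)) {
  stopifnot(is.data.frame(records),
            all(c("species", "basic_density") %in% names(records)))
  d <- dplyr::filter(records, !is.na(.data$species),
                     !is.na(.data$basic_density))
  if (nrow(d) == 0) stop("no usable records", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$species),
    n_samples = dplyr::n(),
    median_density = stats::median(.data$basic_density),
    .groups = "drop")
  out$density_class <- classify_density(out$median_density, thresholds)
  dplyr::arrange(out, .data$species)
}

#' Species counts per density class
#'
#' @param summaries A tibble from [species_medians()] (or any data frame
#'   with a `median_density` column).
#' @param thresholds Classification cut points.
#' @return A named integer vector `c(n_low, n_medium, n_high)`; the three
#'   counts always sum to the number of species.
#' @export
class_counts <- function(summaries, thresholds = c(0.40, 0.75)) {
  if (nrow(summaries) == 0) {
    return(c(n_low = 0L, n_medium = 0L, n_high = 0L))
  }
  cls <- classify_density(summaries$median_density, thresholds)
  tab <- table(cls)
  c(n_low = as.integer(tab[["low"]]),
    n_medium = as.integer(tab[["medium"]]),
    n_high = as.integer(tab[["high"]]))
}

#' Species with the lightest or heaviest wood
#'
#' Ranks species by median basic density among those with at least
#' `min_n` samples and returns the top `k`. Ties are broken
#' alphabetically by species name.
#'
#' @param summaries A tibble from [species_medians()].
#' @param min_n Minimum sample count to qualify; default 3.
#' @param k How many species to return; default 3. If fewer qualify, the
#'   list is shorter.
#' @param direction `"lightest"` (ascending) or `"heaviest"` (descending).
#' @return A tibble of up to `k` rows in rank order.
#' @export
extreme_species <- function(summaries, min_n = 3, k = 3,
                            direction = c("lightest", "heaviest")) {
  direction <- match.arg(direction)
  stopifnot(min_n >= 1, k >= 1)
  d <- dplyr::filter(summaries, .data$n_samples >= min_n)
  d <- if (direction == "lightest") {
    dplyr::arrange(d, .data$median_density, .data$species)
  } else {
    dplyr::arrange(d, dplyr::desc(.data$median_density), .data$species)
  }
  utils::head(d, k)
}

#' Histogram of species median densities
#'
#' Bins species medians into half-open bins `[k*w, (k+1)*w)` and labels
#' each bin with the density class of its midpoint. With a bin width that
#' divides the class thresholds (e.g. 0.05), per-class bin totals equal
#' [class_counts()].
#'
#' @param summaries A tibble from [species_medians()].
#' @param bin_width Bin width in g/cm3; default 0.05.
#' @param thresholds Classification cut points.
#' @return A tibble `(bin_start, bin_end, count, class)` covering the
#'   occupied range; counts sum to the number of species.
#' @export
density_histogram <- function(summaries, bin_width = 0.05,
                              thresholds = c(0.40, 0.75)) {
  stopifnot(bin_width > 0)
  x <- summaries$median_density
  if (length(x) == 0) {
    return(tibble::tibble(bin_start = numeric(), bin_end = numeric(),
                          count = integer(), class = factor(character(),
                          levels = c("low", "medium", "high"))))
  }
  idx <- floor(x / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(i) sum(idx == i), integer(1))
  start <- rng * bin_width
  tibble::tibble(bin_start = start,
                 bin_end = start + bin_width,
                 count = counts,
                 class = classify_density(start + bin_width / 2, thresholds))
}

#' Among/within-species variance partition of basic density
#'
#' One-way random-effects variance components by the method of moments
#' with the unbalanced-design correction: species with at least `min_n`
#' samples contribute; from the among- and within-species mean squares,
#' `sigma2_within = MSW` and
#' `sigma2_among = max(0, (MSA - MSW) / n0)` with
#' `n0 = (N - sum(ni^2)/N) / (k - 1)`. Percentages are shares of
#' `sigma2_among + sigma2_within` and sum to 100 exactly.
#'
#' @param records A data frame with columns `species` and `basic_density`.
#' @param min_n Minimum samples per species to enter the partition;
#'   default 2 (a single sample carries no within-species information).
#' @return A list: `pct_among_species`, `pct_within_species`,
#'   `var_among`, `var_within`, `n_species_used`, `n_samples_used`.
#' @examples
#' d <- tibble::tibble(species = rep(c("a", "b"), each = 2),
#'                     basic_density = c(0.4, 0.4, 0.8, 0.8))
#' variance_partition(d)  # 100% among, 0% within
#' @export
variance_partition <- function(records, min_n = 2) {
  stopifnot(is.data.frame(records),
            all(c("species", "basic_density") %in% names(records)))
  d <- dplyr::filter(records, !is.na(.data$species),
                     !is.na(.data$basic_density))
  counts <- table(d$species)
  keep <- names(counts)[counts >= min_n]
  if (length(keep) < 2) {
    stop("variance partition needs at least 2 species with >= ", min_n,
         " samples each; found ", length(keep), call. = FALSE)
  }
  d <- d[d$species %in% keep, ]
  x <- d$basic_density
  g <- factor(d$species)
  ni <- as.numeric(table(g))
  N <- length(x)
  k <- nlevels(g)
  means <- tapply(x, g, mean)
  grand <- mean(x)
  ssw <- sum((x - means[g])^2)
  ssa <- sum(ni * (means - grand)^2)
  msw <- ssw / (N - k)
  msa <- ssa / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_within <- msw
  var_among <- max(0, (msa - msw) / n0)
  total <- var_among + var_within
  if (total == 0) {
    stop("no variance in `basic_density` among the selected records",
         call. = FALSE)
  }
  list(pct_among_species = 100 * var_among / total,
       pct_within_species = 100 * var_within / total,
       var_among = var_among,
       var_within = var_within,
       n_species_used = k,
       n_samples_used = N)
}
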