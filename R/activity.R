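#' Four-parameter logistic model
#'
#' `s(x) = lower + (upper - lower) / (1 + exp(slope * (log(x) - log(midpoint))))`.
#' At dose 0 the curve takes its zero-dose asymptote (`upper` for positive
#' slope, `lower` for negative slope).
#'
#' @param x dose (same units as `midpoint`, typically ug/ml).
#' @param lower,upper asymptotes; `upper` is the survival of the untreated
#'   control (1 after normalisation).
#' @param slope Hill slope (> 0 for a decreasing survival curve).
#' @param midpoint dose at the curve's inflection.
#' @return predicted survival.
#' @export
fourpl <- function(x, lower, upper, slope, midpoint) {
  eta <- slope * (log(x) - log(midpoint))
  lower + (upper - lower) / (1 + exp(eta))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Deterministic least-squares fit: Levenberg-Marquardt runs from a fixed
#' multi-start grid (slope in +/-{0.5, 1, 2}, log-midpoint at the quartiles of
#' the positive doses, asymptotes from the response range); the fit with the
#' smallest SSE wins, ties going to the smallest midpoint. Fits whose SSE ties
#' within `1e-10` but whose midpoints disagree are flagged `unstable`
#' (degenerate, e.g. non-monotone or constant data), with parameters still
#' returned.
#'
#' @param doses dose vector (ug/ml), 0-dose control included.
#' @param survival survival fractions normalised to the 0-dose control.
#' @return object of class `fit_4pl`: `lower`, `upper`, `slope`, `midpoint`,
#'   `sse`, `unstable`, plus the data.
#' @export
fit_4pl <- function(doses, survival) {
  stopifnot(length(doses) == length(survival))
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses (including the 0 control)")
  pos <- sort(unique(doses[doses > 0]))
  lmid_grid <- log(unname(quantile(pos, c(0.25, 0.5, 0.75), type = 1)))
  slope_grid <- c(0.5, 1, 2, -0.5, -1, -2)
  y <- survival; x <- doses
  rng <- range(y)
  lower0 <- rng[1]; upper0 <- rng[2]
  if (upper0 - lower0 < 1e-12) { lower0 <- rng[1] - 0.5; upper0 <- rng[2] + 0.5 }
  fits <- list()
  resid_fn <- function(p) y - fourpl(x, p[1], p[2], p[3], exp(p[4]))
  for (sl in slope_grid) for (lm in lmid_grid) {
    f <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(lower0, upper0, sl, lm), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15))),
      error = function(e) NULL)
    if (is.null(f)) next
    p <- f$par
    fits[[length(fits) + 1L]] <-
      list(lower = p[1], upper = p[2], slope = p[3], midpoint = exp(p[4]),
           sse = sum(resid_fn(p)^2))
  }
  if (length(fits) == 0L)
    return(structure(list(lower = min(y), upper = max(y), slope = NA_real_,
                          midpoint = NA_real_, sse = sum((y - mean(y))^2),
                          unstable = TRUE, doses = doses, survival = survival),
                     class = "fit_4pl"))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  mids <- vapply(fits, `[[`, numeric(1), "midpoint")
  best_sse <- min(sses)
  near <- which(sses <= best_sse + 1e-10)
  pick <- near[which.min(mids[near])]
  unstable <- length(unique(round(log(mids[near]), 6))) > 1L
  out <- fits[[pick]]
  # canonical orientation: a negative slope with swapped asymptotes is the
  # same curve; report slope > 0 when the curve decreases with dose
  if (!is.na(out$slope) && out$slope < 0 && out$lower > out$upper) {
    tmp <- out$lower; out$lower <- out$upper; out$upper <- tmp
    out$slope <- -out$slope
  }
  structure(c(out, list(unstable = unstable, doses = doses,
                        survival = survival)), class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL fit: lower=%.4g upper=%.4g slope=%.4g midpoint=%.4g (SSE %.3g)%s\n",
    x$lower, x$upper, x$slope, x$midpoint, x$sse,
    if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}

#' IC50 from a 4PL fit
#'
#' The smallest dose at which predicted survival equals 0.5 in absolute terms
#' (half of the normalised 0-dose control), solved analytically:
#' `ic50 = midpoint * ((upper - 0.5) / (0.5 - lower))^(1/slope)`. If the curve
#' never crosses 0.5 between 0 and `max_dose_factor` times the largest assay
#' dose, the IC50 is undefined (`NA` with attribute `flag`).
#'
#' @param fit a [fit_4pl()] object.
#' @param max_dose_factor search limit as a multiple of the largest dose.
#' @return IC50 in dose units, or `NA` with a `flag` attribute
#'   (`"no_50pct_crossing"` or `"unstable_fit"`).
#' @export
ic50 <- function(fit, max_dose_factor = 10) {
  if (is.na(fit$slope) || is.na(fit$midpoint))
    return(structure(NA_real_, flag = "unstable_fit"))
  lo <- fit$lower; up <- fit$upper
  if (!(lo < 0.5 && 0.5 < up))
    return(structure(NA_real_, flag = "no_50pct_crossing"))
  x50 <- fit$midpoint * ((up - 0.5) / (0.5 - lo))^(1 / fit$slope)
  lim <- max_dose_factor * max(fit$doses)
  if (!is.finite(x50) || x50 <= 0 || x50 > lim)
    return(structure(NA_real_, flag = "no_50pct_crossing"))
  x50
}

#' Specific antibacterial activity from IC50
#'
#' 1 U is the dose that kills 50% of the bacteria in the 1-ml assay, i.e.
#' `ic50` ug of peptide; 1 mg of peptide therefore contains
#' `1000 / ic50` units. An undefined IC50 reports 0 U/mg with a flag.
#'
#' @param ic50_ug_per_ml IC50 in ug/ml.
#' @return specific activity in U/mg (with attribute `flag = "undefined_ic50"`
#'   when the input is `NA` or non-positive).
#' @export
specific_activity <- function(ic50_ug_per_ml) {
  out <- ifelse(is.na(ic50_ug_per_ml) | ic50_ug_per_ml <= 0,
                0, 1000 / ic50_ug_per_ml)
  if (any(out == 0)) attr(out, "flag") <- "undefined_ic50"
  out
}

#' Activity table with row and column means
#'
#' Aggregates a peptide-by-bacterium matrix of specific activities, adding
#' arithmetic row and column means rounded half-up to integers (printed-table
#' convention). Missing cells produce a warning and means over the available
#' values.
#'
#' @param values numeric matrix or data frame (rows peptides, columns
#'   bacteria), with rownames/colnames.
#' @return list of class `activity_table` with `values`, `row_means`,
#'   `col_means`, `grand_mean`.
#' @export
aggregate_table <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) warning("missing cells; means over available values")
  row_means <- round_half_up(rowMeans(m, na.rm = TRUE))
  col_means <- round_half_up(colMeans(m, na.rm = TRUE))
  structure(list(values = m, row_means = row_means, col_means = col_means,
                 grand_mean = round_half_up(mean(m, na.rm = TRUE))),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  out <- cbind(x$values, Mean = x$row_means)
  out <- rbind(out, Mean = c(x$col_means, x$grand_mean))
  print(out)
  invisible(x)
}

#' Survival fractions from colony counts
#'
#' Converts raw colony counts to survival fractions relative to the 0-dose
#' control of the same peptide/bacterium/replicate series. Counts are taken at
#' the highest plated concentration that still shows distinguishable colonies;
#' the `dilution` column (1 for undiluted, 10 for 1:10) rescales counts to a
#' common scale before normalisation.
#'
#' @param counts data frame with columns `peptide_id`, `bacterium`,
#'   `replicate`, `dose_ug_per_ml`, `dilution`, `colonies`.
#' @return the input with `eff_count` and `survival` columns added.
#' @export
survival_from_counts <- function(counts) {
  need <- c("peptide_id", "bacterium", "replicate", "dose_ug_per_ml",
            "dilution", "colonies")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  counts$eff_count <- counts$colonies * counts$dilution
  key <- interaction(counts$peptide_id, counts$bacterium, counts$replicate,
                     drop = TRUE)
  counts$survival <- NA_real_
  for (g in levels(key)) {
    i <- key == g
    ctrl <- counts$eff_count[i & counts$dose_ug_per_ml == 0]
    if (length(ctrl) != 1L || ctrl <= 0)
      stop("series ", g, " needs exactly one positive 0-dose control")
    counts$survival[i] <- counts$eff_count[i] / ctrl
  }
  counts
}

#' Dose-response analysis of a colony-count assay table
#'
#' Full activity arm: normalise counts to survival, fit a 4PL per
#' peptide/bacterium, extract IC50 and convert to specific activity, then
#' aggregate into a table with means.
#'
#' @param counts colony-count data frame (see [survival_from_counts()]).
#' @return list with `fits` (per-combination data frame: `peptide_id`,
#'   `bacterium`, 4PL parameters, `ic50`, `activity`, `flag`) and `table`
#'   (an [aggregate_table()] of activities).
#' @export
activity_pipeline <- function(counts) {
  counts <- survival_from_counts(counts)
  combos <- unique(counts[, c("peptide_id", "bacterium")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- counts$peptide_id == combos$peptide_id[i] &
      counts$bacterium == combos$bacterium[i]
    fit <- fit_4pl(counts$dose_ug_per_ml[sel], counts$survival[sel])
    x50 <- ic50(fit)
    data.frame(peptide_id = combos$peptide_id[i],
               bacterium = combos$bacterium[i],
               lower = fit$lower, upper = fit$upper, slope = fit$slope,
               midpoint = fit$midpoint, unstable = fit$unstable,
               ic50 = as.numeric(x50),
               activity = as.numeric(specific_activity(as.numeric(x50))),
               flag = if (is.null(attr(x50, "flag"))) "" else attr(x50, "flag"),
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  mat <- tapply(fits$activity, list(fits$peptide_id, fits$bacterium), mean)
  mat <- mat[unique(fits$peptide_id), unique(fits$bacterium), drop = FALSE]
  list(fits = fits, table = aggregate_table(mat))
}
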