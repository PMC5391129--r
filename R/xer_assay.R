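#' Number of divisions from initial and final cell counts
#'
#' In a cassette-excision plating experiment the number of divisions that
#' took place during the exponential phase is deduced from the initial and
#' final number of cells per ml, `n = ln(Nf/Ni) / ln(2)`.
#'
#' @param Ni Initial cell count (cells/ml). Must be positive.
#' @param Nf Final cell count (cells/ml). Must be positive.
#' @param allow_shrinking If `FALSE` (default) a final count below the
#'   initial count (negative division number) is an error; set `TRUE` to
#'   allow it, e.g. for lysing cultures.
#' @return Number of divisions (dimensionless), vectorised over inputs.
#' @examples
#' count_divisions(1e6, 1.024e9) # 10 generations
#' @export
count_divisions <- function(Ni, Nf, allow_shrinking = FALSE) {
  if (any(!is.finite(Ni)) || any(!is.finite(Nf)) ||
      any(Ni <= 0) || any(Nf <= 0)) {
    stop("`Ni` and `Nf` must be positive finite cell counts.", call. = FALSE)
  }
  n <- log(Nf / Ni) / log(2)
  if (!allow_shrinking && any(n < 0)) {
    stop("Nf < Ni implies a shrinking culture; ",
         "set `allow_shrinking = TRUE` if this is intended.", call. = FALSE)
  }
  n
}

#' Per-generation cassette excision frequency
#'
#' Estimates the probability `f` that the reporter cassette is excised per
#' cell per generation, from the non-recombined colony fractions before and
#' after growth and the number of divisions:
#' `f = 1 - exp(ln(Rf/Ri) / n)`, which reduces to `f = 1 - exp(ln(Rf)/n)`
#' when the starting culture is fully non-recombined (`Ri = 1`, the usual
#' case).
#'
#' `Rf` is best measured while still in the 10--90% range; values outside
#' that window are accepted but flagged with a warning attribute, because a
#' nearly exhausted (or barely started) reporter pool makes `f` sensitive to
#' colony-count noise.
#'
#' @param Rf Final non-recombined fraction, in (0, 1].
#' @param n Number of divisions (see [count_divisions()]). Must be positive.
#' @param Ri Initial non-recombined fraction, in (0, 1]; defaults to 1.
#' @return Excision frequency per generation, vectorised. Carries a
#'   character vector attribute `"warnings"` when `Rf` lies outside the
#'   10--90% monitoring window.
#' @examples
#' excision_frequency(0.364, 19.3)  # ~5% per generation
#' excision_frequency(0.798, 19.9)  # ~1% per generation
#' @seealso [predict_final_ratio()] for the inverse, [reca_dependency()].
#' @export
excision_frequency <- function(Rf, n, Ri = 1) {
  if (any(!is.finite(Rf)) || any(Rf <= 0) || any(Rf > 1)) {
    stop("`Rf` must lie in (0, 1].", call. = FALSE)
  }
  if (any(!is.finite(Ri)) || any(Ri <= 0) || any(Ri > 1)) {
    stop("`Ri` must lie in (0, 1].", call. = FALSE)
  }
  if (any(Rf > Ri)) {
    stop("`Rf` exceeds `Ri`: the non-recombined fraction cannot grow; ",
         "check that the colony counts are not swapped.", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("`n` must be a positive number of divisions.", call. = FALSE)
  }
  f <- 1 - exp(log(Rf / Ri) / n)
  out_of_window <- Rf < 0.10 | Rf > 0.90
  if (any(out_of_window)) {
    attr(f, "warnings") <- sprintf(
      "Rf = %.3g outside the 10-90%% monitoring window; f may be unreliable",
      Rf[out_of_window])
  }
  f
}

#' Expected final non-recombined ratio
#'
#' Algebraic inverse of [excision_frequency()]: the expected fraction of
#' non-recombined cells after `n` divisions at per-generation excision
#' frequency `f` is `(1 - f)^n` (times the initial fraction `Ri`).
#'
#' @param f Excision frequency per generation, in \[0, 1).
#' @param n Number of divisions, >= 0.
#' @param Ri Initial non-recombined fraction, defaults to 1.
#' @return Expected final non-recombined fraction.
#' @examples
#' predict_final_ratio(0.05, 20) # ~0.358
#' @export
predict_final_ratio <- function(f, n, Ri = 1) {
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop("`f` must lie in [0, 1).", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("`n` must be >= 0.", call. = FALSE)
  }
  Ri * (1 - f)^n
}

#' recA-dependency of cassette excision
#'
#' Fraction of the excision rate attributable to homologous recombination
#' (chromosome-dimer formation): `1 - f_minus / f_plus`, where `f_plus` and
#' `f_minus` are the per-generation excision frequencies measured in recA+
#' and recA- strains. A value near 1 means excision requires RecA (dimers
#' only); near 0 means excision is dimer-independent.
#'
#' Sampling noise can push the statistic below zero when the true
#' dependency is small; negative values are reported verbatim with a
#' warning, never clamped.
#'
#' @param f_plus Excision frequency in the recA+ strain; must be > 0.
#' @param f_minus Excision frequency in the recA- strain; must be >= 0.
#' @return The dependency fraction, vectorised.
#' @examples
#' reca_dependency(0.0506, 0.0113) # ~0.78: mostly dimer-linked
#' @export
reca_dependency <- function(f_plus, f_minus) {
  if (any(!is.finite(f_plus)) || any(f_plus <= 0)) {
    stop("`f_plus` must be > 0.", call. = FALSE)
  }
  if (any(!is.finite(f_minus)) || any(f_minus < 0)) {
    stop("`f_minus` must be >= 0.", call. = FALSE)
  }
  dep <- 1 - f_minus / f_plus
  if (any(dep < 0)) {
    warning("negative recA-dependency (f_minus > f_plus); ",
            "reported unclamped.", call. = FALSE)
  }
  dep
}

ratio_cols_present <- function(counts) {
  all(c("colonies_total_f", "colonies_white_f") %in% names(counts))
}

#' Derive non-recombined ratios and divisions from a plating-count table
#'
#' Takes one row per plating replicate with raw counts and returns the same
#' table with `Ri`, `Rf` (non-recombined = blue = total - white fractions)
#' and `n` (divisions) columns added. Columns follow the assay CSV layout:
#' `replicate`, optional `condition`, `Ni`, `Nf`, and colony counts
#' `colonies_total_i`, `colonies_white_i`, `colonies_total_f`,
#' `colonies_white_f`. Missing initial colony counts default to `Ri = 1`
#' (fully non-recombined starting culture). Already-present `Ri`/`Rf`
#' columns are honoured.
#'
#' @param counts A data frame of plating counts.
#' @return A tibble with `Ri`, `Rf` and `n` columns.
#' @export
plating_ratios <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("Ni", "Nf") %in% names(counts))) {
    stop("`counts` needs `Ni` and `Nf` columns.", call. = FALSE)
  }
  if (!"Rf" %in% names(counts)) {
    if (!ratio_cols_present(counts)) {
      stop("`counts` needs either an `Rf` column or ",
           "`colonies_total_f`/`colonies_white_f` counts.", call. = FALSE)
    }
    counts <- dplyr::mutate(
      counts,
      Rf = (.data$colonies_total_f - .data$colonies_white_f) /
        .data$colonies_total_f)
  }
  if (!"Ri" %in% names(counts)) {
    if (all(c("colonies_total_i", "colonies_white_i") %in% names(counts))) {
      counts <- dplyr::mutate(
        counts,
        Ri = (.data$colonies_total_i - .data$colonies_white_i) /
          .data$colonies_total_i)
    } else {
      counts <- dplyr::mutate(counts, Ri = 1)
    }
  }
  dplyr::mutate(counts, n = count_divisions(.data$Ni, .data$Nf))
}

#' Estimate excision frequency from replicate plating counts
#'
#' Computes the per-generation excision frequency for a table of plating
#' replicates (see [plating_ratios()] for the expected columns). Two
#' aggregation modes are offered: `"per_replicate"` (default) computes `f`
#' separately for each replicate and averages, matching how per-experiment
#' means are usually reported; `"pooled"` first pools `Rf` and `n` across
#' replicates (mean ratio, mean divisions) and applies the formula once.
#'
#' @param counts Plating-count table, one row per replicate.
#' @param aggregate `"per_replicate"` or `"pooled"`.
#' @param n_boot Number of bootstrap resamples for the percentile CI over
#'   replicates; `0` (default) skips the CI. Needs >= 2 replicates.
#' @param conf_level Confidence level for the bootstrap interval.
#' @param seed Integer seed for the bootstrap; required when `n_boot > 0`.
#' @return An object of class `excision_fit`: a list with elements
#'   `estimate` (tibble: `f`, `n`, `sd_f`, `ci_low`, `ci_high`,
#'   `n_replicates`), `per_replicate` (tibble with per-replicate `f`),
#'   `aggregate`, and `warnings`. `tidy()` and `glance()` methods are
#'   provided.
#' @examples
#' tab <- tibble::tibble(replicate = 1:3,
#'                       Ni = 1e6, Nf = 1e6 * 2^19.3,
#'                       Rf = c(0.33, 0.36, 0.40))
#' fit <- estimate_excision(tab)
#' tidy(fit)
#' @export
estimate_excision <- function(counts,
                              aggregate = c("per_replicate", "pooled"),
                              n_boot = 0, conf_level = 0.95, seed = NULL) {
  aggregate <- match.arg(aggregate)
  tab <- plating_ratios(counts)
  fvec <- excision_frequency(tab$Rf, tab$n, tab$Ri)
  warnings <- attr(fvec, "warnings") %||% character()
  per <- dplyr::mutate(tab, f = as.numeric(fvec))

  if (aggregate == "per_replicate") {
    f_hat <- mean(per$f)
    n_hat <- mean(per$n)
  } else {
    n_hat <- mean(per$n)
    f_hat <- as.numeric(excision_frequency(mean(per$Rf), n_hat,
                                           mean(per$Ri)))
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (nrow(per) < 2) {
      stop("bootstrap CI needs >= 2 replicates.", call. = FALSE)
    }
    if (is.null(seed)) {
      stop("supply `seed` for a reproducible bootstrap.", call. = FALSE)
    }
    ci <- local_seed(seed, {
      stat <- function(idx) {
        sub <- per[idx, , drop = FALSE]
        if (aggregate == "per_replicate") mean(sub$f)
        else as.numeric(excision_frequency(mean(sub$Rf), mean(sub$n),
                                           mean(sub$Ri)))
      }
      boots <- vapply(seq_len(n_boot), function(i) {
        stat(sample.int(nrow(per), replace = TRUE))
      }, numeric(1))
      alpha <- (1 - conf_level) / 2
      unname(quantile(boots, c(alpha, 1 - alpha), type = 6))
    })
  }

  out <- list(
    estimate = tibble::tibble(
      f = f_hat, n = n_hat, sd_f = sd(per$f),
      ci_low = ci[1], ci_high = ci[2],
      n_replicates = nrow(per), conf_level = conf_level),
    per_replicate = per,
    aggregate = aggregate,
    warnings = warnings %||% character())
  class(out) <- "excision_fit"
  out
}

#' Bootstrap confidence interval for the excision frequency
#'
#' Percentile bootstrap over plating replicates of the plug-in estimator.
#' A convenience wrapper around [estimate_excision()] with `n_boot` set.
#'
#' @inheritParams estimate_excision
#' @param n_boot Number of bootstrap resamples (default 1999).
#' @return An `excision_fit` with `ci_low`/`ci_high` populated.
#' @export
bootstrap_ci <- function(counts, n_boot = 1999, seed,
                         conf_level = 0.95,
                         aggregate = c("per_replicate", "pooled")) {
  estimate_excision(counts, aggregate = match.arg(aggregate),
                    n_boot = n_boot, conf_level = conf_level, seed = seed)
}

#' @export
print.excision_fit <- function(x, ...) {
  e <- x$estimate
  cat("Cassette excision estimate (", x$aggregate, " aggregation)\n",
      sep = "")
  cat(sprintf("  f = %.4f per generation (sd %.4f, %d replicates)\n",
              e$f, e$sd_f, e$n_replicates))
  cat(sprintf("  n = %.2f divisions\n", e$n))
  if (!is.na(e$ci_low)) {
    cat(sprintf("  %g%% bootstrap CI: [%.4f, %.4f]\n",
                100 * e$conf_level, e$ci_low, e$ci_high))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @rdname estimate_excision
#' @param x An `excision_fit` object.
#' @param ... Unused.
#' @export
tidy.excision_fit <- function(x, ...) {
  dplyr::select(x$per_replicate, dplyr::any_of(
    c("replicate", "condition", "Ni", "Nf", "Ri", "Rf", "n", "f")))
}

#' @rdname estimate_excision
#' @export
glance.excision_fit <- function(x, ...) x$estimate

`%||%` <- function(a, b) if (is.null(a)) b else a
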