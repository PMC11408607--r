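#' Paired t test on per-fly means
#'
#' Two-tailed paired t test, the comparison used for the background-plus-
#' pulse experiment: per-fly mean response to the cognate odorant alone
#' versus with the incognate odorant present.
#'
#' @param x,y Paired numeric vectors (same flies, same order), length >= 2.
#' @return A one-row `test_result` data frame with `comparison`, `statistic`,
#'   `p`, `p_adjusted`, `method`, `n`, and a `degenerate` flag set when the
#'   paired differences have zero variance.
#' @export
paired_t_test <- function(x, y, comparison = "paired") {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need paired samples of equal length >= 2")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    # zero-variance differences: t undefined unless all differences are 0
    return(data.frame(comparison = comparison,
                      statistic = if (all(d == 0)) 0 else NA_real_,
                      p = if (all(d == 0)) 1 else NA_real_,
                      p_adjusted = if (all(d == 0)) 1 else NA_real_,
                      method = "none", n = length(x), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  data.frame(comparison = comparison, statistic = unname(ht$statistic),
             p = ht$p.value, p_adjusted = ht$p.value, method = "none",
             n = length(x), degenerate = FALSE)
}

#' Normalize responses to the cognate-alone response
#'
#' Divides every value by the mean cognate-alone response of the same fly,
#' unit, and concentration level. The cognate-alone stimulus for unit A is
#' the single-odorant stimulus `"A"`, and `"B"` for unit B; their normalized
#' per-fly means are 1 by construction.
#'
#' @param table Response table from [compute_response_table()].
#' @param cognate_map Named character: cognate-alone `stimulus_id` per unit.
#' @return The table with `value` replaced by the normalized value.
#' @export
normalize_to_cognate <- function(table, cognate_map = c(A = "A", B = "B")) {
  out <- table
  key <- interaction(table$fly_id, table$unit, table$level, drop = TRUE)
  for (k in levels(key)) {
    sel <- key == k
    unit <- table$unit[sel][1L]
    ref <- sel & table$stimulus_id == cognate_map[[unit]]
    if (!any(ref)) {
      stop("no cognate-alone trials for fly ", table$fly_id[sel][1L],
           ", unit ", unit)
    }
    m <- mean(table$value[ref])
    if (!is.finite(m) || m == 0) {
      stop("zero or non-finite cognate mean for fly ",
           table$fly_id[sel][1L], ", unit ", unit)
    }
    out$value[sel] <- table$value[sel] / m
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values controlling the false discovery rate.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length, each >= the raw value.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Onset-asynchrony test battery
#'
#' For each unit and each mixture stimulus, a two-tailed paired t test of the
#' per-fly mean normalized response against the per-fly mean normalized
#' cognate-alone response (which is 1 by construction), followed by
#' Benjamini-Hochberg correction across each unit's battery. Tests operate on
#' fly means (n = number of flies), matching how group sizes are reported.
#'
#' @param table Normalized response table (see [normalize_to_cognate()]).
#' @param cognate_map Cognate-alone `stimulus_id` per unit.
#' @return A `test_result` data frame, one row per (unit, stimulus), with
#'   columns `unit`, `stimulus_id`, `onset_asynchrony_ms`, `mean_normalized`,
#'   `statistic`, `p`, `p_adjusted`, `method`, `n`.
#' @export
asynchrony_test_battery <- function(table, cognate_map = c(A = "A", B = "B")) {
  res <- list()
  for (unit in unique(table$unit)) {
    tu <- table[table$unit == unit, ]
    cog <- cognate_map[[unit]]
    stims <- setdiff(unique(tu$stimulus_id), unname(cognate_map))
    if (!length(stims)) stop("no non-cognate stimuli for unit ", unit)
    cog_means <- tapply(tu$value[tu$stimulus_id == cog],
                        tu$fly_id[tu$stimulus_id == cog], mean)
    if (length(cog_means) < 2L) {
      stop("battery needs at least 2 flies")
    }
    rows <- lapply(stims, function(st) {
      sel <- tu$stimulus_id == st
      if (!any(sel)) stop("missing stimulus ", st)
      fly_means <- tapply(tu$value[sel], tu$fly_id[sel], mean)
      flies <- intersect(names(fly_means), names(cog_means))
      if (length(flies) < 2L) stop("battery needs at least 2 flies")
      tt <- paired_t_test(fly_means[flies], cog_means[flies],
                          comparison = paste0(unit, ": ", st, " vs ", cog))
      data.frame(unit = unit, stimulus_id = st,
                 onset_asynchrony_ms = tu$onset_asynchrony_ms[sel][1L],
                 mean_normalized = mean(fly_means[flies]),
                 statistic = tt$statistic, p = tt$p, n = tt$n)
    })
    battery <- do.call(rbind, rows)
    battery$p_adjusted <- fdr_adjust(battery$p)
    battery$method <- "BH"
    res[[unit]] <- battery
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Synchrony-window width from a test battery
#'
#' The synchrony window is the range of onset asynchronies over which the
#' mixture significantly suppresses the unit's response: the largest
#' significant |asynchrony| on the A-leading side plus the largest on the
#' B-leading side (each side contributing 0 when only the synchronous
#' stimulus, or nothing, is significant).
#'
#' @param battery Output of [asynchrony_test_battery()].
#' @param unit Unit to evaluate (default `"B"`, the more suppressed neuron).
#' @param alpha Significance level on the adjusted p values.
#' @return Width in milliseconds, with attribute `none_significant` set when
#'   no stimulus at all reached significance.
#' @export
synchrony_window_width <- function(battery, unit = "B", alpha = 0.05) {
  b <- battery[battery$unit == unit &
                 !is.na(battery$onset_asynchrony_ms) &
                 battery$mean_normalized < 1, ]
  sig <- b[!is.na(b$p_adjusted) & b$p_adjusted < alpha, ]
  a_side <- sig$onset_asynchrony_ms[sig$onset_asynchrony_ms > 0]
  b_side <- -sig$onset_asynchrony_ms[sig$onset_asynchrony_ms < 0]
  width <- (if (length(a_side)) max(a_side) else 0) +
    (if (length(b_side)) max(b_side) else 0)
  attr(width, "none_significant") <- nrow(sig) == 0L
  width
}

#' Per-fly and pooled regression of response on onset asynchrony
#'
#' Pools trailing and leading onset shifts by regressing the normalized
#' response on x = |onset asynchrony|: responses recover as the onsets move
#' apart, so inhibition that grows with synchrony appears as a positive
#' slope. One ordinary least-squares line per fly over its trial values,
#' plus an average regression over all points.
#'
#' @param table Normalized response table restricted by `unit`.
#' @param unit Unit to analyse.
#' @return A `regression_result` list: `per_fly` data frame (`fly_id`,
#'   `slope`, `intercept`, `r_squared`, `p`) and `average` (same fields on
#'   the pooled points).
#' @export
pooled_synchrony_regression <- function(table, unit = "B") {
  tu <- table[table$unit == unit & !is.na(table$onset_asynchrony_ms), ]
  if (!nrow(tu)) stop("no asynchrony trials for unit ", unit)
  tu$x <- abs(tu$onset_asynchrony_ms)
  ols <- function(df) {
    if (length(unique(df$x)) < 3L) {
      stop("need at least 3 distinct asynchronies per fly")
    }
    fit <- stats::lm(value ~ x, data = df)
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else
      NA_real_
    data.frame(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = sm$r.squared, p = p)
  }
  per_fly <- do.call(rbind, lapply(split(tu, tu$fly_id), ols))
  per_fly <- cbind(fly_id = as.numeric(rownames(per_fly)), per_fly)
  rownames(per_fly) <- NULL
  avg <- ols(tu)
  structure(list(per_fly = per_fly, average = avg),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> average slope %.4g per ms, r^2 = %.3f, p = %.3g\n",
    x$average$slope, x$average$r_squared, x$average$p))
  cat(sprintf("  per-fly slopes: %d flies, %d with p < 0.05\n",
              nrow(x$per_fly), sum(x$per_fly$p < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Within-fly pairwise Victor-Purpura distance groups
#'
#' For each labeled stimulus pair (X, Y), computes all within-fly cross-trial
#' distances between the unit's responses to X and to Y — all unordered trial
#' pairs excluding self-pairs when X = Y, all ordered combinations otherwise
#' — pooled across flies.
#'
#' @param tt A [trial_table()] containing the fluctuating stimuli.
#' @param q Victor-Purpura cost factor, 1/s.
#' @param pairs List of length-2 character vectors of `stimulus_id`s.
#' @param unit Unit whose trains are compared.
#' @param window Comparison window `[a, b)` in analysis seconds; spikes
#'   outside are dropped (default the full 10-s fluctuating segment).
#' @return Long data frame: `fly_id`, `unit`, `pair`, `stim_i`, `trial_i`,
#'   `stim_j`, `trial_j`, `q`, `d_vp`.
#' @export
dvp_comparison_groups <- function(tt, q = 20,
                                  pairs = list(c("A", "A"), c("B", "B"),
                                               c("AB_i", "AB_i"),
                                               c("AB_i", "A"),
                                               c("AB_i", "B"),
                                               c("AB_A", "A"),
                                               c("AB_B", "B")),
                                  unit = "B", window = c(0, 10)) {
  stopifnot(inherits(tt, "trial_table"))
  tr <- tt$trains[tt$trains$unit == unit, ]
  clip <- function(x) x[x >= window[1] & x < window[2]]
  out <- list()
  for (pair in pairs) {
    x <- pair[1L]; y <- pair[2L]
    if (!all(c(x, y) %in% tr$stimulus_id)) {
      stop("missing stimulus in trial table: ", paste(pair, collapse = ", "))
    }
    for (fly in unique(tr$fly_id)) {
      ti <- tr[tr$fly_id == fly & tr$stimulus_id == x, ]
      tj <- tr[tr$fly_id == fly & tr$stimulus_id == y, ]
      if (nrow(ti) < 2L || nrow(tj) < 2L) {
        stop("need >= 2 trials per stimulus per fly")
      }
      combos <- if (x == y) {
        utils::combn(nrow(ti), 2L)
      } else {
        t(as.matrix(expand.grid(seq_len(nrow(ti)), seq_len(nrow(tj)))))
      }
      d <- apply(combos, 2L, function(ij) {
        victor_purpura_distance(clip(ti$times[[ij[1L]]]),
                                clip(tj$times[[ij[2L]]]), q)
      })
      out[[length(out) + 1L]] <- data.frame(
        fly_id = fly, unit = unit,
        pair = paste0("(", x, ", ", y, ")"),
        stim_i = x, trial_i = ti$trial[combos[1L, ]],
        stim_j = y, trial_j = tj$trial[combos[2L, ]],
        q = q, d_vp = d)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mann-Whitney U tests with Bonferroni correction
#'
#' Two-sided U tests between named groups of distances, with p values
#' multiplied by the number of comparisons (capped at 1).
#'
#' @param groups Named list of numeric vectors (each n >= 3).
#' @param comparisons List of length-2 character vectors naming the groups to
#'   compare; default all unordered pairs.
#' @return A `test_result` data frame with `comparison`, `statistic` (U),
#'   `p`, `p_adjusted`, `method`, `n1`, `n2`.
#' @export
utest_bonferroni <- function(groups, comparisons = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    stop("each group needs n >= 3")
  }
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(groups), 2L, simplify = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    x <- groups[[cmp[1L]]]; y <- groups[[cmp[2L]]]
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    data.frame(comparison = paste(cmp, collapse = " vs "),
               statistic = unname(ht$statistic), p = ht$p.value,
               p_adjusted = min(1, ht$p.value * m), method = "bonferroni",
               n1 = length(x), n2 = length(y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
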