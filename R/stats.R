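#' Log-normalize values by the control group's median
#'
#' For log-normally distributed variables (diffusion coefficients, explored
#' areas, cluster metrics) each value is divided by the median of the
#' control group and log-transformed: `v' = log(v / median(control))`, so
#' the transformed control median is exactly 0. Non-positive values cannot
#' be log-transformed; they are returned as NA and their count is reported
#' in a message (callers exclude them upstream).
#'
#' @param values numeric vector (> 0 for finite output).
#' @param condition character/factor vector, same length as `values`.
#' @param control the control level of `condition` (default `"control"`).
#' @return numeric vector of transformed values with attribute
#'   `control_median`.
#' @export
lognormalize <- function(values, condition, control = "control") {
  stopifnot(length(values) == length(condition))
  ctrl <- values[condition == control]
  ctrl <- ctrl[is.finite(ctrl) & ctrl > 0]
  if (!length(ctrl)) stop("control group is empty (or all non-positive)")
  med <- median(ctrl)
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    message(sum(bad), " non-positive value(s) set to NA before log transform")
  }
  out <- rep(NA_real_, length(values))
  pos <- !is.na(values) & values > 0
  out[pos] <- log(values[pos] / med)
  attr(out, "control_median") <- med
  out
}

#' Two-group comparison with normality-driven test selection
#'
#' Decides between the Welch unequal-variance t-test and the two-sided
#' Mann-Whitney U test the way the quantification pipeline does: both groups
#' are checked with Shapiro-Wilk at `alpha_normality`; if both pass, Welch's
#' t is used, otherwise Mann-Whitney. The Mann-Whitney branch uses the exact
#' null when both groups have n <= 20 and there are no ties, and the
#' continuity-corrected normal approximation (mid-ranks for ties) otherwise.
#' A zero-variance group makes Welch undefined; the test falls back to
#' Mann-Whitney with a note.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param alpha_normality Shapiro-Wilk alpha (default 0.05).
#' @param method `"auto"` (normality-driven), or force `"welch"` / `"mw"`.
#' @return list of class `spt_test_result`: `statistic` (t or U), `p_value`,
#'   `test_name`, `n`, `normality` (per-group Shapiro p and decision),
#'   `note`.
#' @export
choose_and_test <- function(a, b, alpha_normality = 0.05,
                            method = c("auto", "welch", "mw")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  shap <- function(x) {
    if (length(unique(x)) < 3L) return(0) # degenerate: clearly non-normal
    x <- if (length(x) > 5000) sample(x, 5000) else x
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  pa <- shap(a)
  pb <- shap(b)
  normal <- pa > alpha_normality && pb > alpha_normality
  use_welch <- switch(method, auto = normal, welch = TRUE, mw = FALSE)
  note <- NULL
  if (use_welch) {
    res <- tryCatch(t.test(a, b, var.equal = FALSE), error = function(e) NULL)
    if (is.null(res)) {
      use_welch <- FALSE
      note <- "welch undefined (zero-variance group); fell back to MW"
    } else {
      return(structure(
        list(statistic = unname(res$statistic), p_value = res$p.value,
             test_name = "welch_t", n = c(length(a), length(b)),
             normality = list(p_a = pa, p_b = pb, normal = normal),
             note = note),
        class = "spt_test_result"
      ))
    }
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- max(length(a), length(b)) <= 20L && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(res$statistic), p_value = res$p.value,
         test_name = "mann_whitney", n = c(length(a), length(b)),
         normality = list(p_a = pa, p_b = pb, normal = normal),
         note = note),
    class = "spt_test_result"
  )
}

# Mann-Whitney U of group a vs b via mid-ranks (U + U' = n_a * n_b).
mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# two-sided p for U under the normal null (continuity-corrected, no tie
# correction: used on continuous resampled values)
mw_p_normal <- function(u, na, nb) {
  mu <- na * nb / 2
  sd <- sqrt(na * nb * (na + nb + 1) / 12)
  z <- (abs(u - mu) - 0.5) / sd
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Balanced Monte-Carlo Mann-Whitney test for clustered observations
#'
#' Resampling procedure for super-resolution cluster metrics where
#' observations are nested in neurons and cultures and per-neuron counts are
#' unequal. Per repetition (seeded): `m` = the minimum per-neuron
#' observation count across all neurons of both conditions; `m` observations
#' are drawn without replacement from every neuron; within each culture the
#' selected values are divided by the median of that culture's selected
#' control values; cultures are pooled, the log is applied, and the
#' Mann-Whitney U of treated vs control is computed. After `n_reps`
#' repetitions the summary U is the median of the per-repetition U values
#' and the p-value is its two-sided tail probability under the Mann-Whitney
#' null for the balanced per-repetition sample sizes
#' (`p_method = "tail"`); `p_method = "median_p"` instead reports the
#' median of the per-repetition p-values.
#'
#' The equal per-neuron draw prevents any single neuron, condition or
#' culture from dominating the pooled rank statistic, which is the stated
#' purpose of the balanced selection.
#'
#' @param data `data.frame` with columns `value` (> 0), `condition` (two
#'   levels, one equal to `control`), `culture`, `neuron`.
#' @param n_reps number of repetitions (default 1000).
#' @param seed integer seed; the procedure is deterministic under a fixed
#'   seed and invariant to input row order (rows are sorted internally).
#' @param control control level of `condition`.
#' @param p_method `"tail"` or `"median_p"` (both described above).
#' @return list of class `mcmw_result`: `u_values` (length `n_reps`), `u`
#'   (median U), `p_value`, `p_value_median_p` (the alternative
#'   aggregation, always reported alongside), `n` (balanced sizes), `m`,
#'   `n_reps`, `seed`, `n_excluded_nonpositive`, `n_excluded_neurons`.
#' @export
mc_balanced_mw <- function(data, n_reps = 1000L, seed = NULL,
                           control = "control",
                           p_method = c("tail", "median_p")) {
  p_method <- match.arg(p_method)
  stopifnot(all(c("value", "condition", "culture", "neuron") %in%
                  names(data)))
  n_bad <- sum(!is.finite(data$value) | data$value <= 0)
  if (n_bad) {
    message(n_bad, " non-positive value(s) excluded")
    data <- data[is.finite(data$value) & data$value > 0, , drop = FALSE]
  }
  conds <- unique(as.character(data$condition))
  if (length(conds) != 2L || !(control %in% conds)) {
    stop("condition must have exactly two levels including '", control, "'")
  }
  treated <- setdiff(conds, control)
  # canonical row order: procedure invariant to input permutation
  ord <- order(data$culture, data$condition, data$neuron, data$value)
  data <- data[ord, , drop = FALSE]
  key <- interaction(data$culture, data$condition, data$neuron, drop = TRUE)
  idx_by_neuron <- split(seq_len(nrow(data)), key)
  sizes <- lengths(idx_by_neuron)
  n_excluded_neurons <- sum(sizes == 0L)
  idx_by_neuron <- idx_by_neuron[sizes > 0L]
  info <- do.call(rbind, lapply(names(idx_by_neuron), function(k) {
    i <- idx_by_neuron[[k]][1]
    data.frame(culture = as.character(data$culture[i]),
               condition = as.character(data$condition[i]))
  }))
  for (cc in conds) {
    if (sum(info$condition == cc) < 2L) {
      stop("condition '", cc, "' has fewer than 2 neurons with observations")
    }
  }
  for (cu in unique(info$culture)) {
    if (!any(info$condition == control & info$culture == cu)) {
      stop("culture '", cu, "' has no control observations")
    }
  }
  m <- min(lengths(idx_by_neuron))
  values <- data$value
  is_treated_neuron <- info$condition == treated
  culture_of_neuron <- info$culture
  cultures <- unique(culture_of_neuron)
  n_t <- m * sum(is_treated_neuron)
  n_c <- m * sum(!is_treated_neuron)
  .local_seed(seed)
  nn <- length(idx_by_neuron)
  # per-neuron draw templates
  u_values <- numeric(n_reps)
  p_values <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sel <- lapply(idx_by_neuron, function(ix) {
      if (length(ix) == m) ix else ix[sample.int(length(ix), m)]
    })
    v <- values[unlist(sel, use.names = FALSE)]
    neuron_of_obs <- rep(seq_len(nn), each = m)
    cult <- culture_of_neuron[neuron_of_obs]
    trt <- is_treated_neuron[neuron_of_obs]
    for (cu in cultures) {
      in_cu <- cult == cu
      med <- median(v[in_cu & !trt])
      v[in_cu] <- v[in_cu] / med
    }
    lv <- log(v)
    u_values[r] <- mw_u(lv[trt], lv[!trt])
    p_values[r] <- mw_p_normal(u_values[r], n_t, n_c)
  }
  u_med <- median(u_values)
  p_tail <- mw_p_normal(u_med, n_t, n_c)
  p_med <- median(p_values)
  structure(
    list(
      u_values = u_values, u = u_med,
      p_value = if (p_method == "tail") p_tail else p_med,
      p_value_tail = p_tail, p_value_median_p = p_med,
      p_method = p_method,
      n = c(treated = n_t, control = n_c), m = m, n_reps = n_reps,
      seed = seed, n_excluded_nonpositive = n_bad,
      n_excluded_neurons = n_excluded_neurons
    ),
    class = "mcmw_result"
  )
}
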