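#' Cliff's delta effect size
#'
#' Nonparametric dominance effect size: the normalised difference between
#' the number of cross-sample pairs where `a` exceeds `b` and where `b`
#' exceeds `a`:
#' \deqn{\delta = (\#\{a_i > b_j\} - \#\{a_i < b_j\}) / (|a| |b|)}
#'
#' @param a,b Nonempty numeric samples.
#' @return Delta in `[-1, 1]`.
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4)) # -5/9
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("cliffs_delta: empty sample", call. = FALSE)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  d <- outer(a, b, "-")
  (sum(d > 0) - sum(d < 0)) / (length(a) * length(b))
}

#' Categorical label for a Cliff's delta
#'
#' Maps `|delta|` to negligible / small / medium / large. The default cuts
#' are 0.15, 0.33 and 0.66; unlike the conventional 0.474 medium/large cut,
#' these reproduce the labelling used in the questionnaire analysis this
#' package mirrors (where 0.5 counts as a medium effect). The cuts are
#' configurable.
#'
#' @param delta Numeric delta(s) with `|delta| <= 1`.
#' @param cuts Increasing positive thresholds `c(negligible, small, medium)`.
#' @return Character vector of labels.
#' @examples
#' effect_label(c(-0.4, 0.3, 0.0)) # medium, small, negligible
#' @export
effect_label <- function(delta, cuts = c(0.15, 0.33, 0.66)) {
  stopifnot(all(abs(delta) <= 1 + 1e-12), length(cuts) == 3L,
            all(diff(cuts) > 0), all(cuts > 0))
  a <- abs(delta)
  out <- character(length(a))
  out[a < cuts[1]] <- "negligible"
  out[a >= cuts[1] & a < cuts[2]] <- "small"
  out[a >= cuts[2] & a < cuts[3]] <- "medium"
  out[a >= cuts[3]] <- "large"
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed-rank test in the convention of the mainstream scientific-Python
#' toolkits: zero differences are dropped, the reported statistic is
#' `min(W+, W-)`, and the p-value comes from the normal approximation with
#' the tie-corrected variance (no continuity correction). This makes the
#' printed statistic directly comparable to published W values; for small
#' tie-free samples `stats::wilcox.test` serves as an exact cross-check.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return List with `statistic` (min(W+, W-)), `z`, `p_value` and
#'   `n_effective` (pairs with nonzero difference).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  statistic <- min(w_plus, w_minus)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (statistic - mu) / sqrt(sigma2)
  list(statistic = statistic, z = z,
       p_value = min(1, 2 * stats::pnorm(-abs(z))),
       n_effective = n)
}

# assemble one test outcome with its effect size
stat_result <- function(test_name, statistic, p_value, a = NULL, b = NULL,
                        n = NA_integer_, note = NA_character_,
                        delta = NULL) {
  if (is.null(delta))
    delta <- if (!is.null(a) && !is.null(b)) cliffs_delta(a, b) else NA_real_
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         effect_size = delta,
         effect_label = if (is.na(delta)) NA_character_ else effect_label(delta),
         n = as.integer(n), note = note),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result %s> stat = %s, p = %s, delta = %s (%s), n = %d%s\n",
              x$test_name,
              format(x$statistic, digits = 4), format(x$p_value, digits = 4),
              format(x$effect_size, digits = 3),
              ifelse(is.na(x$effect_label), "-", x$effect_label), x$n,
              if (is.na(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Compare two paired samples with normality gating
#'
#' Runs Shapiro-Wilk at `alpha` either on both sample margins (raw
#' condition scores) or on the paired differences (derived difference
#' scores); if any normality test rejects, the comparison uses the Wilcoxon
#' signed-rank test, otherwise a paired Student t-test. Cliff's delta and
#' its label are always attached.
#'
#' @param x,y Paired numeric samples (`n >= 5`), aligned by participant.
#' @param force_test `"auto"` (gate on normality), `"wilcoxon"` or `"t"`.
#' @param normality_on `"margins"` or `"differences"`.
#' @param alpha Level of the Shapiro-Wilk gate (default 0.05).
#' @return A `stat_result`; its `shapiro` attribute carries the gate
#'   p-values.
#' @export
compare_paired <- function(x, y, force_test = c("auto", "wilcoxon", "t"),
                           normality_on = c("margins", "differences"),
                           alpha = 0.05) {
  force_test <- match.arg(force_test)
  normality_on <- match.arg(normality_on)
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- x - y
  if (all(d == 0))
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  shapiro_p <- if (normality_on == "margins")
    c(x = stats::shapiro.test(x)$p.value, y = stats::shapiro.test(y)$p.value)
  else c(d = stats::shapiro.test(d)$p.value)
  use_wilcoxon <- switch(force_test,
                         auto = any(shapiro_p < alpha),
                         wilcoxon = TRUE,
                         t = FALSE)
  res <- if (use_wilcoxon) {
    w <- wilcoxon_signed_rank(x, y)
    stat_result("wilcoxon_signed_rank", w$statistic, w$p_value,
                a = x, b = y, n = length(x))
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    stat_result("paired_t", unname(tt$statistic), tt$p.value,
                a = x, b = y, n = length(x))
  }
  attr(res, "shapiro") <- shapiro_p
  res
}

#' Human-baseline correction of per-participant synchrony times
#'
#' Subtracts each participant's `human`-condition value from their
#' `coupling` and `no_coupling` values, removing idiosyncratic tendencies
#' (e.g. holding the button regardless of condition).
#'
#' @param sync_times Data frame with columns `participant`, `condition`
#'   (`human`, `no_coupling`, `coupling`) and a value column (default
#'   `time_pressed_s`); every participant must have all three conditions.
#' @param value Name of the value column.
#' @return Data frame with columns `participant`, `coupling_minus_human`,
#'   `no_coupling_minus_human`.
#' @export
baseline_correct <- function(sync_times, value = "time_pressed_s") {
  needed <- c("human", "no_coupling", "coupling")
  stopifnot(all(c("participant", "condition", value) %in% names(sync_times)))
  wide <- stats::reshape(
    sync_times[, c("participant", "condition", value)],
    idvar = "participant", timevar = "condition", direction = "wide"
  )
  cols <- paste(value, needed, sep = ".")
  if (!all(cols %in% names(wide)) || anyNA(wide[, cols]))
    stop("baseline_correct: every participant needs all three conditions",
         call. = FALSE)
  data.frame(
    participant = wide$participant,
    coupling_minus_human = wide[[cols[3]]] - wide[[cols[1]]],
    no_coupling_minus_human = wide[[cols[2]]] - wide[[cols[1]]]
  )
}

#' Per-question condition comparison of questionnaire responses
#'
#' For each graded question, compares the two conditions across participants
#' with the Wilcoxon signed-rank test (the convention for ordinal scales),
#' and reports per-condition medians, Cliff's delta (`a` vs `b` order) and
#' its label. No multiple-testing correction is applied by default, matching
#' the practice of reporting raw per-question p-values; Holm correction can
#' be switched on.
#'
#' @param table Questionnaire data frame (`participant`, `condition`,
#'   `question`, `response`), e.g. from [generate_questionnaire()].
#' @param cond_a,cond_b Conditions to compare (defaults `no_coupling` vs
#'   `coupling`).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Data frame, one row per question: `question`, `median_a`,
#'   `median_b`, `statistic`, `p_value`, `delta`, `label`; conditions are
#'   recorded in attributes `cond_a` / `cond_b`.
#' @export
analyze_questionnaire <- function(table, cond_a = "no_coupling",
                                  cond_b = "coupling", p_adjust = "none") {
  stopifnot(all(c("participant", "condition", "question", "response")
                %in% names(table)))
  qs <- sort(unique(table$question))
  rows <- lapply(qs, function(q) {
    sub <- table[table$question == q, ]
    a <- sub[sub$condition == cond_a, c("participant", "response")]
    b <- sub[sub$condition == cond_b, c("participant", "response")]
    m <- merge(a, b, by = "participant", suffixes = c("_a", "_b"))
    if (nrow(m) < nrow(a) || nrow(m) < nrow(b) || nrow(m) == 0L)
      stop(sprintf("question %s: conditions are not completely paired", q),
           call. = FALSE)
    res <- tryCatch(wilcoxon_signed_rank(m$response_a, m$response_b),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    delta <- cliffs_delta(m$response_a, m$response_b)
    data.frame(question = q,
               median_a = stats::median(m$response_a),
               median_b = stats::median(m$response_b),
               statistic = res$statistic, p_value = res$p_value,
               delta = delta, label = effect_label(delta))
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- cond_b
  out
}

#' Two-stage analysis of reported synchrony times
#'
#' Stage 1 works on the raw per-participant times: Shapiro-Wilk normality
#' per condition, then a Wilcoxon signed-rank comparison of `coupling` vs
#' `no_coupling`. Stage 2 removes each participant's `human` baseline with
#' [baseline_correct()], re-tests normality on the two difference samples,
#' and compares them with a paired t-test plus Cliff's delta. Degenerate
#' inputs (all differences zero, or constant samples) are propagated as
#' flagged null results rather than errors.
#'
#' @inheritParams baseline_correct
#' @return Object of class `sync_times_analysis`: a list of `stat_result`s
#'   named `shapiro_human`, `shapiro_no_coupling`, `shapiro_coupling`,
#'   `wilcoxon_raw`, `shapiro_coupling_minus_human`,
#'   `shapiro_no_coupling_minus_human`, `paired_t_baseline`, plus the
#'   baseline-corrected `differences` data frame and their means/sds.
#' @export
analyze_sync_times <- function(sync_times, value = "time_pressed_s") {
  conds <- c("human", "no_coupling", "coupling")
  get_cond <- function(cond) {
    sub <- sync_times[sync_times$condition == cond, ]
    sub[[value]][order(sub$participant)]
  }
  vals <- lapply(stats::setNames(conds, conds), get_cond)
  if (any(vapply(vals, length, 1L) == 0L))
    stop("analyze_sync_times: every condition must be present", call. = FALSE)

  safe_shapiro <- function(v, name) {
    tryCatch({
      s <- stats::shapiro.test(v)
      stat_result(paste0("shapiro_", name), unname(s$statistic), s$p.value,
                  n = length(v))
    }, error = function(e)
      stat_result(paste0("shapiro_", name), NA_real_, NA_real_,
                  n = length(v), note = "degenerate"))
  }
  out <- list()
  for (cond in conds) out[[paste0("shapiro_", cond)]] <-
    safe_shapiro(vals[[cond]], cond)
  out$wilcoxon_raw <- tryCatch({
    w <- wilcoxon_signed_rank(vals$coupling, vals$no_coupling)
    stat_result("wilcoxon_raw", w$statistic, w$p_value,
                a = vals$coupling, b = vals$no_coupling,
                n = length(vals$coupling))
  }, error = function(e)
    stat_result("wilcoxon_raw", NA_real_, NA_real_,
                n = length(vals$coupling), note = "degenerate"))

  diffs <- baseline_correct(sync_times, value = value)
  out$shapiro_coupling_minus_human <-
    safe_shapiro(diffs$coupling_minus_human, "coupling_minus_human")
  out$shapiro_no_coupling_minus_human <-
    safe_shapiro(diffs$no_coupling_minus_human, "no_coupling_minus_human")
  out$paired_t_baseline <- tryCatch({
    if (all(diffs$coupling_minus_human == diffs$no_coupling_minus_human))
      stop("degenerate")
    tt <- stats::t.test(diffs$coupling_minus_human,
                        diffs$no_coupling_minus_human, paired = TRUE)
    stat_result("paired_t_baseline", unname(tt$statistic), tt$p.value,
                a = diffs$coupling_minus_human,
                b = diffs$no_coupling_minus_human, n = nrow(diffs))
  }, error = function(e)
    stat_result("paired_t_baseline", NA_real_, NA_real_,
                n = nrow(diffs), note = "degenerate"))
  out$differences <- diffs
  out$difference_summary <- data.frame(
    sample = c("coupling_minus_human", "no_coupling_minus_human"),
    mean = c(mean(diffs$coupling_minus_human),
             mean(diffs$no_coupling_minus_human)),
    sd = c(stats::sd(diffs$coupling_minus_human),
           stats::sd(diffs$no_coupling_minus_human))
  )
  class(out) <- "sync_times_analysis"
  out
}

#' @export
print.sync_times_analysis <- function(x, ...) {
  cat("<sync_times_analysis>\n")
  for (nm in names(x))
    if (inherits(x[[nm]], "stat_result")) print(x[[nm]])
  invisible(x)
}
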