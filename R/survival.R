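#' Two-group log-rank test
#'
#' The standard log-rank comparison of two survival curves: at each distinct
#' event time the observed number of events in the first group is compared
#' with its hypergeometric expectation given the risk-set margins; the
#' statistic is \code{(sum O - sum E)^2 / sum V}, referred to a chi-square
#' distribution with one degree of freedom. Also returns the signed
#' standardized statistic \code{z = (sum O - sum E) / sqrt(sum V)} used by
#' the maximally selected cutpoint scan.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level grouping (logical, factor, or two-valued vector).
#' @return List with \code{statistic}, \code{p_value}, \code{z},
#'   \code{observed}, \code{expected} (for the first group level).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("times must be positive")
  g <- as.factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("group must contain exactly two non-empty levels")
  }
  in1 <- g == levels(g)[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (V == 0) {
    return(list(statistic = 0, p_value = 1, z = 0, observed = O,
                expected = E))
  }
  z <- (O - E) / sqrt(V)
  stat <- z^2
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       z = z, observed = O, expected = E)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Scans every observed score value whose induced low/high split keeps both
#' group proportions within \code{[minprop, 1 - minprop]}, evaluates the
#' standardized log-rank statistic at each candidate, and returns the
#' cutpoint maximizing its absolute value (ties broken toward the smaller
#' cutpoint). Samples with score less than or equal to the cutpoint form the
#' "low" group.
#'
#' Note the selected cutpoint's naive log-rank p-value is anticonservative:
#' the maximum over many candidate splits inflates the statistic relative to
#' a prespecified split, so model-based inference should accompany any
#' Kaplan-Meier display stratified this way.
#'
#' @param scores named numeric vector of per-sample scores (as from
#'   \code{\link{network_activity_score}}).
#' @param survival data.frame with columns \code{sample}, \code{time},
#'   \code{event}.
#' @param minprop minimum group proportion for an admissible split.
#' @return An object of class \code{cutpoint_result}: list with
#'   \code{cutpoint}, \code{statistic} (max |z|), \code{groups} (named
#'   factor "low"/"high"), \code{candidates} (data.frame of scanned
#'   cutpoints and their |z|), \code{logrank} (test at the selected split).
#' @export
maxstat_cutpoint <- function(scores, survival, minprop = 0.1) {
  stopifnot(all(c("sample", "time", "event") %in% names(survival)))
  if (length(scores) < 10) stop("need at least 10 samples")
  idx <- match(survival$sample, names(scores))
  if (anyNA(idx)) stop("survival table names sample(s) without scores")
  s <- scores[idx]
  time <- survival$time
  event <- survival$event
  if (sum(event) < 1) stop("need at least one event")
  n <- length(s)

  cand <- sort(unique(s))
  admissible <- vapply(cand, function(ct) {
    nlow <- sum(s <= ct)
    nlow / n >= minprop && nlow / n <= 1 - minprop
  }, logical(1))
  cand <- cand[admissible]
  if (length(cand) == 0) {
    stop("no candidate cutpoint respects minprop = ", minprop)
  }
  zs <- vapply(cand, function(ct) {
    logrank_test(time, event, factor(ifelse(s <= ct, "low", "high"),
                                     levels = c("low", "high")))$z
  }, numeric(1))
  best <- which.max(abs(zs))  # which.max returns the first (smallest) tie
  cut <- cand[best]
  groups <- factor(ifelse(s <= cut, "low", "high"),
                   levels = c("low", "high"))
  names(groups) <- survival$sample
  structure(list(
    cutpoint = cut,
    statistic = abs(zs[best]),
    groups = groups,
    candidates = data.frame(cutpoint = cand, abs_z = abs(zs)),
    logrank = logrank_test(time, event, groups)
  ), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("maxstat cutpoint:", format(x$cutpoint, digits = 4),
      "| standardized log-rank", format(x$statistic, digits = 4),
      "| groups:", sum(x$groups == "low"), "low /",
      sum(x$groups == "high"), "high\n")
  cat("  log-rank at cutpoint: chi-sq =",
      format(x$logrank$statistic, digits = 4), ", p =",
      format(x$logrank$p_value, digits = 3),
      "(anticonservative for the selected split)\n")
  invisible(x)
}

#' Kaplan-Meier table per group
#'
#' Product-limit survival estimates tabulated at each distinct event time
#' within each group, for writing alongside a cutpoint stratification.
#'
#' @param time,event,group as in \code{\link{logrank_test}}.
#' @return data.frame with columns \code{group}, \code{time},
#'   \code{n_at_risk}, \code{n_events}, \code{survival}.
#' @export
km_table <- function(time, event, group) {
  g <- as.factor(group)
  out <- lapply(levels(g), function(lev) {
    t <- time[g == lev]; e <- event[g == lev]
    ts <- sort(unique(t[e == 1]))
    surv <- 1
    rows <- lapply(ts, function(tt) {
      n_risk <- sum(t >= tt)
      d <- sum(e == 1 & t == tt)
      surv <<- surv * (1 - d / n_risk)
      data.frame(group = lev, time = tt, n_at_risk = n_risk,
                 n_events = d, survival = surv)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(group = character(), time = numeric(),
                      n_at_risk = integer(), n_events = integer(),
                      survival = numeric())
  }
  rownames(res) <- NULL
  res
}
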