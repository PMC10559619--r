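# Kaplan-Meier product-limit estimation with Greenwood variance, log-log
# confidence intervals, Brookmeyer-Crowley median intervals, and the
# log-rank two-group comparison.

#' Kaplan-Meier product-limit fit
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times,
#' with events processed before censorings at tied times. Greenwood's
#' formula gives the pointwise variance; 95% confidence intervals use the
#' complementary log-log transform. The median is the first event time
#' with `S(t) <= 0.5` (NA when the curve never reaches 0.5); its 95%
#' interval inverts the pointwise interval (first times the lower / upper
#' confidence curves drop to <= 0.5).
#'
#' @param records data.frame (sample, time, event, group); `event` 1 =
#'   event, 0 = censored.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `km_curve`: `table` (time, n_risk, n_event,
#'   n_censor, surv, greenwood_var, lo, hi), `median`, `median_ci`,
#'   `n`, `n_events`.
#' @export
km_fit <- function(records, conf_level = 0.95) {
  if (nrow(records) == 0) stop("no survival records")
  if (any(records$time < 0)) stop("negative survival times")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  times <- sort(unique(records$time))
  n <- nrow(records)
  surv <- 1
  cumhaz_var <- 0 # sum d / (n (n - d)), the Greenwood accumulator
  rows <- lapply(times, function(t) {
    n_risk <- sum(records$time >= t)
    d <- sum(records$time == t & records$event == 1)
    cens <- sum(records$time == t & records$event == 0)
    surv <<- surv * (1 - d / n_risk)
    if (d > 0 && n_risk > d)
      cumhaz_var <<- cumhaz_var + d / (n_risk * (n_risk - d))
    gvar <- if (surv %in% c(0, 1)) 0 else surv^2 * cumhaz_var
    if (surv > 0 && surv < 1) {
      se_cll <- sqrt(cumhaz_var) / abs(log(surv))
      lo <- surv^exp(z * se_cll)
      hi <- surv^exp(-z * se_cll)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    data.frame(time = t, n_risk = n_risk, n_event = d, n_censor = cens,
               surv = surv, greenwood_var = gvar, lo = lo, hi = hi)
  })
  tab <- do.call(rbind, rows)
  ev <- tab[tab$n_event > 0, , drop = FALSE]
  median_t <- if (any(ev$surv <= 0.5)) min(ev$time[ev$surv <= 0.5]) else NA_real_
  first_below <- function(curve) {
    ok <- !is.na(curve) & curve <= 0.5
    # S = 0 rows have NA CI; the point estimate itself bounds them
    ok <- ok | (is.na(curve) & tab$surv <= 0.5)
    if (any(ok)) min(tab$time[ok]) else NA_real_
  }
  median_ci <- c(lower = first_below(tab$lo), upper = first_below(tab$hi))
  structure(list(table = tab, median = median_t, median_ci = median_ci,
                 n = n, n_events = sum(records$event == 1),
                 conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s (%s CI %s-%s)\n",
              x$n, x$n_events, format(x$median, digits = 4),
              format(x$conf_level), format(x$median_ci[1], digits = 4),
              format(x$median_ci[2], digits = 4)))
  invisible(x)
}

#' Two-group survival comparison by the log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom over the pooled
#' distinct event times, plus per-group product-limit curves.
#'
#' @param records data.frame (sample, time, event, group).
#' @param group_a,group_b group labels to compare (both non-empty).
#' @return list: `statistic` (chi-square), `p_value`, `observed` /
#'   `expected` for group a, `curves` (named list of `km_curve`).
#' @export
km_compare <- function(records, group_a, group_b) {
  ra <- records[records$group == group_a, , drop = FALSE]
  rb <- records[records$group == group_b, , drop = FALSE]
  if (nrow(ra) == 0 || nrow(rb) == 0) stop("both groups must be non-empty")
  if (sum(ra$event) == 0 || sum(rb$event) == 0)
    warning("a group has zero events; the log-rank statistic may be degenerate")
  pooled <- rbind(ra, rb)
  ev_times <- sort(unique(pooled$time[pooled$event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    n1 <- sum(ra$time >= t); n2 <- sum(rb$time >= t)
    d1 <- sum(ra$time == t & ra$event == 1)
    d2 <- sum(rb$time == t & rb$event == 1)
    nt <- n1 + n2; dt <- d1 + d2
    if (nt == 0) next
    o1 <- o1 + d1
    e1 <- e1 + dt * n1 / nt
    if (nt > 1)
      v <- v + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, observed = o1, expected = e1,
       curves = stats::setNames(list(km_fit(ra), km_fit(rb)),
                                c(group_a, group_b)))
}

#' Write a fitted Kaplan-Meier curve as TSV
#' @param curve `km_curve`.
#' @param path output file.
#' @export
write_km_tsv <- function(curve, path) {
  utils::write.table(curve$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
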