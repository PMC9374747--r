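#' Log2 fold changes against the fasting baseline
#'
#' Fold change of the mean amount at each post-administration time point
#' over the mean amount at the fasting state (0 min), per molecule and
#' genotype; means are arithmetic means of non-missing replicates on the
#' raw scale. Molecules with a zero or missing baseline mean get NA fold
#' changes (flagged, excluded from responsiveness calls).
#'
#' @param tc an \code{omics_timecourse}.
#' @return data.frame(molecule_id, genotype, time, log2fc).
#' @export
log2_fold_changes <- function(tc) {
  mt <- tc_mean_traces(tc)
  times <- tc_times(tc)
  post <- times[times > 0]
  out <- list()
  for (g in c("WT", "OB")) {
    base <- mt[, g, "0"]
    for (t in as.character(post)) {
      fc <- log2(mt[, g, t] / base)
      fc[!is.finite(base) | base <= 0] <- NA_real_
      fc[is.nan(fc)] <- NA_real_
      out[[paste(g, t)]] <- data.frame(
        molecule_id = tc_molecules(tc), genotype = g, time = as.numeric(t),
        log2fc = unname(fc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Half-time of a response trace
#'
#' T1/2 is the first time a trace's deviation from its 0-min baseline
#' reaches half of its extremal amplitude in the called direction, with
#' linear interpolation between sampled time points (first crossing wins).
#' For non-monotone traces the amplitude is the extremum in the called
#' direction over all time points. A flat trace has no defined half-time.
#'
#' @param trace numeric trace defined at every time point (any scale; the
#'   pipeline uses the log2 fold-change trace with 0 at baseline).
#' @param times sampling times in minutes, starting at 0.
#' @param direction "increase" or "decrease".
#' @return half-time in minutes, or NA if the amplitude is zero or the
#'   half level is never reached.
#' @export
half_time <- function(trace, times, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(length(trace) == length(times), times[1] == 0)
  if (anyNA(trace)) return(NA_real_)
  dev <- trace - trace[1]
  amp <- if (direction == "increase") max(dev) else min(dev)
  if (amp == 0) {
    warning("flat trace: half-time undefined")
    return(NA_real_)
  }
  target <- amp / 2
  for (i in 2:length(times)) {
    reached <- if (direction == "increase") dev[i] >= target else dev[i] <= target
    if (reached) {
      return(times[i - 1] +
               (target - dev[i - 1]) / (dev[i] - dev[i - 1]) *
               (times[i] - times[i - 1]))
    }
  }
  NA_real_
}

#' Speed class of a half-time
#'
#' Rapid responses have T1/2 strictly below \code{rapid_max_min} (20 min by
#' default, the time blood insulin peaks); slow responses strictly above
#' \code{slow_min_min} (60 min, when insulin is back to baseline); the
#' boundary values themselves are intermediate.
#' @param t_half half-time in minutes (NA allowed).
#' @param config a \code{pipeline_config}.
#' @return "rapid", "intermediate", "slow" or "undefined".
#' @export
speed_class <- function(t_half, config = pipeline_config()) {
  ifelse(is.na(t_half), "undefined",
         ifelse(t_half < config$rapid_max_min, "rapid",
                ifelse(t_half > config$slow_min_min, "slow", "intermediate")))
}

#' Apply the responsiveness criteria to aligned fold changes and q-values
#'
#' A molecule is glucose-responsive in a genotype when, at some
#' post-administration time point, q <= q_threshold AND
#' |log2 fold change| >= fc_threshold_log2. The direction is the sign of
#' the fold change at the earliest significant time point.
#'
#' @param log2fc numeric vector of log2 fold changes at the post times.
#' @param q matching q-values.
#' @param times the post-administration times (minutes).
#' @param config a \code{pipeline_config}.
#' @return list(responsive, direction, earliest_sig_time).
#' @export
call_responsiveness <- function(log2fc, q, times, config = pipeline_config()) {
  stopifnot(length(log2fc) == length(q), length(q) == length(times))
  sig <- !is.na(q) & !is.na(log2fc) &
    q <= config$q_threshold & abs(log2fc) >= config$fc_threshold_log2
  if (!any(sig))
    return(list(responsive = FALSE, direction = "none",
                earliest_sig_time = NA_real_))
  first <- which(sig)[1]
  list(responsive = TRUE,
       direction = if (log2fc[first] > 0) "increase" else "decrease",
       earliest_sig_time = times[first])
}

#' Cross-genotype response class of one molecule
#'
#' @param wt_responsive,ob_responsive logicals.
#' @param wt_direction,ob_direction "increase"/"decrease"/"none".
#' @return "WT_specific", "OB_specific", "common" (responsive in both with
#'   the same direction), "opposite" (responsive in both with opposite
#'   directions) or "none".
#' @export
response_class <- function(wt_responsive, wt_direction,
                           ob_responsive, ob_direction) {
  if (isTRUE(wt_responsive) && isTRUE(ob_responsive)) {
    if (wt_direction == ob_direction) "common" else "opposite"
  } else if (isTRUE(wt_responsive)) "WT_specific"
  else if (isTRUE(ob_responsive)) "OB_specific"
  else "none"
}

#' Per-genotype responsiveness calls for one omic layer
#'
#' Full responsiveness workflow: detection filtering, fold changes of
#' replicate means versus the 0-min baseline, per-time-point two-group
#' tests against baseline (Welch for metabolite/phospho abundances; the
#' registered count test on library-size-scaled log2(count+1) values for
#' the gene layer), Storey q-values across molecules (per time point and
#' genotype by default, pooled across times behind a config flag), the
#' q/fold-change conjunction, and T1/2 with its speed class computed on the
#' log2 fold-change trace.
#'
#' @param tc an \code{omics_timecourse}.
#' @param config a \code{pipeline_config}.
#' @param count_method registered count-test method for the gene layer.
#' @return data.frame with one row per molecule x genotype: molecule_id,
#'   genotype, responsive, direction, earliest_sig_time, t_half, speed,
#'   baseline_undefined, and per-time log2fc_/p_/q_ columns.
#' @export
responsiveness_calls <- function(tc, config = pipeline_config(),
                                 count_method = "log_welch") {
  tc <- filter_detected(tc, config$min_detected_fraction)
  times <- tc_times(tc)
  post <- times[times > 0]
  ids <- tc_molecules(tc)
  if (length(ids) == 0L) {
    return(empty_calls_frame(post))
  }
  test_tc <- tc
  transform_counts <- tc$layer == "gene"
  if (transform_counts) test_tc <- scale_library_sizes(tc)
  mt <- tc_mean_traces(tc)
  res <- list()
  for (g in c("WT", "OB")) {
    X0 <- tc_slice(test_tc, g, 0)
    if (transform_counts) X0 <- log2(X0 + 1)
    P <- matrix(NA_real_, length(ids), length(post),
                dimnames = list(ids, as.character(post)))
    FC <- P
    for (t in as.character(post)) {
      Xt <- tc_slice(test_tc, g, t)
      if (transform_counts) {
        if (identical(count_method, "log_welch")) {
          P[, t] <- row_welch(log2(Xt + 1), X0)
        } else {
          raw0 <- tc_slice(test_tc, g, 0)
          P[, t] <- vapply(seq_along(ids), function(i)
            count_test(Xt[i, ], raw0[i, ], method = count_method), 0)
        }
        zero_both <- rowSums(Xt, na.rm = TRUE) == 0 &
          rowSums(tc_slice(test_tc, g, 0), na.rm = TRUE) == 0
        P[zero_both, t] <- 1
      } else {
        P[, t] <- row_welch(Xt, X0)
      }
      base <- mt[, g, "0"]
      fc <- log2(mt[, g, t] / base)
      fc[!is.finite(base) | base <= 0 | is.nan(fc) | is.infinite(fc)] <- NA_real_
      FC[, t] <- fc
    }
    if (config$pool_qvalues_across_times) {
      Q <- matrix(storey_qvalues(as.vector(P),
                                 fixed_lambda = config$storey_fixed_lambda),
                  nrow = nrow(P), dimnames = dimnames(P))
    } else {
      Q <- P
      for (t in as.character(post))
        Q[, t] <- storey_qvalues(P[, t],
                                 fixed_lambda = config$storey_fixed_lambda)
    }
    baseline_undefined <- apply(FC, 1, function(v) all(is.na(v)))
    rows <- lapply(seq_along(ids), function(i) {
      cl <- call_responsiveness(FC[i, ], Q[i, ], post, config)
      t_half <- NA_real_
      speed <- "undefined"
      if (cl$responsive) {
        trace <- c(0, FC[i, ])
        if (!anyNA(trace)) {
          t_half <- suppressWarnings(half_time(trace, times, cl$direction))
        }
        speed <- speed_class(t_half, config)
      }
      data.frame(molecule_id = ids[i], genotype = g,
                 responsive = cl$responsive, direction = cl$direction,
                 earliest_sig_time = cl$earliest_sig_time,
                 t_half = t_half, speed = speed,
                 baseline_undefined = baseline_undefined[i],
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    colnames(FC) <- paste0("log2fc_", colnames(FC))
    colnames(P) <- paste0("p_", colnames(P))
    colnames(Q) <- paste0("q_", colnames(Q))
    res[[g]] <- cbind(block, FC, P, Q)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  message(sprintf("responsiveness [%s]: %d of %d molecules responsive in WT, %d in OB",
                  tc$layer,
                  sum(out$responsive[out$genotype == "WT"]),
                  length(ids),
                  sum(out$responsive[out$genotype == "OB"])))
  out
}

empty_calls_frame <- function(post) {
  base <- data.frame(molecule_id = character(0), genotype = character(0),
                     responsive = logical(0), direction = character(0),
                     earliest_sig_time = numeric(0), t_half = numeric(0),
                     speed = character(0), baseline_undefined = logical(0),
                     stringsAsFactors = FALSE)
  for (pre in c("log2fc_", "p_", "q_"))
    for (t in as.character(post)) base[[paste0(pre, t)]] <- numeric(0)
  base
}

#' Cross-genotype response classes for a calls table
#'
#' @param calls output of \code{\link{responsiveness_calls}} (both
#'   genotypes).
#' @return data.frame(molecule_id, class, direction_WT, direction_OB,
#'   t_half_WT, t_half_OB, speed_WT, speed_OB).
#' @export
response_class_map <- function(calls) {
  wt <- calls[calls$genotype == "WT", ]
  ob <- calls[calls$genotype == "OB", ]
  ids <- union(wt$molecule_id, ob$molecule_id)
  wt <- wt[match(ids, wt$molecule_id), ]
  ob <- ob[match(ids, ob$molecule_id), ]
  cls <- vapply(seq_along(ids), function(i) {
    response_class(wt$responsive[i], wt$direction[i],
                   ob$responsive[i], ob$direction[i])
  }, "")
  data.frame(molecule_id = ids, class = cls,
             direction_WT = wt$direction, direction_OB = ob$direction,
             t_half_WT = wt$t_half, t_half_OB = ob$t_half,
             speed_WT = wt$speed, speed_OB = ob$speed,
             responsive_WT = wt$responsive, responsive_OB = ob$responsive,
             stringsAsFactors = FALSE)
}

#' Baseline (0-min) WT-versus-OB difference q-values
#'
#' Tests each molecule's fasting abundance between genotypes (Welch, or the
#' count test for the gene layer) and converts the p-vector to Storey
#' q-values. Used to select genes for the clustering analysis.
#' @param tc an \code{omics_timecourse}.
#' @param config a \code{pipeline_config}.
#' @return data.frame(molecule_id, p, q).
#' @export
baseline_difference_qvalues <- function(tc, config = pipeline_config()) {
  test_tc <- tc
  transform_counts <- tc$layer == "gene"
  if (transform_counts) test_tc <- scale_library_sizes(tc)
  W <- tc_slice(test_tc, "WT", 0)
  O <- tc_slice(test_tc, "OB", 0)
  if (transform_counts) {
    W <- log2(W + 1); O <- log2(O + 1)
  }
  p <- row_welch(W, O)
  data.frame(molecule_id = tc_molecules(tc), p = p,
             q = storey_qvalues(p, fixed_lambda = config$storey_fixed_lambda),
             stringsAsFactors = FALSE)
}
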